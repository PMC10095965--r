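# Growing zone membership, measured in natural arc length from the apical
# end (the zone advects with the tip as the rod grows).

# natural arc distance from the apex to each bond midpoint
bond_tip_distance <- function(a) {
  rev(cumsum(rev(a))) - a / 2
}

# natural arc distance from the apex to each interior vertex (2..N-1)
vertex_tip_distance <- function(a) {
  n <- length(a) + 1
  rev(cumsum(rev(a)))[-1] # vertex i sits below bonds i..N-1
}

#' One growth increment of the apical zone
#'
#' Every bond whose natural-arc-length midpoint lies within `Lgz` of the
#' apical end elongates its natural length by the uniform relative rate
#' `v / Lgz` over `dt`; bonds outside the zone are unchanged. The clamped
#' basal bond (between the two fixed vertices) never grows: the clamp holds
#' material points, so growth there could not be expressed and would only
#' pump spurious stretching energy into the base. Intrinsic curvatures are
#' stored per unit length and are therefore preserved under elongation (the
#' natural turning angle `phi0 = kappa0 * abar` rescales automatically).
#'
#' @param state a [rod_state()].
#' @param gp a [growth_params()].
#' @return The grown [rod_state()] (an attribute `elongation_rate` carries
#'   the per-bond relative elongation rate, 1/min).
#' @export
grow_step <- function(state, gp) {
  stopifnot(inherits(state, "rod_state"), inherits(gp, "growth_params"))
  a <- state$a
  in_zone <- bond_tip_distance(a) <= gp$Lgz
  in_zone[1] <- FALSE
  rate <- ifelse(in_zone, gp$v / gp$Lgz, 0)
  state$a <- a * (1 + rate * gp$dt)
  attr(state, "elongation_rate") <- rate
  state
}

#' Gravi-proprioceptive intrinsic-curvature update
#'
#' In the growing zone only, the intrinsic curvature of each interior vertex
#' follows `kappa0 <- kappa0 + dt * (beta * sigma * cos(theta) -
#' gamma * kappa)`: gravitropic bending proportional to the horizontal
#' component of the local tangent (the sine of the angle from the vertical),
#' opposed by proprioceptive straightening proportional to the current
#' curvature. `theta` is the local tangent angle from horizontal and `kappa`
#' the realized curvature of the supplied geometry (or the intrinsic
#' curvature when `gp$proprio_on_intrinsic`). Outside the growing zone the
#' target geometry is left untouched.
#'
#' @param state a [rod_state()].
#' @param geom the [rod_geometry()] of the current equilibrium.
#' @param gp a [growth_params()].
#' @return The updated [rod_state()].
#' @export
gravi_proprio_update <- function(state, geom, gp) {
  stopifnot(inherits(state, "rod_state"), inherits(geom, "rod_geometry"),
            inherits(gp, "growth_params"))
  in_zone <- vertex_tip_distance(state$a) <= gp$Lgz
  if (!any(in_zone)) return(state)
  theta <- geom$vertex_angles[-c(1, length(geom$vertex_angles))]
  kap <- if (gp$proprio_on_intrinsic) state$kappa0 else geom$curvatures
  dk <- gp$dt * (gp$beta * gp$sigma * cos(theta) - gp$gamma * kap)
  state$kappa0[in_zone] <- state$kappa0[in_zone] + dk[in_zone]
  state
}

#' Simulate a growing gravitropic shoot
#'
#' The simulation loop: record the current equilibrium, then grow the apical
#' zone, update the intrinsic curvature by the gravi-proprioceptive law, and
#' relax back to mechanical equilibrium; repeat until `t_end`. Each stored
#' step keeps the out-of-balance forces at relaxation start (the forces that
#' drive the motion of that step) and the per-component displacement record
#' accumulated along the relaxation path.
#'
#' @param init an equilibrated (or to-be-equilibrated) initial [rod_state()].
#' @param mp a [mech_params()].
#' @param gp a [growth_params()].
#' @param pre_equilibrate relax `init` before the loop (default `TRUE`).
#' @return An object of class `rod_trajectory`: list with `frames` (each
#'   `time`, `state`, `geom`), `steps` (each `time`, `forces_start`,
#'   `displacement`, `elongation_rate`), and the parameter objects.
#' @export
simulate_shoot <- function(init, mp, gp, pre_equilibrate = TRUE) {
  stopifnot(inherits(init, "rod_state"), inherits(mp, "mech_params"),
            inherits(gp, "growth_params"))
  state <- init
  if (pre_equilibrate) {
    state <- tryCatch(equilibrate(state, mp)$state,
                      error = function(e) stop("pre-equilibration failed: ",
                                               conditionMessage(e)))
  }
  times <- seq(0, gp$t_end, by = gp$dt)
  frames <- vector("list", length(times))
  steps <- vector("list", max(length(times) - 1, 0))
  for (k in seq_along(times)) {
    state$t <- times[k]
    frames[[k]] <- list(time = times[k], state = state,
                        geom = rod_geometry(state))
    if (k == length(times)) break
    state <- grow_step(state, gp)
    elong <- attr(state, "elongation_rate")
    state <- gravi_proprio_update(state, frames[[k]]$geom, gp)
    f0 <- rod_forces(state, mp)
    eq <- tryCatch(equilibrate(state, mp), error = function(e) {
      stop(sprintf("equilibration failed at t = %g min: %s",
                   times[k + 1], conditionMessage(e)))
    })
    state <- eq$state
    steps[[k]] <- list(time = times[k], forces_start = f0,
                       displacement = eq$record, elongation_rate = elong)
  }
  traj <- list(frames = frames, steps = steps, mp = mp, gp = gp,
               times = times)
  class(traj) <- "rod_trajectory"
  traj
}

#' @export
print.rod_trajectory <- function(x, ...) {
  n <- length(x$frames)
  L0 <- x$frames[[1]]$geom$L
  L1 <- x$frames[[n]]$geom$L
  cat(sprintf("rod_trajectory: %d frames over %g min, L %.2f -> %.2f mm\n",
              n, x$times[n], L0, L1))
  invisible(x)
}

#' Serialize / load a trajectory directory
#'
#' Writes one rod-state CSV per frame plus a JSON manifest holding the
#' parameters and per-step relaxation residuals.
#'
#' @param traj a `rod_trajectory`.
#' @param dir output directory (created if needed).
#' @export
write_trajectory <- function(traj, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(traj$frames)) {
    write_rod_state(traj$frames[[k]]$state,
                    file.path(dir, sprintf("frame_%04d.csv", k)))
  }
  manifest <- list(
    times = traj$times,
    mech = unclass(traj$mp)[c("ks", "B", "rho", "g", "mu", "dtau", "eps_f",
                              "max_relax_iters", "method")],
    growth = unclass(traj$gp),
    residuals = vapply(traj$steps, function(s) s$displacement$residual, 0))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_trajectory
#' @return `read_trajectory()` returns a list with `frames` (states only) and
#'   the manifest.
#' @export
read_trajectory <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  frames <- lapply(seq_along(man$times), function(k) {
    read_rod_state(file.path(dir, sprintf("frame_%04d.csv", k)),
                   t = man$times[k])
  })
  list(frames = frames, manifest = man)
}
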