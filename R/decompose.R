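# Attribution of shoot motion to stretching, bending and gravitational
# forces. At equilibrium the net force vanishes, so instantaneous forces at
# the equilibria cannot be compared directly; instead each component's
# displacement is accumulated along the relaxation path (mu * F_c * dtau per
# relaxation step), which makes the attribution exactly additive.

#' Decompose a trajectory's motion into per-force displacement maps
#'
#' Aggregates the per-step, per-vertex component displacements onto
#' (time x arc-length) grids: magnitudes `|dx_c|` and signed projections of
#' each component onto the local bending direction (the unit normal toward
#' the side the shoot curves to; positive = promotes bending). Force grids
#' `Fproj_s`, `Fproj_b`, `Fproj_g` are the same signed projections of the
#' out-of-balance forces at relaxation start — the active forces injected
#' by the growth increment (stretching) and the gravi-proprioceptive
#' curvature increment (bending). Projecting onto the bending direction
#' isolates their bending-relevant part: the raw stretching force also
#' carries a purely axial stress jump at the growth-zone boundary
#' (`ks * da`), a discretization artifact that is independent of the
#' bending state and would otherwise mask the biology. The scalar maxima
#' `F_s_max`, `F_b_max` are the largest projected magnitudes over free
#' vertices and steps.
#'
#' @param traj a `rod_trajectory` from [simulate_shoot()].
#' @param side bending side: `"auto"` (default; the sign of the
#'   length-weighted mean curvature of each frame) or `+1` / `-1` to force
#'   the counter-clockwise / clockwise side.
#' @return An object of class `force_maps`: list of matrices (`steps` x
#'   `vertices`) `mag_total`, `mag_s`, `mag_b`, `mag_g`, `proj_s`, `proj_b`,
#'   `proj_g`, `proj_total`, `Fproj_s`, `Fproj_b`, `Fproj_g`, plus `times`,
#'   `s` (arc length per vertex at each step start), `F_s_max`, `F_b_max`.
#' @export
decompose_displacements <- function(traj, side = "auto") {
  stopifnot(inherits(traj, "rod_trajectory"))
  if (!length(traj$steps)) stop("trajectory has no step records")
  ns <- length(traj$steps)
  n <- nrow(traj$frames[[1]]$state$x)
  mk <- function() matrix(0, ns, n)
  out <- list(mag_total = mk(), mag_s = mk(), mag_b = mk(), mag_g = mk(),
              proj_total = mk(), proj_s = mk(), proj_b = mk(), proj_g = mk(),
              Fproj_s = mk(), Fproj_b = mk(), Fproj_g = mk())
  smat <- mk()
  free <- 3:n
  Fsmax <- 0; Fbmax <- 0
  for (k in seq_len(ns)) {
    st <- traj$steps[[k]]
    geom <- traj$frames[[k]]$geom
    smat[k, ] <- geom$arc_length
    # per-vertex unit tangent angle -> bending normal
    th <- geom$vertex_angles
    sgn <- if (identical(side, "auto")) {
      s0 <- sum(geom$curvatures * geom$voronoi_lengths)
      if (s0 >= 0) 1 else -1
    } else side
    nx <- -sin(th) * sgn
    ny <- cos(th) * sgn
    d <- st$displacement
    comp <- list(total = d$dx_total, s = d$dx_s, b = d$dx_b, g = d$dx_g)
    for (nm in names(comp)) {
      m <- comp[[nm]]
      out[[paste0("mag_", nm)]][k, ] <- sqrt(m[, 1]^2 + m[, 2]^2)
      out[[paste0("proj_", nm)]][k, ] <- m[, 1] * nx + m[, 2] * ny
    }
    # active (out-of-balance) forces at relaxation start, bending part
    f <- st$forces_start
    out$Fproj_s[k, ] <- f$Fs[, 1] * nx + f$Fs[, 2] * ny
    out$Fproj_b[k, ] <- f$Fb[, 1] * nx + f$Fb[, 2] * ny
    out$Fproj_g[k, ] <- f$Fg[, 1] * nx + f$Fg[, 2] * ny
    Fsmax <- max(Fsmax, abs(out$Fproj_s[k, free]))
    Fbmax <- max(Fbmax, abs(out$Fproj_b[k, free]))
  }
  out$times <- vapply(traj$steps, function(s) s$time, 0)
  out$s <- smat
  out$F_s_max <- Fsmax
  out$F_b_max <- Fbmax
  class(out) <- "force_maps"
  out
}

#' Compare maximum out-of-balance forces between two runs
#'
#' @param trajA,trajB `rod_trajectory` objects (e.g. wild-type-like and
#'   mutant-like averaged models).
#' @return A data frame with `F_s_max` and `F_b_max` for each run and the
#'   B/A ratios.
#' @export
compare_max_forces <- function(trajA, trajB) {
  a <- decompose_displacements(trajA)
  b <- decompose_displacements(trajB)
  data.frame(force = c("stretching", "bending"),
             max_A = c(a$F_s_max, a$F_b_max),
             max_B = c(b$F_s_max, b$F_b_max),
             ratio_B_over_A = c(b$F_s_max / a$F_s_max,
                                b$F_b_max / a$F_b_max))
}

#' Flank elongation rates and differential-cell-growth map
#'
#' Treats the shoot as a solid rod of radius `R`: the two flanks of a
#' segment with natural length `a` and intrinsic curvature `kappa0` have
#' natural lengths `L_plus = a (1 + R kappa0)` (the flank that lengthens as
#' the up-bending curvature grows: the convex, outer flank for positive
#' curvature) and `L_minus = a (1 - R kappa0)` (inner flank). Relative
#' elongation rates are `Edot = d ln L / dt` across consecutive steps, and
#' the differential-cell-growth measure is `DCG = Edot_in - Edot_out`:
#' negative when the outer flank grows faster (up-bending), positive when
#' the inner one does (straightening). `normalized = TRUE` divides DCG by
#' the mean absolute flank rate.
#'
#' @param traj a `rod_trajectory`.
#' @param R flank half-thickness (mm); must satisfy `R * |kappa0| < 1`
#'   everywhere.
#' @param normalized divide DCG by the mean absolute flank rate.
#' @return An object of class `dcg_map`: list with `times`, `s` (bond
#'   midpoints per step), matrices `E_out`, `E_in`, `DCG`.
#' @export
flank_rates <- function(traj, R = 0.5, normalized = FALSE) {
  stopifnot(inherits(traj, "rod_trajectory"), R > 0)
  nf <- length(traj$frames)
  if (nf < 2) stop("need at least two frames")
  dt <- traj$gp$dt
  nb <- nrow(traj$frames[[1]]$state$x) - 1
  flank <- function(state) {
    k0b <- bond_kappa0_mid(state)
    if (any(R * abs(k0b) >= 1)) {
      stop("R * |kappa0| >= 1: flank construction geometrically invalid")
    }
    list(out = state$a * (1 + R * k0b), inn = state$a * (1 - R * k0b))
  }
  E_out <- matrix(NA_real_, nf - 1, nb)
  E_in <- matrix(NA_real_, nf - 1, nb)
  smid <- matrix(NA_real_, nf - 1, nb)
  prev <- flank(traj$frames[[1]]$state)
  for (k in 2:nf) {
    cur <- flank(traj$frames[[k]]$state)
    E_out[k - 1, ] <- (log(cur$out) - log(prev$out)) / dt
    E_in[k - 1, ] <- (log(cur$inn) - log(prev$inn)) / dt
    s <- traj$frames[[k - 1]]$geom$arc_length
    smid[k - 1, ] <- (s[-1] + s[-(nb + 1)]) / 2
    prev <- cur
  }
  DCG <- E_in - E_out
  if (normalized) {
    denom <- pmax((abs(E_in) + abs(E_out)) / 2, .Machine$double.eps)
    DCG <- DCG / denom
  }
  out <- list(times = traj$times[-nf], s = smid,
              E_out = E_out, E_in = E_in, DCG = DCG, R = R,
              normalized = normalized)
  class(out) <- "dcg_map"
  out
}

# bond-level intrinsic curvature: mean of adjacent interior-vertex values,
# with end bonds taking their single neighbour's value
bond_kappa0_mid <- function(state) {
  k0v <- c(state$kappa0[1], state$kappa0,
           state$kappa0[length(state$kappa0)])
  (k0v[-length(k0v)] + k0v[-1]) / 2
}

#' Flag cells where the inner flank shrinks while the outer grows
#'
#' @param traj a `rod_trajectory`.
#' @param R flank half-thickness (mm).
#' @return A list with the logical flag matrix `shrinking`, the number of
#'   flagged (time, segment) cells and the underlying [flank_rates()] map.
#' @export
inner_flank_shrinkage_check <- function(traj, R = 0.5) {
  m <- flank_rates(traj, R = R)
  flag <- m$E_in < 0 & m$E_out > 0
  list(shrinking = flag, n_cells = sum(flag), map = m)
}

#' Write a (time x position) map as TSV
#'
#' @param mat matrix with rows = times.
#' @param times row time stamps.
#' @param path TSV path.
#' @param col_prefix prefix for column names.
#' @export
write_map_tsv <- function(mat, times, path, col_prefix = "c") {
  df <- data.frame(time_min = times, mat, check.names = FALSE)
  names(df) <- c("time_min", sprintf("%s%d", col_prefix, seq_len(ncol(mat))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
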