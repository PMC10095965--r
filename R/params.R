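#' Mechanical parameters of the discrete rod
#'
#' Bundles the elastic and relaxation constants of the discrete rod. Working
#' units are millimetres and minutes; the force unit is fixed by the bending
#' modulus `B` (default 1), since only the combination `rho * g` (self-weight
#' per unit length) and `B` enter the equilibrium shapes through the
#' elasto-gravity length `Lg = (B / (rho*g))^(1/3)`. Physical reporting in
#' newtons, when wanted, uses the Young's modulus `E` (MPa) and radius `R`
#' (mm) via `B = E * pi * R^4 / 4`.
#'
#' The stretching stiffness `ks` is chosen so the rod is practically
#' inextensible: axial loads of order `rho*g*L` and `B*kappa/a` then produce
#' bond strains below `1e-3`.
#'
#' @param ks stretching stiffness (force/mm) of each bond spring.
#' @param B bending modulus (force * mm^2); the per-vertex discrete bending
#'   stiffness is `kb_i = B / abar_i` where `abar_i` is the Voronoi length.
#' @param E,R optional Young's modulus (MPa) and radius (mm); when both are
#'   given they override `B` via `B = E * pi * R^4 / 4`.
#' @param rho linear mass density (mass/mm). Give either `rho` or `Lg`.
#' @param g gravitational acceleration (oriented along -y). Only `rho * g`
#'   matters.
#' @param Lg elasto-gravity length (mm); used to set `rho = B / (g * Lg^3)`
#'   when `rho` is not supplied.
#' @param mu mobility (mm / (force * pseudo-time)) of the overdamped
#'   relaxation.
#' @param dtau relaxation pseudo-time step; default `0.1 / sqrt(ks)`, a tenth
#'   of the stability bound set by the stiffest (stretching) mode.
#' @param eps_f force tolerance: relaxation stops when the largest net force
#'   on a free vertex falls below `eps_f`.
#' @param max_relax_iters iteration cap for one equilibration.
#' @param method relaxation scheme: `"newton"` (default; damped Newton with
#'   a banded Cholesky solve), `"lbfgs"` (limited-memory quasi-Newton) or
#'   `"fire"` / `"gd"` (first-order inertial / plain overdamped gradient
#'   descent, the textbook scheme). In every scheme the search direction is
#'   a linear operator applied to the total force, so the same operator
#'   applied to each force component yields per-component displacements
#'   that sum exactly to the total (the attribution contract used by the
#'   force-decomposition stage).
#' @return An object of class `mech_params`.
#' @export
mech_params <- function(ks = 200, B = NULL, E = NULL, R = 0.5,
                        rho = NULL, g = 1, Lg = 40,
                        mu = 1, dtau = NULL, eps_f = 1e-8,
                        max_relax_iters = 500000L,
                        method = c("newton", "lbfgs", "fire", "gd")) {
  method <- match.arg(method)
  if (!is.null(E) && !is.null(R)) {
    B <- E * pi * R^4 / 4
  } else if (is.null(B)) {
    B <- 1
  }
  if (is.null(rho)) {
    stopifnot(Lg > 0)
    rho <- B / (g * Lg^3)
  }
  if (is.null(dtau)) dtau <- 0.1 / sqrt(ks)
  p <- list(ks = ks, B = B, E = E, R = R, rho = rho, g = g,
            mu = mu, dtau = dtau, eps_f = eps_f,
            max_relax_iters = as.integer(max_relax_iters),
            method = method)
  stopifnot(p$ks > 0, p$B > 0, p$rho > 0, p$g > 0, p$mu > 0,
            p$dtau > 0, p$eps_f > 0, p$max_relax_iters > 0)
  class(p) <- "mech_params"
  p
}

#' Growth and gravi-proprioceptive parameters
#'
#' @param v uniform growth speed (mm/min) of the apical growing zone.
#' @param Lgz length of the growing zone measured in natural arc length from
#'   the apical end (mm).
#' @param beta gravitropic sensitivity (1/(mm*min)): rate of intrinsic
#'   curvature gain per unit horizontal stimulus `cos(theta)`.
#' @param gamma proprioceptive sensitivity (1/min): rate at which realized
#'   curvature is straightened out of the intrinsic curvature.
#' @param dt simulation time step (min); default 1, matching a one-frame-per-
#'   minute acquisition.
#' @param t_end end of the run (min), default 140.
#' @param sigma sign selecting the upward-bending curvature direction for the
#'   rod's pointing direction: `+1` for a rod pointing along +x
#'   (counter-clockwise curvature bends it upward).
#' @param proprio_on_intrinsic if `TRUE` the proprioceptive term reads the
#'   intrinsic curvature `kappa0` instead of the realized curvature `kappa`.
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(v = 0.02, Lgz = 40, beta = 1e-3, gamma = 0.02,
                          dt = 1, t_end = 140, sigma = 1,
                          proprio_on_intrinsic = FALSE) {
  stopifnot(v >= 0, Lgz > 0, beta >= 0, gamma >= 0, dt > 0, t_end >= 0,
            sigma %in% c(-1, 1))
  p <- list(v = v, Lgz = Lgz, beta = beta, gamma = gamma, dt = dt,
            t_end = t_end, sigma = sigma,
            proprio_on_intrinsic = isTRUE(proprio_on_intrinsic))
  class(p) <- "growth_params"
  p
}

#' Dimensionless groups of the growing-rod model
#'
#' Three length scales control the model: the sensitivity length
#' `ls = gamma / beta` (where gravitropic bending and proprioceptive
#' straightening balance), the growing-zone length `Lgz`, and the
#' elasto-gravity length `Lg = (B / (rho*g))^(1/3)` over which elasticity
#' withstands sagging. The two governing dimensionless numbers are the
#' growth-sensitivity parameter `S = Lgz / ls` and the growth-elasto-gravity
#' parameter `Gt = Lg / Lgz`.
#'
#' @param gp a [growth_params()] object.
#' @param mp a [mech_params()] object.
#' @return A list with `ls`, `Lg`, `S`, `Gt`.
#' @export
dimensionless_groups <- function(gp, mp) {
  stopifnot(inherits(gp, "growth_params"), inherits(mp, "mech_params"))
  if (gp$beta <= 0) stop("beta must be positive to define ls = gamma / beta")
  ls <- gp$gamma / gp$beta
  Lg <- (mp$B / (mp$rho * mp$g))^(1 / 3)
  list(ls = ls, Lg = Lg, S = gp$Lgz / ls, Gt = Lg / gp$Lgz)
}

#' Solve for beta giving a requested growth-sensitivity parameter S
#'
#' Inverse helper: with `gamma` and `Lgz` held fixed, `S = Lgz * beta / gamma`
#' so `beta = S * gamma / Lgz`.
#'
#' @param S requested growth-sensitivity parameter (> 0).
#' @param gamma proprioceptive sensitivity (1/min).
#' @param Lgz growing-zone length (mm).
#' @export
beta_for_S <- function(S, gamma, Lgz) {
  stopifnot(S > 0, gamma > 0, Lgz > 0)
  S * gamma / Lgz
}

#' Solve for rho giving a requested growth-elasto-gravity parameter Gt
#'
#' Inverse helper: `Gt = Lg / Lgz` with `Lg = (B/(rho*g))^(1/3)`, so
#' `rho = B / (g * (Gt * Lgz)^3)`.
#'
#' @param Gt requested growth-elasto-gravity parameter (> 0).
#' @param Lgz growing-zone length (mm).
#' @param B bending modulus.
#' @param g gravitational acceleration.
#' @export
rho_for_Gt <- function(Gt, Lgz, B = 1, g = 1) {
  stopifnot(Gt > 0, Lgz > 0, B > 0, g > 0)
  B / (g * (Gt * Lgz)^3)
}

#' @export
print.mech_params <- function(x, ...) {
  cat("Mechanical parameters (mm/min units, force unit set by B)\n")
  cat(sprintf("  ks = %g, B = %g, rho*g = %g (Lg = %.3g mm)\n",
              x$ks, x$B, x$rho * x$g, (x$B / (x$rho * x$g))^(1 / 3)))
  cat(sprintf("  relaxation: %s, dtau = %g, eps_f = %g, max %d iters\n",
              x$method, x$dtau, x$eps_f, x$max_relax_iters))
  invisible(x)
}

#' @export
print.growth_params <- function(x, ...) {
  cat("Growth / gravi-proprioceptive parameters\n")
  cat(sprintf("  v = %g mm/min, Lgz = %g mm, beta = %g /(mm min), gamma = %g /min\n",
              x$v, x$Lgz, x$beta, x$gamma))
  cat(sprintf("  dt = %g min, t_end = %g min\n", x$dt, x$t_end))
  invisible(x)
}
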