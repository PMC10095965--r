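#' Discrete rod state
#'
#' A rod state is the full configuration of the discrete shoot centerline:
#' vertex positions, the natural (stress-free) length of each bond and the
#' intrinsic curvature at each interior vertex. The first two vertices are
#' clamped (fixed position, hence fixed base tangent); the apical end is free
#' of force and moment conditions.
#'
#' @param x numeric N x 2 matrix of vertex positions (mm), base first.
#' @param a numeric vector of N-1 natural bond lengths (mm); defaults to the
#'   current bond lengths (rod at rest).
#' @param kappa0 numeric vector of N-2 intrinsic curvatures (1/mm) at the
#'   interior vertices; defaults to 0 (straight natural shape).
#' @param t time stamp (min).
#' @return An object of class `rod_state`.
#' @export
rod_state <- function(x, a = NULL, kappa0 = NULL, t = 0) {
  x <- as.matrix(x)
  if (ncol(x) != 2) stop("x must be an N x 2 matrix")
  n <- nrow(x)
  if (n < 3) stop("a rod needs at least 3 vertices")
  d <- sqrt(rowSums((x[-1, , drop = FALSE] - x[-n, , drop = FALSE])^2))
  if (any(d < 1e-12)) stop("degenerate geometry: coincident consecutive vertices")
  if (is.null(a)) a <- d
  if (length(a) != n - 1 || any(a <= 0)) stop("a must be N-1 positive lengths")
  if (is.null(kappa0)) kappa0 <- numeric(n - 2)
  if (length(kappa0) != n - 2) stop("kappa0 must have N-2 entries")
  theta_base <- atan2(x[2, 2] - x[1, 2], x[2, 1] - x[1, 1])
  s <- list(x = unname(x), a = as.numeric(a), kappa0 = as.numeric(kappa0),
            theta_base = theta_base, t = t)
  class(s) <- "rod_state"
  s
}

#' Straight rod builder
#'
#' @param L total length (mm).
#' @param n number of vertices.
#' @param theta base tangent angle from horizontal (rad).
#' @param base 2-vector base position (mm).
#' @export
straight_rod <- function(L, n = 41, theta = 0, base = c(0, 0)) {
  stopifnot(L > 0, n >= 3)
  s <- seq(0, L, length.out = n)
  rod_state(cbind(base[1] + s * cos(theta), base[2] + s * sin(theta)))
}

#' Geometry of a rod state
#'
#' Computes realized bond lengths, bond tangent angles (vs the +x axis),
#' turning angles at interior vertices, Voronoi lengths
#' `abar_i = (a_{i-1} + a_i)/2` built from *natural* lengths, the discrete
#' curvature `kappa_i = phi_i / abar_i` and the cumulative arc length with
#' origin at the base. `vertex_angles` holds a per-vertex tangent angle (mean
#' of the adjacent bond angles at interior vertices) used by the
#' gravi-proprioceptive update.
#'
#' @param state a [rod_state()].
#' @return An object of class `rod_geometry`.
#' @export
rod_geometry <- function(state) {
  stopifnot(inherits(state, "rod_state"))
  x <- state$x
  n <- nrow(x)
  e <- x[-1, , drop = FALSE] - x[-n, , drop = FALSE]
  l <- sqrt(rowSums(e^2))
  if (any(l < 1e-12)) stop("degenerate geometry: coincident consecutive vertices")
  theta <- atan2(e[, 2], e[, 1])
  # turning angle at interior vertex i: angle from bond i-1 to bond i
  e1 <- e[-(n - 1), , drop = FALSE]
  e2 <- e[-1, , drop = FALSE]
  cross <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  dot <- rowSums(e1 * e2)
  phi <- atan2(cross, dot)
  abar <- (state$a[-(n - 1)] + state$a[-1]) / 2
  kappa <- phi / abar
  s <- c(0, cumsum(l))
  vertex_angles <- c(theta[1], (theta[-(n - 1)] + theta[-1]) / 2, theta[n - 1])
  g <- list(bond_lengths = l, bond_angles = theta, turning_angles = phi,
            voronoi_lengths = abar, curvatures = kappa, arc_length = s,
            L = sum(l), vertex_angles = vertex_angles)
  class(g) <- "rod_geometry"
  g
}

# lumped vertex masses from natural lengths (half segments at the ends)
vertex_masses <- function(state, mp) {
  a <- state$a
  n <- length(a) + 1
  mp$rho * c(a[1] / 2, (a[-(n - 1)] + a[-1]) / 2, a[n - 1] / 2)
}

#' Elastic and gravitational potential energies of a rod state
#'
#' `U_s = (ks/2) sum (l_j - a_j)^2`,
#' `U_b = sum (kb_i/2) (phi_i - kappa0_i * abar_i)^2` with `kb_i = B/abar_i`,
#' `U_g = g * sum m_i y_i` with lumped masses `m_i = rho * abar_i`.
#'
#' @param state a [rod_state()].
#' @param mp a [mech_params()].
#' @return Named numeric vector `c(U_s, U_b, U_g)`.
#' @export
rod_energies <- function(state, mp) {
  stopifnot(inherits(state, "rod_state"), inherits(mp, "mech_params"))
  g <- rod_geometry(state)
  U_s <- mp$ks / 2 * sum((g$bond_lengths - state$a)^2)
  kb <- mp$B / g$voronoi_lengths
  phi0 <- state$kappa0 * g$voronoi_lengths
  U_b <- sum(kb / 2 * (g$turning_angles - phi0)^2)
  U_g <- mp$g * sum(vertex_masses(state, mp) * state$x[, 2])
  c(U_s = U_s, U_b = U_b, U_g = U_g)
}

#' Per-vertex forces on a rod state
#'
#' Exact analytic negative gradients of the stretching, bending and
#' gravitational potentials with respect to the vertex positions, plus the
#' internal moment `M_i = kb_i (phi_i - phi0_i)` at interior vertices.
#' Clamped vertices report their forces but are never moved by
#' [equilibrate()].
#'
#' @param state a [rod_state()].
#' @param mp a [mech_params()].
#' @return An object of class `force_set`: list with N x 2 matrices `Fs`,
#'   `Fb`, `Fg` and the interior-moment vector `M`.
#' @export
rod_forces <- function(state, mp) {
  stopifnot(inherits(state, "rod_state"), inherits(mp, "mech_params"))
  f <- cpp_rod_forces(state$x, state$a, state$kappa0,
                      mp$ks, mp$B, mp$rho * mp$g)
  g <- rod_geometry(state)
  kb <- mp$B / g$voronoi_lengths
  f$M <- kb * (g$turning_angles - state$kappa0 * g$voronoi_lengths)
  class(f) <- "force_set"
  f
}

#' Relax a rod to mechanical equilibrium
#'
#' Overdamped relaxation of the free vertices,
#' `x_i <- x_i + mu * (Fs_i + Fb_i + Fg_i) * dtau`, until the largest net
#' force on a free vertex is below `eps_f`. The default scheme is FIRE
#' (inertial minimization with adaptive step), which takes steps parallel to
#' a velocity built linearly from past total forces; the velocity is carried
#' split into stretching/bending/gravity parts so the accumulated
#' per-component displacements sum exactly to the total displacement.
#'
#' @param state a [rod_state()] (first two vertices clamped).
#' @param mp a [mech_params()].
#' @return A list with `state` (equilibrated [rod_state()]) and `record`, a
#'   displacement record with N x 2 matrices `dx_total`, `dx_s`, `dx_b`,
#'   `dx_g` plus `iterations` and `residual`.
#' @export
equilibrate <- function(state, mp) {
  stopifnot(inherits(state, "rod_state"), inherits(mp, "mech_params"))
  r <- if (mp$method == "newton") {
    cpp_relax_newton(state$x, state$a, state$kappa0,
                     mp$ks, mp$B, mp$rho * mp$g,
                     2L, mp$eps_f, min(mp$max_relax_iters, 10000L))
  } else if (mp$method == "lbfgs") {
    cpp_relax_lbfgs(state$x, state$a, state$kappa0,
                    mp$ks, mp$B, mp$rho * mp$g,
                    2L, mp$eps_f, mp$max_relax_iters)
  } else {
    cpp_relax(state$x, state$a, state$kappa0,
              mp$ks, mp$B, mp$rho * mp$g,
              2L, mp$mu, mp$dtau, mp$eps_f, mp$max_relax_iters,
              if (mp$method == "gd") 0L else 1L, 5)
  }
  if (!r$converged) {
    stop(sprintf(
      "equilibration did not converge in %d iterations (residual %.3g > eps_f %.3g)",
      r$iterations, r$residual, mp$eps_f))
  }
  out <- state
  out$x <- r$x
  list(state = out,
       record = list(dx_total = r$dx_total, dx_s = r$dx_s, dx_b = r$dx_b,
                     dx_g = r$dx_g, iterations = r$iterations,
                     residual = r$residual))
}

#' Write / read a rod state as CSV
#'
#' Columns: `index, x_mm, y_mm, natural_length_mm, intrinsic_curvature_per_mm`
#' (header mandatory). The natural length on row i belongs to the bond from
#' vertex i to i+1 (last row NA); intrinsic curvature is defined on interior
#' vertices only (first and last rows NA).
#'
#' @param state a [rod_state()].
#' @param path file path.
#' @export
write_rod_state <- function(state, path) {
  n <- nrow(state$x)
  df <- data.frame(index = seq_len(n),
                   x_mm = state$x[, 1], y_mm = state$x[, 2],
                   natural_length_mm = c(state$a, NA),
                   intrinsic_curvature_per_mm = c(NA, state$kappa0, NA))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rod_state
#' @param t time stamp to attach to the state read back.
#' @export
read_rod_state <- function(path, t = 0) {
  df <- read.csv(path)
  need <- c("index", "x_mm", "y_mm", "natural_length_mm",
            "intrinsic_curvature_per_mm")
  if (!all(need %in% names(df))) {
    stop("malformed rod-state CSV: expected columns ",
         paste(need, collapse = ", "))
  }
  df <- df[order(df$index), ]
  n <- nrow(df)
  rod_state(cbind(df$x_mm, df$y_mm),
            a = df$natural_length_mm[-n],
            kappa0 = df$intrinsic_curvature_per_mm[c(-1, -n)],
            t = t)
}

#' @export
print.rod_state <- function(x, ...) {
  g <- rod_geometry(x)
  cat(sprintf("rod_state: %d vertices, L = %.3f mm (natural %.3f mm), t = %g min\n",
              nrow(x$x), g$L, sum(x$a), x$t))
  cat(sprintf("  base at (%.2f, %.2f), base tangent %.1f deg\n",
              x$x[1, 1], x$x[1, 2], x$theta_base * 180 / pi))
  invisible(x)
}
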