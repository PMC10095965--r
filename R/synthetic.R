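# Synthetic time-lapse cohorts with known ground truth, emulating
# near-horizontal Arabidopsis inflorescence stems imaged over 140 min.
# No experimental dataset ships with the package; the generator is the
# test bed for every downstream stage.

#' Specification of a synthetic cohort
#'
#' Defaults emulate a typical gravistimulation experiment: primary
#' inflorescence stems 40-80 mm long (drawn around 45 mm), placed almost
#' horizontally (small base-angle jitter), imaged once per minute for
#' 140 min and digitized as about 20 points per frame with ~0.1 mm
#' positional noise. The genotype contrast is carried purely by the
#' gravitropic sensitivity `beta`; a mutant-like cohort uses the wild-type
#' spec with `beta` halved, equal proprioception `gamma` and equal growth.
#'
#' @param n_individuals cohort size (default 16, wild-type-like).
#' @param genotype label.
#' @param L0_mean,L0_sd,L0_range initial length distribution (mm), truncated
#'   to `L0_range`.
#' @param base_angle_sd jitter of the base tangent around horizontal (rad).
#' @param beta_mean,beta_sd gravitropic sensitivity (1/(mm min)).
#' @param gamma_mean,gamma_sd proprioceptive sensitivity (1/min).
#' @param v_mean,v_sd growth speed (mm/min).
#' @param Lgz growing-zone length (mm); `NULL` = the individual's initial
#'   length (whole shoot grows).
#' @param Gt growth-elasto-gravity parameter used to set the mass density.
#' @param frame_times sampling times (min).
#' @param n_points points digitized per frame (`interval` overrides).
#' @param interval point spacing (mm) or `NULL`.
#' @param sigma isotropic Gaussian positional noise (mm).
#' @param n_vertices rod discretization; `NULL` = about one vertex per mm.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_individuals = 16, genotype = "WT",
                        L0_mean = 45, L0_sd = 3, L0_range = c(40, 80),
                        base_angle_sd = 0.087,
                        beta_mean = 1e-3, beta_sd = 1e-4,
                        gamma_mean = 0.02, gamma_sd = 0.002,
                        v_mean = 0.02, v_sd = 0.002,
                        Lgz = NULL, Gt = 1,
                        frame_times = seq(0, 140, by = 1),
                        n_points = 20, interval = NULL, sigma = 0.1,
                        n_vertices = NULL) {
  spec <- list(n_individuals = as.integer(n_individuals), genotype = genotype,
               L0_mean = L0_mean, L0_sd = L0_sd, L0_range = L0_range,
               base_angle_sd = base_angle_sd,
               beta_mean = beta_mean, beta_sd = beta_sd,
               gamma_mean = gamma_mean, gamma_sd = gamma_sd,
               v_mean = v_mean, v_sd = v_sd,
               Lgz = Lgz, Gt = Gt, frame_times = frame_times,
               n_points = n_points, interval = interval, sigma = sigma,
               n_vertices = n_vertices)
  stopifnot(spec$n_individuals >= 1, sigma >= 0, Gt > 0,
            all(diff(frame_times) > 0))
  class(spec) <- "cohort_spec"
  spec
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- rnorm(1, mean, sd)
      if (v >= lo && v <= hi) break
    }
    out[i] <- v
  }
  out
}

#' Draw one individual's parameters from a cohort spec
#'
#' @param spec a [cohort_spec()].
#' @return A list of drawn parameters (uses the current RNG state).
#' @export
draw_individual <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  L0 <- rtrunc_norm(1, spec$L0_mean, spec$L0_sd,
                    spec$L0_range[1], spec$L0_range[2])
  list(L0 = L0,
       base_angle = rnorm(1, 0, spec$base_angle_sd),
       beta = max(rnorm(1, spec$beta_mean, spec$beta_sd), 1e-6),
       gamma = max(rnorm(1, spec$gamma_mean, spec$gamma_sd), 1e-4),
       v = max(rnorm(1, spec$v_mean, spec$v_sd), 0),
       Lgz = if (is.null(spec$Lgz)) L0 else spec$Lgz)
}

#' Build the initial rod of one synthetic individual
#'
#' A straight rod of the drawn length, clamped at the drawn base angle and
#' pre-equilibrated under gravity (so the run starts at mechanical
#' equilibrium, as the observed plants do).
#'
#' @param L0 initial length (mm).
#' @param base_angle base tangent angle from horizontal (rad).
#' @param mp a [mech_params()].
#' @param n_vertices number of vertices; default about one per mm.
#' @return An equilibrated [rod_state()].
#' @export
make_initial_rod <- function(L0, base_angle = 0, mp = mech_params(),
                             n_vertices = NULL) {
  if (is.null(n_vertices)) n_vertices <- max(round(L0) + 1, 11)
  rod <- straight_rod(L0, n = n_vertices, theta = base_angle)
  equilibrate(rod, mp)$state
}

# points along the smooth curve through a rod's vertices, equally spaced in
# arc length (base point always included)
rod_curve_points <- function(state, n_points = 20, interval = NULL) {
  sm <- centerline_sample(state$t, state$x)
  fit <- fit_centerline(sm, smoothing = 0)
  s <- if (!is.null(interval)) {
    unique(c(seq(0, fit$L, by = interval), fit$L))
  } else {
    seq(0, fit$L, length.out = n_points)
  }
  uu <- fit$u_of_s(s)
  cbind(fit$ex(uu), fit$ey(uu))
}

#' Sample a simulated trajectory like a digitized time-lapse
#'
#' For each requested frame, points are placed at equal arc-length spacing
#' along the smooth curve through the rod's vertices and perturbed by
#' isotropic Gaussian noise of sd `sigma` (digitization error; no temporal
#' correlation). The base point is always included.
#'
#' @param traj a `rod_trajectory`.
#' @param frame_times times to sample (min); must exist in the trajectory.
#' @param n_points,interval,sigma sampling parameters (see [cohort_spec()]).
#' @param id,genotype labels for the resulting series.
#' @return A [centerline_series()].
#' @export
sample_series <- function(traj, frame_times = NULL, n_points = 20,
                          interval = NULL, sigma = 0.1,
                          id = "sim", genotype = "model") {
  stopifnot(inherits(traj, "rod_trajectory"))
  if (is.null(frame_times)) frame_times <- traj$times
  idx <- match(frame_times, traj$times)
  if (anyNA(idx)) {
    stop("frame times not in trajectory: ",
         paste(frame_times[is.na(idx)], collapse = ", "))
  }
  samples <- lapply(idx, function(k) {
    st <- traj$frames[[k]]$state
    xy <- rod_curve_points(st, n_points = n_points, interval = interval)
    if (sigma > 0) xy <- xy + matrix(rnorm(length(xy), 0, sigma), ncol = 2)
    centerline_sample(traj$times[k], xy)
  })
  centerline_series(id, genotype, samples)
}

#' Simulate one synthetic individual
#'
#' @param ind parameter draw from [draw_individual()].
#' @param spec the [cohort_spec()].
#' @param mp_template a [mech_params()] supplying `ks`, `B`, `g` and
#'   relaxation settings; the density is set from `spec$Gt`.
#' @param id,genotype labels.
#' @return List with the sampled `series`, the `trajectory` and the ground
#'   `truth` row.
#' @export
simulate_individual <- function(ind, spec, mp_template = mech_params(),
                                id = "ind", genotype = spec$genotype) {
  rho <- rho_for_Gt(spec$Gt, ind$Lgz, B = mp_template$B, g = mp_template$g)
  mp <- mp_template
  mp$rho <- rho
  gp <- growth_params(v = ind$v, Lgz = ind$Lgz, beta = ind$beta,
                      gamma = ind$gamma, dt = 1,
                      t_end = max(spec$frame_times))
  rod <- make_initial_rod(ind$L0, ind$base_angle, mp,
                          n_vertices = spec$n_vertices)
  traj <- simulate_shoot(rod, mp, gp, pre_equilibrate = FALSE)
  series <- sample_series(traj, frame_times = spec$frame_times,
                          n_points = spec$n_points, interval = spec$interval,
                          sigma = spec$sigma, id = id, genotype = genotype)
  gr <- dimensionless_groups(gp, mp)
  truth <- data.frame(individual_id = id, genotype = genotype,
                      beta = ind$beta, gamma = ind$gamma, v = ind$v,
                      L0 = ind$L0, Lgz = ind$Lgz, rho = rho,
                      base_angle = ind$base_angle, S = gr$S, Gt = gr$Gt)
  list(series = series, trajectory = traj, truth = truth)
}

#' Generate paired synthetic cohorts with ground truth
#'
#' Simulates and samples `wt_spec$n_individuals` wild-type-like and
#' `mut_spec$n_individuals` mutant-like shoots (defaults 16 and 15; the
#' mutant spec halves `beta` and keeps everything else). Fully deterministic
#' under a fixed seed.
#'
#' @param wt_spec a [cohort_spec()] for the wild-type-like cohort.
#' @param mut_spec a [cohort_spec()]; default: `wt_spec` with `beta` halved,
#'   15 individuals, genotype `"mutant"`.
#' @param mp_template shared [mech_params()] template.
#' @param seed RNG seed.
#' @param keep_trajectories keep the simulated trajectories (memory heavier).
#' @return A list with `series` (list of [centerline_series()]), `truth`
#'   (data frame) and optionally `trajectories`.
#' @export
make_cohorts <- function(wt_spec = cohort_spec(),
                         mut_spec = NULL,
                         mp_template = mech_params(),
                         seed = 1, keep_trajectories = FALSE) {
  if (is.null(mut_spec)) {
    mut_spec <- wt_spec
    mut_spec$n_individuals <- 15L
    mut_spec$genotype <- "mutant"
    mut_spec$beta_mean <- wt_spec$beta_mean / 2
    mut_spec$beta_sd <- wt_spec$beta_sd / 2
  }
  set.seed(seed)
  series <- list(); truth <- list(); trajs <- list()
  for (spec in list(wt_spec, mut_spec)) {
    for (i in seq_len(spec$n_individuals)) {
      id <- sprintf("%s_%02d", spec$genotype, i)
      ind <- draw_individual(spec)
      sim <- simulate_individual(ind, spec, mp_template, id = id)
      series[[id]] <- sim$series
      truth[[id]] <- sim$truth
      if (keep_trajectories) trajs[[id]] <- sim$trajectory
    }
  }
  out <- list(series = unname(series), truth = do.call(rbind, truth))
  rownames(out$truth) <- NULL
  if (keep_trajectories) out$trajectories <- trajs
  out
}
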