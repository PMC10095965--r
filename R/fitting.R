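#' Deviation between model and data morphospace points
#'
#' Scale-free squared relative deviation,
#' `D = w_k ((k_model - k_data)/k_data)^2 + w_e ((e_model - e_data)/e_data)^2`,
#' zero iff the coordinates match.
#'
#' @param model,data [morphospace_point()] objects (or lists with
#'   `kappa_max` and `extension_ratio`).
#' @param weights named vector `c(kappa = , eps = )`, non-negative, not both
#'   zero.
#' @return The deviation (numeric scalar).
#' @export
deviation <- function(model, data, weights = c(kappa = 1, eps = 1)) {
  if (data$kappa_max <= 0 || data$extension_ratio <= 0) {
    stop("data morphospace coordinates must be positive")
  }
  stopifnot(all(weights >= 0), any(weights > 0))
  wk <- weights[["kappa"]]; we <- weights[["eps"]]
  wk * ((model$kappa_max - data$kappa_max) / data$kappa_max)^2 +
    we * ((model$extension_ratio - data$extension_ratio) /
            data$extension_ratio)^2
}

#' Configuration of the (S, Gt) morphospace grid search
#'
#' The search varies the growth-sensitivity parameter `S` through the
#' gravitropic sensitivity `beta = S * gamma / Lgz` (with the proprioceptive
#' sensitivity `gamma` held at a representative fixed value) and the
#' growth-elasto-gravity parameter `Gt` through the mass density
#' `rho = B / (g (Gt Lgz)^3)`. The growing zone is fixed to the initial
#' length `L0`. Default grids span one decade around `S = 1`, `Gt = 1` with
#' 10 log-spaced nodes each.
#'
#' @param S_grid,Gt_grid strictly increasing positive grids.
#' @param gamma fixed proprioceptive sensitivity (1/min).
#' @param L0 initial (and growing-zone) length of the model shoot (mm).
#' @param v growth speed (mm/min).
#' @param n_vertices rod discretization of the model shoot.
#' @param t_end,dt simulation window and step (min).
#' @param n_points noise-free sampling density used to measure the model
#'   morphospace point (kept equal to the data digitization density so
#'   spline attenuation cancels in the comparison).
#' @param mp_template a [mech_params()] supplying `ks`, `B`, `g` and
#'   relaxation settings.
#' @param weights deviation weights, see [deviation()].
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(S_grid = 10^seq(-0.5, 0.5, length.out = 10),
                       Gt_grid = 10^seq(-0.5, 0.5, length.out = 10),
                       gamma = 0.02, L0 = 40, v = 0.02,
                       n_vertices = 41, t_end = 140, dt = 1,
                       n_points = 20,
                       mp_template = mech_params(),
                       weights = c(kappa = 1, eps = 1)) {
  stopifnot(length(S_grid) >= 1, length(Gt_grid) >= 1,
            all(S_grid > 0), all(Gt_grid > 0),
            !is.unsorted(S_grid, strictly = TRUE),
            !is.unsorted(Gt_grid, strictly = TRUE),
            gamma > 0, L0 > 0, v >= 0, n_vertices >= 5)
  cfg <- list(S_grid = S_grid, Gt_grid = Gt_grid, gamma = gamma, L0 = L0,
              Lgz = L0, v = v, n_vertices = as.integer(n_vertices),
              t_end = t_end, dt = dt, n_points = n_points,
              mp_template = mp_template, weights = weights)
  class(cfg) <- "fit_config"
  cfg
}

#' Model morphospace table over the (S, Gt) grid
#'
#' Runs one simulation per grid node (straight horizontal rod of length
#' `L0`, growing zone the whole shoot) and measures its morphospace point
#' through the same centerline-analysis pipeline used on data (noise-free
#' sampling at the data's digitization density). The table is the expensive
#' part of the search and can be shared across every fit that uses the same
#' configuration.
#'
#' @param cfg a [fit_config()].
#' @param verbose print progress.
#' @return A data frame with one row per node: `S`, `Gt`, `beta`, `rho`,
#'   `extension_ratio`, `kappa_max`, `ok`, `message`.
#' @export
morphospace_table <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "fit_config"))
  nodes <- expand.grid(S = cfg$S_grid, Gt = cfg$Gt_grid,
                       KEEP.OUT.ATTRS = FALSE)
  nodes$beta <- beta_for_S(nodes$S, cfg$gamma, cfg$Lgz)
  nodes$rho <- rho_for_Gt(nodes$Gt, cfg$Lgz, B = cfg$mp_template$B,
                          g = cfg$mp_template$g)
  nodes$extension_ratio <- NA_real_
  nodes$kappa_max <- NA_real_
  nodes$ok <- FALSE
  nodes$message <- ""
  for (i in seq_len(nrow(nodes))) {
    res <- tryCatch({
      pt <- model_morphospace_point(nodes$S[i], nodes$Gt[i], cfg)
      nodes$extension_ratio[i] <- pt$extension_ratio
      nodes$kappa_max[i] <- pt$kappa_max
      nodes$ok[i] <- TRUE
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) {
      nodes$message[i] <- res
      warning(sprintf("grid node (S = %.3g, Gt = %.3g) failed: %s",
                      nodes$S[i], nodes$Gt[i], res))
    }
    if (verbose) {
      message(sprintf("node %d/%d: S = %.3g, Gt = %.3g -> kmax = %.4g",
                      i, nrow(nodes), nodes$S[i], nodes$Gt[i],
                      nodes$kappa_max[i]))
    }
  }
  nodes
}

# simulate the model shoot at one (S, Gt) node and return its morphospace
# point; also returns the trajectory when keep_trajectory
model_morphospace_point <- function(S, Gt, cfg, keep_trajectory = FALSE) {
  mp <- cfg$mp_template
  mp$rho <- rho_for_Gt(Gt, cfg$Lgz, B = mp$B, g = mp$g)
  gp <- growth_params(v = cfg$v, Lgz = cfg$Lgz,
                      beta = beta_for_S(S, cfg$gamma, cfg$Lgz),
                      gamma = cfg$gamma, dt = cfg$dt, t_end = cfg$t_end)
  rod <- straight_rod(cfg$L0, n = cfg$n_vertices)
  traj <- simulate_shoot(rod, mp, gp)
  series <- sample_series(traj, frame_times = c(0, cfg$t_end),
                          n_points = cfg$n_points, sigma = 0,
                          id = "model", genotype = "model")
  pt <- morphospace_point(series, t_end = cfg$t_end)
  if (keep_trajectory) attr(pt, "trajectory") <- traj
  pt
}

#' Exhaustive grid search for the best-fitting (S, Gt)
#'
#' Evaluates the deviation [deviation()] between the data morphospace point
#' and the model point at every grid node and returns the arg-min, with a
#' deterministic tie-break (smallest `S`, then smallest `Gt`). Failed nodes
#' are excluded with a warning. A warning is also raised when the optimum
#' sits on the grid boundary.
#'
#' @param data a [morphospace_point()] measured from data.
#' @param cfg a [fit_config()].
#' @param table optionally a precomputed [morphospace_table()] for `cfg`
#'   (reused across individuals of a cohort).
#' @return An object of class `fit_result`: best `S`, `Gt`, underlying
#'   `beta`, `gamma`, `rho`, `ls`, `D_min`, the full deviation grid
#'   `D` (S x Gt), the model point at the optimum and the node table.
#' @export
grid_search <- function(data, cfg, table = NULL) {
  stopifnot(inherits(cfg, "fit_config"))
  if (is.null(table)) table <- morphospace_table(cfg)
  D <- rep(NA_real_, nrow(table))
  for (i in seq_len(nrow(table))) {
    if (!table$ok[i]) next
    D[i] <- deviation(list(kappa_max = table$kappa_max[i],
                           extension_ratio = table$extension_ratio[i]),
                      data, cfg$weights)
  }
  if (all(is.na(D))) stop("all grid nodes failed")
  ord <- order(D, table$S, table$Gt, na.last = TRUE)
  best <- ord[1]
  iS <- match(table$S[best], cfg$S_grid)
  iG <- match(table$Gt[best], cfg$Gt_grid)
  on_boundary <- iS %in% c(1, length(cfg$S_grid)) ||
    iG %in% c(1, length(cfg$Gt_grid))
  if (on_boundary) {
    warning("grid-search optimum lies on the grid boundary; widen the grid")
  }
  Dmat <- matrix(D, nrow = length(cfg$S_grid), ncol = length(cfg$Gt_grid),
                 dimnames = list(S = signif(cfg$S_grid, 4),
                                 Gt = signif(cfg$Gt_grid, 4)))
  res <- list(S = table$S[best], Gt = table$Gt[best],
              beta = table$beta[best], gamma = cfg$gamma,
              rho = table$rho[best], ls = cfg$gamma / table$beta[best],
              D_min = D[best], D = Dmat,
              index = c(S = iS, Gt = iG), on_boundary = on_boundary,
              model = list(kappa_max = table$kappa_max[best],
                           extension_ratio = table$extension_ratio[best]),
              data = list(kappa_max = data$kappa_max,
                          extension_ratio = data$extension_ratio),
              table = table, cfg = cfg)
  class(res) <- "fit_result"
  res
}

#' Fit a cohort of centerline series
#'
#' Per-individual grid searches (sharing one model table) plus a fit to the
#' cohort-mean morphospace point (the "averaged model" of the cohort).
#'
#' @param series_list list of [centerline_series()].
#' @param cfg a [fit_config()].
#' @param table optional precomputed [morphospace_table()].
#' @param t_end morphospace evaluation time.
#' @return A list with `individual` (list of `fit_result`), `points`
#'   (data frame of per-individual morphospace coordinates), `average`
#'   (fit to the cohort mean) and the shared `table`.
#' @export
fit_cohort <- function(series_list, cfg, table = NULL, t_end = cfg$t_end) {
  stopifnot(length(series_list) >= 1)
  if (is.null(table)) table <- morphospace_table(cfg)
  pts <- lapply(series_list, morphospace_point, t_end = t_end)
  fits <- lapply(pts, grid_search, cfg = cfg, table = table)
  names(fits) <- vapply(series_list, function(s) as.character(s$id), "")
  df <- data.frame(
    individual_id = names(fits),
    extension_ratio = vapply(pts, function(p) p$extension_ratio, 0),
    kappa_max = vapply(pts, function(p) p$kappa_max, 0),
    S = vapply(fits, function(f) f$S, 0),
    Gt = vapply(fits, function(f) f$Gt, 0),
    beta = vapply(fits, function(f) f$beta, 0),
    row.names = NULL)
  avg_pt <- list(kappa_max = mean(df$kappa_max),
                 extension_ratio = mean(df$extension_ratio))
  avg <- grid_search(avg_pt, cfg, table = table)
  list(individual = fits, points = df, average = avg, table = table)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: S = %.4g, Gt = %.4g (D_min = %.4g)\n",
              x$S, x$Gt, x$D_min))
  cat(sprintf("  beta = %.4g /(mm min), gamma = %.4g /min, rho = %.4g\n",
              x$beta, x$gamma, x$rho))
  cat(sprintf("  model (eps, kmax) = (%.4f, %.4g); data = (%.4f, %.4g)\n",
              x$model$extension_ratio, x$model$kappa_max,
              x$data$extension_ratio, x$data$kappa_max))
  if (x$on_boundary) cat("  note: optimum on grid boundary\n")
  invisible(x)
}
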