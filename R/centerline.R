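#' Sampled centerline of one frame
#'
#' @param t time stamp (min).
#' @param xy ordered n x 2 matrix of points (mm), base first.
#' @return An object of class `centerline_sample`.
#' @export
centerline_sample <- function(t, xy) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2 || nrow(xy) < 4) {
    stop("a centerline sample needs at least 4 (x, y) points")
  }
  d <- sqrt(rowSums((xy[-1, , drop = FALSE] - xy[-nrow(xy), , drop = FALSE])^2))
  if (any(d < 1e-9)) stop("duplicate consecutive points in centerline sample")
  s <- list(t = t, xy = unname(xy))
  class(s) <- "centerline_sample"
  s
}

#' Time series of sampled centerlines for one individual
#'
#' @param id individual identifier.
#' @param genotype genotype label (e.g. `"WT"`, `"mutant"`).
#' @param samples list of [centerline_sample()] at strictly increasing times.
#' @return An object of class `centerline_series`.
#' @export
centerline_series <- function(id, genotype, samples) {
  times <- vapply(samples, function(s) s$t, 0)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("centerline samples must have strictly increasing times")
  }
  s <- list(id = id, genotype = genotype, samples = samples, times = times)
  class(s) <- "centerline_series"
  s
}

#' Fit a smooth curve through a sampled centerline
#'
#' Cubic-spline fit of `x(u)`, `y(u)` against the chord-length parameter `u`,
#' then reparameterized by arc length via numerical quadrature (refined to
#' relative tolerance 1e-5). The default is a penalized spline with a fixed
#' effective dimension `df = min(5, n - 2)`: shoots are gently curved, so a
#' moderate, density-independent stiffness both suppresses digitization
#' noise and keeps the fit invariant under resampling (data-driven GCV
#' penalties proved noisier on ~20-point samples). `smoothing = 0` forces
#' pure interpolation; an integer `>= 2` sets the spline df directly.
#'
#' @param sample a [centerline_sample()].
#' @param smoothing `NULL` for the default penalty, `0` for pure
#'   interpolation, or a spline `df >= 2`.
#' @return An object of class `centerline_fit` with the total length `L`,
#'   derivative evaluators and the arc-length table.
#' @export
fit_centerline <- function(sample, smoothing = NULL) {
  stopifnot(inherits(sample, "centerline_sample"))
  xy <- sample$xy
  n <- nrow(xy)
  u <- c(0, cumsum(sqrt(rowSums((xy[-1, , drop = FALSE] -
                                   xy[-n, , drop = FALSE])^2))))
  df_val <- if (is.null(smoothing)) min(5, n - 2) else smoothing
  if (identical(df_val, 0) || n < 8) {
    fx <- splinefun(u, xy[, 1], method = "fmm")
    fy <- splinefun(u, xy[, 2], method = "fmm")
    dfun <- function(f) function(uu, d = 0) f(uu, deriv = d)
    ex <- dfun(fx); ey <- dfun(fy)
  } else {
    stopifnot(df_val >= 2)
    sx <- smooth.spline(u, xy[, 1], df = df_val)
    sy <- smooth.spline(u, xy[, 2], df = df_val)
    dfun <- function(f) function(uu, d = 0) predict(f, uu, deriv = d)$y
    ex <- dfun(sx); ey <- dfun(sy)
  }
  # arc length by composite trapezoid on a refined grid
  m <- 512
  repeat {
    ug <- seq(0, max(u), length.out = m + 1)
    sp <- sqrt(ex(ug, 1)^2 + ey(ug, 1)^2)
    h <- diff(ug)
    seg <- h * (sp[-1] + sp[-length(sp)]) / 2
    L <- sum(seg)
    if (m >= 4096) break
    m2 <- m * 2
    ug2 <- seq(0, max(u), length.out = m2 + 1)
    sp2 <- sqrt(ex(ug2, 1)^2 + ey(ug2, 1)^2)
    L2 <- sum(diff(ug2) * (sp2[-1] + sp2[-length(sp2)]) / 2)
    if (abs(L2 - L) <= 1e-5 * L2) { m <- m2; ug <- ug2; sp <- sp2
      seg <- diff(ug) * (sp[-1] + sp[-length(sp)]) / 2; L <- L2; break }
    m <- m2
  }
  s_of_u <- approxfun(ug, c(0, cumsum(seg)), rule = 2)
  u_of_s <- approxfun(c(0, cumsum(seg)), ug, rule = 2)
  fit <- list(t = sample$t, L = L, u_max = max(u),
              ex = ex, ey = ey, s_of_u = s_of_u, u_of_s = u_of_s)
  class(fit) <- "centerline_fit"
  fit
}

#' Signed curvature along a fitted centerline
#'
#' Evaluates `kappa = (x' y'' - y' x'') / (x'^2 + y'^2)^(3/2)` (invariant
#' under reparameterization) on a uniform arc-length grid, optionally
#' smoothed by a centered moving average of `window` samples. Positive
#' curvature is counter-clockwise, matching the rod simulator's convention.
#' One `window` of samples at each end is regarded as edge-affected
#' (attribute `edge_exclude`) and is excluded from maximum-curvature
#' summaries.
#'
#' @param fit a [centerline_fit()].
#' @param ds arc-length grid spacing (mm), default 0.5.
#' @param window moving-average width in samples (odd; default 7). Use 1 for
#'   no smoothing.
#' @return A data frame with columns `s`, `kappa`, `kappa_raw`.
#' @export
curvature_profile <- function(fit, ds = 0.5, window = 7L) {
  stopifnot(inherits(fit, "centerline_fit"), ds > 0, window >= 1)
  s <- seq(0, fit$L, by = ds)
  uu <- fit$u_of_s(s)
  x1 <- fit$ex(uu, 1); y1 <- fit$ey(uu, 1)
  x2 <- fit$ex(uu, 2); y2 <- fit$ey(uu, 2)
  kraw <- (x1 * y2 - y1 * x2) / (x1^2 + y1^2)^1.5
  k <- if (window > 1) {
    w <- as.integer(window)
    kf <- stats::filter(kraw, rep(1 / w, w), sides = 2)
    as.numeric(ifelse(is.na(kf), kraw, kf))
  } else kraw
  out <- data.frame(s = s, kappa = k, kappa_raw = kraw)
  attr(out, "edge_exclude") <- as.integer(window)
  out
}

#' Curvature kymograph of a centerline series
#'
#' Stacks per-frame curvature profiles on a shared arc-length grid; cells
#' beyond the current length of the shoot are `NA` (ragged mask).
#'
#' @param series a [centerline_series()].
#' @param ds grid spacing (mm).
#' @param window moving-average width passed to [curvature_profile()].
#' @param smoothing spline smoothing passed to [fit_centerline()].
#' @return An object of class `kymograph`: list with `times`, `s`, `kappa`
#'   (time x s matrix), `L` (lengths per frame).
#' @export
kymograph <- function(series, ds = 0.5, window = 7L, smoothing = NULL) {
  stopifnot(inherits(series, "centerline_series"))
  fits <- lapply(series$samples, fit_centerline, smoothing = smoothing)
  L <- vapply(fits, function(f) f$L, 0)
  s <- seq(0, max(L), by = ds)
  mat <- matrix(NA_real_, nrow = length(fits), ncol = length(s))
  for (i in seq_along(fits)) {
    prof <- curvature_profile(fits[[i]], ds = ds, window = window)
    mat[i, seq_len(nrow(prof))] <- prof$kappa
  }
  k <- list(times = series$times, s = s, kappa = mat, L = L,
            id = series$id, genotype = series$genotype)
  class(k) <- "kymograph"
  k
}

#' Morphospace coordinates of a centerline series
#'
#' The morphospace summarizes a bending event by two numbers: the extension
#' ratio `eps = L(t_end) / L(t_start)` (a shoot-strain proxy; set
#' `mode = "strain"` for `(L_end - L_start)/L_start`) and the maximum
#' absolute curvature along the shoot at `t_end` after default smoothing,
#' excluding one smoothing window at each end.
#'
#' @param series a [centerline_series()].
#' @param t_end evaluation time (min); default the last frame.
#' @param ds,window,smoothing passed to the curvature machinery.
#' @param mode `"ratio"` (default) or `"strain"`.
#' @return An object of class `morphospace_point`: list with
#'   `extension_ratio`, `kappa_max`, `L_start`, `L_end`, `t_end`.
#' @export
morphospace_point <- function(series, t_end = NULL, ds = 0.5, window = 7L,
                              smoothing = NULL, mode = c("ratio", "strain")) {
  stopifnot(inherits(series, "centerline_series"))
  mode <- match.arg(mode)
  if (is.null(t_end)) t_end <- max(series$times)
  iend <- which(abs(series$times - t_end) < 1e-9)
  if (length(iend) != 1) {
    stop(sprintf("series has no frame at t_end = %g min", t_end))
  }
  f0 <- fit_centerline(series$samples[[1]], smoothing = smoothing)
  f1 <- fit_centerline(series$samples[[iend]], smoothing = smoothing)
  prof <- curvature_profile(f1, ds = ds, window = window)
  w <- attr(prof, "edge_exclude")
  keep <- seq_len(nrow(prof))
  if (nrow(prof) > 2 * w) keep <- (w + 1):(nrow(prof) - w)
  kmax <- max(abs(prof$kappa[keep]))
  eps <- if (mode == "ratio") f1$L / f0$L else (f1$L - f0$L) / f0$L
  p <- list(extension_ratio = eps, kappa_max = kmax,
            L_start = f0$L, L_end = f1$L, t_end = t_end, mode = mode)
  class(p) <- "morphospace_point"
  p
}

#' Welch comparison of two cohorts in morphospace
#'
#' Two-sided Welch t-tests on maximum curvature and on extension ratio
#' between two groups of [morphospace_point()]s. Exact ties across both
#' groups give `t = 0, p = 1`.
#'
#' @param groupA,groupB lists of [morphospace_point()] (each of length >= 3).
#' @return A data frame with one row per metric: `t`, `p`, group means.
#' @export
group_compare <- function(groupA, groupB) {
  stopifnot(length(groupA) >= 3, length(groupB) >= 3)
  get <- function(g, f) vapply(g, function(p) p[[f]], 0)
  one <- function(a, b) {
    if (all(c(a, b) == c(a, b)[1])) return(c(t = 0, p = 1))
    if (sd(a) == 0 && sd(b) == 0) { # constant but different
      return(c(t = sign(mean(a) - mean(b)) * Inf, p = 0))
    }
    tt <- t.test(a, b)
    c(t = unname(tt$statistic), p = tt$p.value)
  }
  ka <- get(groupA, "kappa_max"); kb <- get(groupB, "kappa_max")
  ea <- get(groupA, "extension_ratio"); eb <- get(groupB, "extension_ratio")
  rk <- one(ka, kb); re <- one(ea, eb)
  data.frame(metric = c("kappa_max", "extension_ratio"),
             t = c(rk["t"], re["t"]), p = c(rk["p"], re["p"]),
             mean_A = c(mean(ka), mean(ea)), mean_B = c(mean(kb), mean(eb)),
             row.names = NULL)
}

#' Write / read centerline series as CSV
#'
#' Long format with columns
#' `individual_id, genotype, time_min, point_index, x_mm, y_mm`.
#'
#' @param series a [centerline_series()] or list of them.
#' @param path CSV path.
#' @export
write_centerline_csv <- function(series, path) {
  if (inherits(series, "centerline_series")) series <- list(series)
  rows <- lapply(series, function(sr) {
    do.call(rbind, lapply(sr$samples, function(sm) {
      data.frame(individual_id = sr$id, genotype = sr$genotype,
                 time_min = sm$t, point_index = seq_len(nrow(sm$xy)),
                 x_mm = sm$xy[, 1], y_mm = sm$xy[, 2])
    }))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centerline_csv
#' @return `read_centerline_csv()` returns a list of [centerline_series()].
#' @export
read_centerline_csv <- function(path) {
  df <- read.csv(path)
  need <- c("individual_id", "genotype", "time_min", "point_index",
            "x_mm", "y_mm")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("malformed centerline CSV: missing columns ",
         paste(miss, collapse = ", "))
  }
  out <- lapply(split(df, df$individual_id), function(d) {
    times <- sort(unique(d$time_min))
    samples <- lapply(times, function(t) {
      dd <- d[d$time_min == t, ]
      dd <- dd[order(dd$point_index), ]
      centerline_sample(t, cbind(dd$x_mm, dd$y_mm))
    })
    centerline_series(d$individual_id[1], d$genotype[1], samples)
  })
  unname(out)
}

#' Write a kymograph as TSV
#'
#' Header row carries the arc-length grid; one row per frame, first column
#' the time stamp.
#'
#' @param kymo a [kymograph()].
#' @param path TSV path.
#' @export
write_kymograph_tsv <- function(kymo, path) {
  stopifnot(inherits(kymo, "kymograph"))
  df <- data.frame(time_min = kymo$times, kymo$kappa, check.names = FALSE)
  names(df) <- c("time_min", sprintf("s_%g", kymo$s))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.morphospace_point <- function(x, ...) {
  cat(sprintf("morphospace point at t = %g min: extension ratio %.4f, max |kappa| %.4g /mm\n",
              x$t_end, x$extension_ratio, x$kappa_max))
  invisible(x)
}
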