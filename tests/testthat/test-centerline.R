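test_that("centerline samples validate their inputs", {
  expect_error(centerline_sample(0, rbind(c(0, 0), c(1, 0), c(2, 0))),
               "at least 4")
  expect_error(centerline_sample(0, rbind(c(0, 0), c(1, 0), c(1, 0), c(2, 0))),
               "duplicate")
  expect_error(centerline_series("a", "WT", list(
    centerline_sample(10, cbind(0:4, 0)),
    centerline_sample(5, cbind(0:4, 0)))), "increasing")
})

test_that("arc length: collinear points and semicircle", {
  xy <- cbind(seq(0, 12, length.out = 10), 0.5 * seq(0, 12, length.out = 10))
  f <- fit_centerline(centerline_sample(0, xy), smoothing = 0)
  expect_equal(f$L, sqrt(12^2 + 6^2), tolerance = 1e-6)

  th <- seq(0, pi, length.out = 20)
  f2 <- fit_centerline(centerline_sample(0, cbind(10 * cos(th),
                                                  10 * sin(th))),
                       smoothing = 0)
  expect_lt(abs(f2$L - 10 * pi) / (10 * pi), 0.005)
})

test_that("curvature profile: line, circle, and noisy circle (MC)", {
  xy <- cbind(seq(0, 20, length.out = 15), 1 + 0.3 * seq(0, 20, length.out = 15))
  pr <- curvature_profile(fit_centerline(centerline_sample(0, xy)))
  expect_lt(max(abs(pr$kappa)), 1e-8)

  th <- seq(0, pi, length.out = 25)
  pr2 <- curvature_profile(fit_centerline(
    centerline_sample(0, cbind(10 * cos(th), 10 * sin(th))),
    smoothing = 0))
  w <- attr(pr2, "edge_exclude")
  inner <- pr2$kappa[(w + 1):(nrow(pr2) - w)]
  expect_true(all(abs(abs(inner) - 0.1) < 0.001))
  # sign: counter-clockwise arc has positive curvature
  expect_true(all(inner > 0))

  # Monte-Carlo: n = 20 points, sigma = 0.05 mm digitization noise
  set.seed(101)
  errs <- replicate(200, {
    xy <- cbind(10 * cos(th[seq(1, 25, length.out = 20)]),
                10 * sin(th[seq(1, 25, length.out = 20)])) +
      matrix(rnorm(40, 0, 0.05), ncol = 2)
    prn <- curvature_profile(fit_centerline(centerline_sample(0, xy)))
    kk <- prn$kappa[(w + 1):(nrow(prn) - w)]
    median(abs(abs(kk) - 0.1))
  })
  expect_lt(median(errs), 0.01)
})

test_that("curvature is invariant under resampling density", {
  shape <- function(t) cbind(t, 5 * sin(t / 8))
  p1 <- curvature_profile(fit_centerline(
    centerline_sample(0, shape(seq(0, 30, length.out = 41)))))
  p2 <- curvature_profile(fit_centerline(
    centerline_sample(0, shape(seq(0, 30, length.out = 21)))))
  n <- min(nrow(p1), nrow(p2))
  i <- 8:(n - 8)
  rel <- sqrt(mean((p1$kappa[i] - p2$kappa[i])^2)) /
    sqrt(mean(p1$kappa[i]^2))
  expect_lt(rel, 0.01)
})

test_that("kymograph of identical straight frames is zero with ragged mask", {
  xy <- cbind(seq(0, 30, length.out = 20), 0)
  ser <- centerline_series("s", "WT", lapply(0:3 * 10, centerline_sample,
                                             xy = xy))
  ky <- kymograph(ser)
  expect_true(all(abs(ky$kappa) < 1e-8, na.rm = TRUE))
  expect_equal(dim(ky$kappa), c(4, length(ky$s)))
  expect_equal(ky$L, rep(30, 4), tolerance = 1e-4)
})

test_that("kymograph round-trips the simulator's curvature field", {
  mp <- mech_params(rho = 1e-300) # negligible gravity
  gp <- growth_params(t_end = 60)
  traj <- simulate_shoot(straight_rod(40, 41), mp, gp)
  ser <- sample_series(traj, frame_times = seq(0, 60, by = 10),
                       n_points = 20, sigma = 0)
  ky <- kymograph(ser, smoothing = 0) # noise-free: interpolate
  diffs <- c()
  for (j in seq_along(ky$times)) {
    g <- traj$frames[[which(traj$times == ky$times[j])]]$geom
    mod <- approx(g$arc_length[2:40], g$curvatures, xout = ky$s)$y
    ok <- !is.na(mod) & !is.na(ky$kappa[j, ]) & ky$s > 2 & ky$s < g$L - 2
    diffs <- c(diffs, ky$kappa[j, ok] - mod[ok])
  }
  expect_lt(sqrt(mean(diffs^2)) / max(abs(ky$kappa), na.rm = TRUE), 0.05)
})

test_that("morphospace point: trivial cases and simulator round trip", {
  xy <- cbind(seq(0, 40, length.out = 20), 0)
  ser <- centerline_series("s", "WT", list(centerline_sample(0, xy),
                                           centerline_sample(140, xy)))
  pt <- morphospace_point(ser)
  expect_equal(pt$extension_ratio, 1, tolerance = 1e-9)
  expect_lt(pt$kappa_max, 1e-8)
  # strain variant
  expect_equal(morphospace_point(ser, mode = "strain")$extension_ratio, 0,
               tolerance = 1e-9)
  expect_error(morphospace_point(ser, t_end = 70), "no frame")

  # L 40 -> 44 gives extension ratio 1.1
  xy2 <- cbind(seq(0, 44, length.out = 20), 0)
  ser2 <- centerline_series("s", "WT", list(centerline_sample(0, xy),
                                            centerline_sample(140, xy2)))
  expect_equal(morphospace_point(ser2)$extension_ratio, 1.1,
               tolerance = 1e-6)
})

test_that("group comparison: ties, degenerate variance and Welch vs permutation", {
  mk <- function(k, e) list(kappa_max = k, extension_ratio = e)
  gA <- lapply(c(1, 1, 1), mk, e = 2)
  out <- group_compare(gA, gA)
  expect_equal(out$t, c(0, 0))
  expect_equal(out$p, c(1, 1))
  # constant but different groups
  gB <- lapply(c(2, 2, 2), mk, e = 2)
  out2 <- group_compare(gA, gB)
  expect_equal(out2$p[1], 0)
  expect_equal(out2$p[2], 1)

  # permutation oracle on a textbook two-sample comparison (cohort sizes
  # mirror the default cohort sizes: 16 vs 15)
  set.seed(5)
  a <- rnorm(16, 0.050, 0.010)
  b <- rnorm(15, 0.042, 0.010)
  out3 <- group_compare(lapply(a, mk, e = 1), lapply(b, mk, e = 1))
  welch_t <- function(x, y) {
    (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
  }
  tobs <- abs(welch_t(a, b))
  pool <- c(a, b)
  set.seed(6)
  perm <- replicate(1e5, {
    idx <- sample.int(31, 16)
    abs(welch_t(pool[idx], pool[-idx]))
  })
  p_perm <- mean(perm >= tobs)
  mc_err <- 3 * sqrt(p_perm * (1 - p_perm) / 1e5)
  expect_lt(abs(out3$p[1] - p_perm), mc_err + 0.01)
})

test_that("centerline CSV and kymograph TSV writers round-trip / validate", {
  mp <- mech_params()
  gp <- growth_params(t_end = 10)
  traj <- simulate_shoot(straight_rod(20, 11), mp, gp)
  set.seed(2)
  ser <- sample_series(traj, frame_times = c(0, 10), n_points = 10,
                       sigma = 0.05, id = "i1", genotype = "WT")
  path <- withr::local_tempfile(fileext = ".csv")
  write_centerline_csv(ser, path)
  back <- read_centerline_csv(path)
  expect_length(back, 1)
  expect_equal(back[[1]]$samples[[2]]$xy, ser$samples[[2]]$xy,
               tolerance = 1e-12)
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(read_centerline_csv(bad), "missing columns")

  ky <- kymograph(ser)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_kymograph_tsv(ky, tsv)
  hdr <- strsplit(readLines(tsv, n = 1), "\t")[[1]]
  expect_equal(hdr[1], "time_min")
  expect_equal(length(hdr), 1 + length(ky$s))
})
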