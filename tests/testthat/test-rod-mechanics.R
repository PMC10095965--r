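test_that("rod geometry: straight, right-angle and circular configurations", {
  # straight rod: zero turning, zero curvature, length additivity
  rod <- straight_rod(2, n = 3)
  g <- rod_geometry(rod)
  expect_equal(g$turning_angles, 0)
  expect_equal(g$curvatures, 0)
  expect_equal(g$L, 2)
  expect_equal(g$arc_length, c(0, 1, 2))

  # right angle: bonds along +x then +y, voronoi length 1
  rod <- rod_state(rbind(c(0, 0), c(1, 0), c(1, 1)))
  g <- rod_geometry(rod)
  expect_equal(g$turning_angles, pi / 2)
  expect_equal(g$curvatures, pi / 2)

  # 41 vertices on a circle of radius 10: discrete curvature 0.100 +/- 0.001
  th <- seq(0, 1.5 * pi, length.out = 41)
  rod <- rod_state(cbind(10 * cos(th), 10 * sin(th)))
  g <- rod_geometry(rod)
  expect_true(all(abs(g$curvatures - 0.1) < 0.001))
})

test_that("degenerate geometry is rejected", {
  expect_error(rod_state(rbind(c(0, 0), c(0, 0), c(1, 0))), "degenerate")
  rod <- straight_rod(2, n = 3)
  rod$x[2, ] <- rod$x[1, ]
  expect_error(rod_geometry(rod), "degenerate")
})

test_that("energies match their defining formulas", {
  mp <- small_mp()
  # rest configuration: all zero with g removed
  mp0 <- small_mp(rho = 1e-300)
  rod <- straight_rod(3, n = 4)
  expect_equal(unname(rod_energies(rod, mp0)), c(0, 0, 0),
               tolerance = 1e-12)

  # one bond stretched by delta: U_s = ks * delta^2 / 2
  delta <- 0.07
  x <- rbind(c(0, 0), c(1, 0), c(2 + delta, 0))
  rod <- rod_state(x, a = c(1, 1))
  U <- rod_energies(rod, mp)
  expect_equal(unname(U["U_s"]), mp$ks * delta^2 / 2)
  expect_equal(unname(U["U_b"]), 0)

  # rigid translation: only gravity changes, by g * dy * total mass
  rod1 <- random_rod(7, seed = 3)
  rod2 <- rod1
  rod2$x[, 2] <- rod2$x[, 2] + 2.5
  dU <- rod_energies(rod2, mp) - rod_energies(rod1, mp)
  total_mass <- mp$rho * sum(rod1$a)
  expect_equal(unname(dU["U_s"]), 0, tolerance = 1e-10)
  expect_equal(unname(dU["U_b"]), 0, tolerance = 1e-10)
  expect_equal(unname(dU["U_g"]), mp$g * 2.5 * total_mass, tolerance = 1e-9)
})

test_that("analytic forces are exact gradients of the potentials", {
  mp <- small_mp()
  h <- 1e-6
  for (seed in 1:5) {
    rod <- random_rod(8, seed = seed)
    f <- rod_forces(rod, mp)
    n <- nrow(rod$x)
    for (comp in 1:3) {
      num <- matrix(0, n, 2)
      for (i in seq_len(n)) for (d in 1:2) {
        rp <- rod; rp$x[i, d] <- rp$x[i, d] + h
        rm_ <- rod; rm_$x[i, d] <- rm_$x[i, d] - h
        num[i, d] <- -(rod_energies(rp, mp)[comp] -
                         rod_energies(rm_, mp)[comp]) / (2 * h)
      }
      ana <- list(f$Fs, f$Fb, f$Fg)[[comp]]
      expect_lt(max(abs(num - ana)) / max(abs(ana)), 1e-6)
    }
  }
})

test_that("gravity force is (0, -m g) per vertex and sums to total weight", {
  mp <- small_mp()
  rod <- random_rod(9, seed = 11)
  f <- rod_forces(rod, mp)
  expect_equal(f$Fg[, 1], rep(0, 9))
  a <- rod$a
  m3 <- mp$rho * (a[2] + a[3]) / 2 # vertex 3 lumped mass
  expect_equal(f$Fg[3, 2], -m3 * mp$g)
  expect_equal(sum(f$Fg[, 2]), -mp$g * mp$rho * sum(a))
})

test_that("forces vanish at an unloaded rest configuration", {
  mp <- small_mp(rho = 1e-300)
  rod <- straight_rod(5, n = 6)
  f <- rod_forces(rod, mp)
  expect_lt(max(abs(f$Fs)), 1e-12)
  expect_lt(max(abs(f$Fb)), 1e-12)
})

test_that("equilibrate restores a straight rod without gravity", {
  mp <- small_mp(rho = 1e-300)
  rod <- straight_rod(10, n = 11, theta = 0.3)
  set.seed(4)
  pert <- rod
  pert$x[3:11, ] <- pert$x[3:11, ] + matrix(rnorm(18, 0, 0.1), ncol = 2)
  eq <- equilibrate(pert, mp)
  # straight line along theta_base through the clamp
  g <- rod_geometry(eq$state)
  expect_lt(max(abs(g$turning_angles)), 1e-6)
  expect_lt(max(abs(g$bond_angles - 0.3)), 1e-6)
})

test_that("equilibrium satisfies discrete force and moment balance", {
  eq <- equilibrate(straight_rod(40, 41), mech_params())
  mp <- mech_params()
  f <- rod_forces(eq$state, mp)
  net <- f$Fs + f$Fb + f$Fg
  expect_lt(max(sqrt(rowSums(net[3:41, ]^2))), mp$eps_f)
  # free-end moment balance: internal moment near the tip is tiny compared
  # to the peak moment (continuum boundary condition M(L) = 0)
  expect_lt(abs(f$M[length(f$M)]), 0.05 * max(abs(f$M)))
})

test_that("cantilever tip deflection matches Euler-Bernoulli closed form", {
  # small-deflection regime: sag about 1.8% of span
  mp <- mech_params(rho = 2e-5, g = 1, ks = 200, eps_f = 1e-11)
  rod <- straight_rod(20, n = 41)
  eq <- equilibrate(rod, mp)
  w <- -eq$state$x[41, 2]
  abar <- rod$a[1]
  L_eff <- 20 - abar / 2 # effective root: middle of the clamped bond
  w_theory <- mp$rho * mp$g * L_eff^4 / (8 * mp$B)
  expect_lt(w / 20, 0.05)
  expect_lt(abs(w - w_theory) / w_theory, 0.02)
})

test_that("zero-gravity equilibrium reproduces the curve integrated from kappa0", {
  mp <- small_mp(rho = 1e-300)
  n <- 41
  rod <- straight_rod(20, n = n)
  s_mid <- rod_geometry(rod)$arc_length[2:(n - 1)]
  k0 <- 0.05 * sin(s_mid / 6)
  rod$kappa0 <- k0
  eq <- equilibrate(rod, mp)
  # direct integration of theta'(s) = kappa0(s) with the same discretization
  abar <- (rod$a[-(n - 1)] + rod$a[-1]) / 2
  theta <- cumsum(c(0, k0 * abar))
  xs <- cumsum(c(0, rod$a * cos(c(theta))))
  ys <- cumsum(c(0, rod$a * sin(c(theta))))
  err <- max(sqrt((eq$state$x[, 1] - xs)^2 + (eq$state$x[, 2] - ys)^2))
  expect_lt(err / 20, 1e-3)
})

test_that("equilibration reports non-convergence", {
  mp <- mech_params(max_relax_iters = 2L)
  expect_error(equilibrate(straight_rod(40, 41), mp), "did not converge")
})

test_that("per-component displacement accumulation is additive (all methods)", {
  for (m in c("newton", "lbfgs", "fire", "gd")) {
    mp <- mech_params(method = m, eps_f = 1e-5,
                      max_relax_iters = 200000L)
    rod <- straight_rod(10, n = 11)
    rod$kappa0 <- rep(0.03, 9)
    eq <- equilibrate(rod, mp)
    r <- eq$record
    gap <- max(abs(r$dx_total - (r$dx_s + r$dx_b + r$dx_g)))
    expect_lt(gap, 1e-8 * 10)
    expect_equal(r$dx_total[1:2, ], matrix(0, 2, 2)) # clamp untouched
    # accumulated total equals the realized displacement
    expect_equal(eq$state$x - rod$x, r$dx_total, tolerance = 1e-9)
  }
})

test_that("rod state CSV round-trips", {
  rod <- random_rod(7, seed = 21)
  path <- withr::local_tempfile(fileext = ".csv")
  write_rod_state(rod, path)
  back <- read_rod_state(path)
  expect_equal(back$x, rod$x)
  expect_equal(back$a, rod$a)
  expect_equal(back$kappa0, rod$kappa0)
  # malformed file rejected
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1:3, b = 2:4), bad, row.names = FALSE)
  expect_error(read_rod_state(bad), "malformed")
})
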