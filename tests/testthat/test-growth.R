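test_that("dimensionless groups and inverse helpers", {
  gp <- growth_params(beta = 5e-4, gamma = 0.02, Lgz = 40)
  mp <- mech_params(B = 1, g = 1, rho = 1 / 8000)
  gr <- dimensionless_groups(gp, mp)
  expect_equal(gr$ls, 40)
  expect_equal(gr$S, 1)
  expect_equal(gr$Lg, 20)
  expect_equal(gr$Gt, 0.5)

  expect_equal(beta_for_S(1, 0.02, 40), 5e-4)
  expect_equal(rho_for_Gt(0.5, 40), 1 / 8000)
  # round trip: requested (S, Gt) realized exactly
  for (S in c(0.3, 1, 2.7)) for (Gt in c(0.4, 1.6)) {
    gp2 <- growth_params(beta = beta_for_S(S, 0.02, 40), gamma = 0.02,
                         Lgz = 40)
    mp2 <- mech_params(rho = rho_for_Gt(Gt, 40))
    gr2 <- dimensionless_groups(gp2, mp2)
    expect_equal(gr2$S, S)
    expect_equal(gr2$Gt, Gt)
  }
  expect_error(dimensionless_groups(growth_params(beta = 0), mp), "beta")
})

test_that("grow_step elongates only the apical zone, clamped bond excluded", {
  gp <- growth_params(v = 0.02, Lgz = 20, dt = 1)
  rod <- straight_rod(40, n = 41)
  grown <- grow_step(rod, gp)
  rate <- gp$v / gp$Lgz
  # apical-half bonds elongate at exactly v/Lgz per unit time
  expect_equal(grown$a[40] / rod$a[40], 1 + rate)
  expect_equal(grown$a[25] / rod$a[25], 1 + rate)
  # basal bonds (outside the zone) unchanged
  expect_equal(grown$a[1:20], rod$a[1:20])
  # kappa0 untouched by growth
  expect_equal(grown$kappa0, rod$kappa0)

  # whole-shoot zone: every bond grows except the clamped basal one
  gp2 <- growth_params(v = 0.02, Lgz = 40, dt = 1)
  g2 <- grow_step(rod, gp2)
  expect_equal(g2$a[1], rod$a[1])
  expect_equal(g2$a[-1] / rod$a[-1], rep(1 + 0.02 / 40, 39))
})

test_that("accumulated natural growth is linear in time to within 0.5%", {
  gp <- growth_params(v = 0.05, Lgz = 20, dt = 1, t_end = 80)
  rod <- straight_rod(40, n = 41)
  for (k in 1:80) rod <- grow_step(rod, gp)
  expect_lt(abs(sum(rod$a) - (40 + 0.05 * 80)) / (40 + 0.05 * 80), 0.005)
})

test_that("gravi-proprioceptive update follows the sine law", {
  gp <- growth_params(beta = 1e-3, gamma = 0.02, Lgz = 40, dt = 1)

  # horizontal straight rod: maximal stimulus, increment beta * dt
  rod <- straight_rod(40, n = 11)
  up <- gravi_proprio_update(rod, rod_geometry(rod), gp)
  expect_equal(up$kappa0, rep(gp$beta * gp$dt, 9))

  # vertical straight rod: no stimulus
  rodv <- straight_rod(40, n = 11, theta = pi / 2)
  upv <- gravi_proprio_update(rodv, rod_geometry(rodv), gp)
  expect_equal(upv$kappa0, rep(0, 9))

  # stationarity: realized kappa = (beta/gamma) cos(theta) is a fixed point
  x <- rbind(c(0, 0), c(1, 0), c(1 + cos(0.2), sin(0.2)))
  rod3 <- rod_state(x)
  geom <- rod_geometry(rod3)
  kap <- geom$curvatures[1]
  th <- geom$vertex_angles[2]
  gp3 <- growth_params(beta = kap * gp$gamma / cos(th), gamma = gp$gamma,
                       Lgz = 10, dt = 1)
  up3 <- gravi_proprio_update(rod3, geom, gp3)
  expect_equal(up3$kappa0, rod3$kappa0, tolerance = 1e-12)

  # outside the growing zone the target geometry is untouched
  gpz <- growth_params(beta = 1e-3, gamma = 0.02, Lgz = 10, dt = 1)
  upz <- gravi_proprio_update(rod, rod_geometry(rod), gpz)
  expect_equal(upz$kappa0[1:7], rep(0, 7)) # basal vertices out of zone
  expect_true(all(upz$kappa0[8:9] > 0))
})

test_that("simulate_shoot: no activity means no motion", {
  mp <- mech_params()
  gp <- growth_params(v = 0, beta = 0, gamma = 0, t_end = 10)
  traj <- simulate_shoot(straight_rod(20, 21), mp, gp)
  x0 <- traj$frames[[1]]$state$x
  x1 <- traj$frames[[11]]$state$x
  expect_lt(max(abs(x1 - x0)), 1e-6)
})

test_that("simulate_shoot: pure growth without gravity stays straight", {
  mp <- mech_params(rho = 1e-300)
  gp <- growth_params(v = 0.05, Lgz = 20, beta = 0, gamma = 0, t_end = 40)
  traj <- simulate_shoot(straight_rod(20, 21), mp, gp)
  gend <- traj$frames[[41]]$geom
  expect_lt(max(abs(gend$curvatures)), 1e-8)
  expect_equal(gend$L, 20 + 0.05 * 40, tolerance = 5e-3)
})

test_that("time-step halving changes final max curvature by < 2%", {
  mp <- mech_params()
  run <- function(dt) {
    gp <- growth_params(dt = dt, t_end = 60)
    traj <- simulate_shoot(straight_rod(40, 21), mp, gp)
    max(abs(traj$frames[[length(traj$frames)]]$geom$curvatures))
  }
  k1 <- run(1)
  k05 <- run(0.5)
  expect_lt(abs(k1 - k05) / k05, 0.02)
})

test_that("WT-like bends more than mutant-like; extension ratios agree", {
  kmax_wt <- max(abs(wt_traj()$frames[[141]]$geom$curvatures))
  kmax_mut <- max(abs(mut_traj()$frames[[141]]$geom$curvatures))
  expect_gt(kmax_wt, kmax_mut)
  eps_wt <- wt_traj()$frames[[141]]$geom$L / wt_traj()$frames[[1]]$geom$L
  eps_mut <- mut_traj()$frames[[141]]$geom$L / mut_traj()$frames[[1]]$geom$L
  expect_lt(abs(eps_wt - eps_mut), 1e-3)
})

test_that("trajectory equilibria keep the inextensibility regime", {
  st <- wt_traj()$frames[[141]]$state
  strain <- abs(rod_geometry(st)$bond_lengths / st$a - 1)
  expect_lt(max(strain), 1e-3)
})

test_that("trajectory serialization round-trips", {
  mp <- mech_params()
  gp <- growth_params(t_end = 5)
  traj <- simulate_shoot(straight_rod(20, 11), mp, gp)
  dir <- withr::local_tempdir()
  write_trajectory(traj, dir)
  back <- read_trajectory(dir)
  expect_equal(length(back$frames), 6)
  expect_equal(back$frames[[6]]$x, traj$frames[[6]]$state$x,
               tolerance = 1e-12)
  expect_equal(back$manifest$growth$v, gp$v)
})
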