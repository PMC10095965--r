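# Shared fixtures. Everything is generated in code; heavier simulations are
# memoised so several test files (and the acceptance criteria) can reuse
# them within one test run.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = fixture_env)) {
    assign(key, force(expr), envir = fixture_env)
  }
  get(key, envir = fixture_env)
}

# a small, fast rod world used by module tests
small_mp <- function(...) mech_params(...)

# random perturbed rod states for gradient checks
random_rod <- function(n = 9, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- cbind(seq(0, n - 1) + rnorm(n, 0, 0.15), rnorm(n, 0, 0.4))
  rod_state(x, a = runif(n - 1, 0.8, 1.2), kappa0 = rnorm(n - 2, 0, 0.15))
}

# default wild-type-like 140-min run (shared by several acceptance criteria)
wt_traj <- function() memo("wt_traj", {
  simulate_shoot(straight_rod(40, 41), mech_params(), growth_params())
})

# mutant-like: beta halved, everything else equal
mut_traj <- function() memo("mut_traj", {
  gp <- growth_params(beta = 5e-4)
  simulate_shoot(straight_rod(40, 41), mech_params(), gp)
})

# fit configuration of the acceptance recovery experiment (10x10 grid,
# 60-vertex rod) and its morphospace table
acc_fit_cfg <- function() fit_config(n_vertices = 60)

acc_table <- function() memo("acc_table", {
  suppressWarnings(morphospace_table(acc_fit_cfg()))
})

# synthetic cohorts at the default design size (16 WT-like, 15 mutant-like)
acc_cohorts <- function() memo("acc_cohorts", {
  make_cohorts(seed = 1)
})
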