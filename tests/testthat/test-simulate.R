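# Simulators: determinism, non-negativity, equilibria, ground truth.

test_that("identical seeds give identical output", {
  a <- simulate_allee(allee_config(seed = 3, t_end = 20))
  b <- simulate_allee(allee_config(seed = 3, t_end = 20))
  expect_identical(a$dense, b$dense)
  expect_identical(a$observations, b$observations)

  f1 <- simulate_fishery(fishery_config(seed = 5, years = 20))
  f2 <- simulate_fishery(fishery_config(seed = 5, years = 20))
  expect_identical(f1$dense, f2$dense)
})

test_that("states stay non-negative and absorbed populations stay extinct", {
  sim <- simulate_allee(allee_config(seed = 8, sigma = 0.05, t_end = 40))
  expect_true(all(sim$dense$A >= 0))
  if (!is.na(sim$collapse_time)) {
    expect_true(all(sim$dense$A[sim$dense$time >= sim$collapse_time] == 0))
  }
  chain <- simulate_food_chain(food_chain_config(seed = 3))
  expect_true(all(as.matrix(chain$dense[, c("X", "Y", "Z")]) >= 0))
  z <- chain$dense$Z
  died <- which(z == 0)
  if (length(died)) expect_true(all(z[died[1]:length(z)] == 0))
})

test_that("a frozen subcritical mortality settles on the upper equilibrium", {
  cfg <- allee_config(sigma = 0, c_rate = 0, c0 = 7, init = 0.9,
                      t_end = 30, burn_in = 30)
  sim <- simulate_allee(cfg)
  g <- allee_percapita(cfg)
  root <- uniroot(function(A) g(A) - 7, c(0.3, 1), tol = 1e-12)$root
  A_obs <- sim$observations$states$A
  expect_lt(max(abs(A_obs - root)) / root, 1e-6)
})

test_that("a frozen supercritical mortality leads to extinction", {
  cfg <- allee_config(sigma = 0, c_rate = 0, c0 = 8.6, t_end = 40, burn_in = 5)
  g <- allee_percapita(cfg)
  expect_gt(8.6, optimize(g, c(1e-4, 1), maximum = TRUE)$objective) # no root
  sim <- simulate_allee(cfg)
  expect_lt(tail(sim$dense$A, 1), 1e-3)
})

test_that("the fold sits at the maximum per-capita birth rate", {
  cfg <- allee_config()
  sim <- simulate_allee(allee_config(sigma = 0, t_end = 20))
  g <- allee_percapita(cfg)
  c_star <- optimize(g, c(1e-4, cfg$K), maximum = TRUE, tol = 1e-10)$objective
  expect_lt(abs(sim$true_bifurcation$value - c_star) / c_star, 1e-6)
})

test_that("collapse lags the fast-subsystem bifurcation (bifurcation delay)", {
  sim <- simulate_allee(allee_config(seed = 12))
  expect_false(is.na(sim$collapse_time))
  expect_gt(sim$collapse_time, sim$true_bifurcation$time)
})

test_that("the trivial transcritical example is located exactly", {
  # dA/dt = A(c - A): the extinct state A = 0 has eigenvalue c, so the
  # crossing sits exactly at c = 0 as c rises
  tb <- true_bifurcation_point(function(A, c) A * (c - A),
                               par_range = c(-1, 1), x0 = 0,
                               min_state = -Inf)
  expect_lt(abs(tb$value), 1e-5)
  expect_identical(tb$kind, "smooth_crossing")
})

test_that("the food-chain Hopf matches a dense analytic sweep", {
  cfg <- food_chain_config()
  sim <- simulate_food_chain(food_chain_config(sigma = 0))
  # oracle: fine sweep of the analytic Jacobian along the closed-form branch
  mzs <- seq(0.5, 0.7, by = 5e-4)
  marg <- sapply(mzs, function(mz) {
    s <- chain_equilibrium(cfg, mz)
    -max(Re(chain_jacobian_eigen(cfg, s, mz)))
  })
  i <- which(marg <= 0)[1]
  mz_hopf <- mzs[i - 1] + (mzs[i] - mzs[i - 1]) *
    marg[i - 1] / (marg[i - 1] - marg[i])
  expect_lt(abs(sim$true_bifurcation$value - mz_hopf), 1e-3)
  # the crossing is carried by a conjugate pair
  s <- chain_equilibrium(cfg, sim$true_bifurcation$value)
  ev <- chain_jacobian_eigen(cfg, s, sim$true_bifurcation$value)
  dom <- ev[which.max(Re(ev))]
  expect_gt(abs(Im(dom)), 0.5)
})

test_that("frozen food-chain runs settle on the coexistence equilibrium", {
  cfg <- food_chain_config(sigma = 0, mZ_rate = 0, mZ0 = 0.35,
                           burn_in = 150, t_end = 10,
                           init = c(1.5, 0.15, 0.3))
  sim <- simulate_food_chain(cfg)
  target <- chain_equilibrium(cfg, 0.35)
  last <- unlist(sim$dense[nrow(sim$dense), c("X", "Y", "Z")])
  expect_lt(max(abs(last - target) / target), 1e-6)
})

test_that("a frozen post-Hopf mortality sustains oscillations", {
  cfg <- food_chain_config(sigma = 0, mZ_rate = 0, mZ0 = 0.68,
                           burn_in = 0, t_end = 250,
                           init = chain_equilibrium(food_chain_config(), 0.68) * c(1.05, 1, 1))
  sim <- simulate_food_chain(cfg)
  X <- sim$dense$X
  tt <- sim$dense$time
  late <- X[tt > 150]
  pre_cfg <- food_chain_config(sigma = 0, mZ_rate = 0, mZ0 = 0.35,
                               burn_in = 100, t_end = 100,
                               init = c(1.5, 0.15, 0.3))
  pre <- simulate_food_chain(pre_cfg)
  pre_range <- diff(range(pre$dense$X[pre$dense$time > 0]))
  expect_gt(diff(range(late)), 10 * max(pre_range, 1e-6))
})

test_that("the fishery map has the two regimes and a fold between them", {
  cfg <- fishery_config(sigma_P = 0, sigma_F = 0)
  step <- fishery_annual_map(cfg)
  run_to_fp <- function(s, h, n = 4000) { for (i in seq_len(n)) s <- step(s, h); s }
  high <- run_to_fp(c(3, 2.5, 0.02), 0)
  expect_gt(high[1], 1)           # high-piscivore state at no harvest
  expect_lt(high[3], 0.1)         # planktivore suppressed
  expect_lt(max(abs(step(high, 0) - high)), 1e-8)

  low <- run_to_fp(c(3, 2.5, 0.02), 0.8)
  expect_lt(low[1], 1e-6)         # piscivore gone at heavy harvest
  expect_gt(low[3], 0.9)          # planktivore released

  sim <- simulate_fishery(cfg)
  tb <- sim$true_bifurcation
  expect_gt(tb$value, 0)
  expect_lt(tb$value, 0.8)
  # the frozen map is stable just below and has no high state just above
  just_below <- run_to_fp(high, tb$value - 0.01)
  expect_gt(just_below[1], 0.5)
  just_above <- run_to_fp(high, tb$value + 0.02)
  expect_lt(just_above[1], 0.5)
})

test_that("simulation output carries a consistent ground-truth record", {
  sim <- simulate_food_chain(food_chain_config(seed = 6))
  expect_identical(sim$true_bifurcation$parameter, "mZ")
  expect_equal(sim$true_bifurcation$time,
               (sim$true_bifurcation$value - 0.2) / 0.005, tolerance = 1e-6)
  if (!is.na(sim$onset_time) && !is.na(sim$collapse_time)) {
    expect_lte(sim$onset_time, sim$collapse_time)
  }
  if (!is.na(sim$onset_time)) {
    expect_gt(sim$onset_time, sim$true_bifurcation$time)
  }
})
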