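# Entry estimators and the full Jacobian-series recipe.

test_that("one-sided derivatives are exact chords and guard spacing", {
  expect_equal(one_sided_derivative(c(1, 2), c(2, 4), k = 2)$value, 2)
  expect_error(one_sided_derivative(c(1, 1 + 1e-12), c(0, 5), k = 2),
               class = "gm_degenerate_spacing")

  # first-order accuracy on f = x^2: halving the spacing halves the error
  err_at <- function(dx) {
    x <- seq(1, 2, by = dx)
    k <- length(x)
    abs(one_sided_derivative(x, x^2, k)$value - 2 * x[k])
  }
  e1 <- err_at(0.01); e2 <- err_at(0.005)
  expect_lt(e1, 0.011)
  expect_lt(abs(e1 / e2 - 2), 1)
})

test_that("balance inference closes the discretized budget", {
  obs <- gm_observations(c(0, 1), states = list(A = c(10, 12)),
                         rates = list(births = c(4, 5)))
  est <- infer_by_balance(allee_model(), obs, "A", k = 2)
  expect_equal(est$value, 3) # 5 - (12-10)/1
  expect_identical(est$method, "balance")

  # discrete time: recruitment closes P[t+1] = P[t] + R - mP P - H exactly
  obs2 <- gm_observations(0:1, states = list(P = c(10, 10)),
                          rates = list(catch = c(1, 1)))
  est2 <- infer_by_balance(mini_fishery_model(0.1), obs2, "P", k = 2)
  expect_equal(est2$value, 2)
})

test_that("assumption-based derivatives implement magnitude/state scaling", {
  expect_equal(derivative_from_assumption(3, 12, "linear")$value, 0.25)
  expect_equal(derivative_from_assumption(8, 4, 2)$value, 4)
  expect_equal(derivative_from_assumption(5, 2, "linear")$value,
               derivative_from_assumption(5, 2, 1)$value)
  expect_error(derivative_from_assumption(3, 0, "linear"),
               class = "gm_domain_error")
})

test_that("trailing smoothing preserves times, length and constants", {
  obs <- gm_observations(1:20, states = list(A = rep(2, 20)),
                        rates = list(r = rnorm(20)))
  sm <- smooth_observations(obs, 4)
  expect_identical(sm$times, obs$times)
  expect_equal(sm$states$A, rep(2, 20))
  expect_identical(smooth_observations(obs, 1), obs)
  expect_error(smooth_observations(obs, 21), class = "gm_usage_error")

  # variance of a smoothed white-noise series is about sigma^2 / window
  set.seed(1)
  n <- 10000; w <- 5
  noisy <- gm_observations(seq_len(n), states = list(A = pmax(rnorm(n, 10), 0)))
  smn <- smooth_observations(noisy, w)
  v <- var(smn$states$A[w:n])
  expect_lt(abs(v - 1 / w) / (1 / w), 0.3)
})

test_that("the population recipe yields one estimate per admissible index", {
  sim <- simulate_allee(allee_config(sigma = 0))
  series <- estimate_jacobian_series(allee_model(), sim$observations)
  # 15 observations, estimates at every index from the second onwards
  expect_length(series$jacobians, 14L)
  expect_equal(series$times, sim$observations$times[-1])
})

test_that("an exactly linear mortality coefficient is recovered", {
  obs_times <- seq(0, 8, by = 0.125)
  cfg <- allee_config(sigma = 0, obs_times = obs_times, t_end = 20)
  sim <- simulate_allee(cfg)
  obs <- sim$observations
  for (k in c(2L, 20L, 40L, length(obs$times))) {
    D <- infer_by_balance(allee_model(), obs, "A", k)$value
    c_hat <- derivative_from_assumption(D, obs$states$A[k], "linear")$value
    c_true <- ramp_value(sim$ramp, obs$times[k])
    expect_lt(abs(c_hat - c_true) / c_true, 1e-3)
  }
})

test_that("estimates are causal: later observations never matter", {
  sim <- simulate_allee(allee_config(seed = 5))
  obs <- sim$observations
  full <- estimate_jacobian_series(allee_model(), obs)
  n_cut <- 10L
  cut <- gm_observations(obs$times[1:n_cut],
                         states = lapply(obs$states, head, n_cut),
                         rates = lapply(obs$rates, head, n_cut))
  part <- estimate_jacobian_series(allee_model(), cut)
  for (i in seq_along(part$jacobians)) {
    expect_equal(part$jacobians[[i]]$matrix, full$jacobians[[i]]$matrix)
  }
})

test_that("noise-free food-chain estimates converge to the analytic Jacobian", {
  errs <- sapply(c(1, 0.5), function(dt_obs) {
    cfg <- food_chain_config(sigma = 0, obs_dt = dt_obs, t_end = 60,
                             burn_in = 30)
    sim <- simulate_food_chain(cfg)
    series <- estimate_jacobian_series(food_chain_model(), sim$observations)
    errs_k <- vapply(series$jacobians, function(J) {
      k <- match(J$time, sim$observations$times)
      s <- c(sim$observations$states$X[k], sim$observations$states$Y[k],
             sim$observations$states$Z[k])
      ev_true <- chain_jacobian_eigen(cfg, s, ramp_value(sim$ramp, J$time))
      max(abs(sort(Re(J$eigenvalues)) - sort(Re(ev_true))))
    }, numeric(1))
    # discard the start-up stencils
    tt <- vapply(series$jacobians, `[[`, numeric(1), "time")
    max(errs_k[tt >= 10])
  })
  expect_lt(errs[1], 0.02)
  rat <- errs[1] / errs[2]
  expect_gt(rat, 1.3)
  expect_lt(rat, 2.7)
})

test_that("entry provenance records how each entry was obtained", {
  sim <- simulate_allee(allee_config(sigma = 0))
  series <- estimate_jacobian_series(allee_model(), sim$observations)
  prov <- series$jacobians[[1]]$provenance
  expect_match(prov[1, 1], "finite_difference")
  expect_match(prov[1, 1], "balance\\+assumption")
})
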