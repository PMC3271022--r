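# Tracking, exclusion, warning logic, transition typing, baselines.

make_traj <- function(ev_matrix, times = seq_len(nrow(ev_matrix)),
                      time_mode = "continuous") {
  structure(list(times = times, eigenvalues = ev_matrix,
                 time_mode = time_mode, excluded = integer()),
            class = "gm_eigen_trajectory")
}

const_jacobian <- function(m, t) {
  model <- gm_model(c("X", "Y"),
                    list(gm_process("g", "gain", "X", "X",
                                    observability = "observed",
                                    assumptions = list(X = "free"))),
                    time_mode = "continuous")
  structure(list(time = t, matrix = m,
                 eigenvalues = sort_eig_helper(m),
                 provenance = NULL, time_mode = "continuous"),
            class = "gm_jacobian")
}
sort_eig_helper <- function(m) {
  ev <- eigen(m, only.values = TRUE)$values
  ev[order(-Re(ev), -Im(ev))]
}

test_that("tracking keeps constant spectra constant and scalars trivial", {
  m <- matrix(c(-1, 2, -2, -1), 2, 2)
  jj <- lapply(1:5, function(t) const_jacobian(m, t))
  traj <- track_eigenvalues(jj)
  expect_true(all(apply(traj$eigenvalues, 2, function(b) length(unique(b)) == 1L)))

  sim <- simulate_allee(allee_config(seed = 2))
  series <- estimate_jacobian_series(allee_model(), sim$observations)
  traj1 <- track_eigenvalues(series)
  expect_identical(ncol(traj1$eigenvalues), 1L)
  expect_equal(Re(traj1$eigenvalues[, 1]),
               vapply(series$jacobians, function(j) Re(j$eigenvalues[1]), 1))
})

test_that("a slowly rotating conjugate pair never swaps partners", {
  angles <- seq(0.2, 1.4, by = 0.05)
  evs <- t(sapply(angles, function(a) {
    c(complex(real = -0.2, imaginary = a), complex(real = -0.2, imaginary = -a))
  }))
  jj <- lapply(seq_along(angles), function(i) {
    structure(list(time = i,
                   matrix = matrix(c(-0.2, angles[i], -angles[i], -0.2), 2, 2),
                   eigenvalues = evs[i, ], provenance = NULL,
                   time_mode = "continuous"), class = "gm_jacobian")
  })
  traj <- track_eigenvalues(jj)
  expect_true(all(Im(traj$eigenvalues[, 1]) > 0))
  expect_true(all(Im(traj$eigenvalues[, 2]) < 0))
  # matches the brute-force assignment step by step
  for (i in 2:length(angles)) {
    oracle <- brute_force_assignment(evs[i - 1, ], evs[i, ])
    expect_equal(sum(Mod(evs[i - 1, ] - traj$eigenvalues[i, ])), oracle$cost,
                 tolerance = 1e-12)
  }
})

test_that("the exclusion rule removes only clearly noisier real branches", {
  set.seed(3)
  n <- 30
  quiet <- -0.3 + cumsum(rnorm(n, sd = 0.005))
  pair <- complex(real = quiet, imaginary = 0.4)
  noisy <- -0.5 + rnorm(n, sd = sqrt(10) * sd(Re(pair)) * 3)
  traj <- make_traj(cbind(pair, Conj(pair), noisy))
  out <- exclude_spurious(traj, variance_ratio = 5)
  expect_identical(out$excluded, 3L)
  expect_identical(ncol(out$eigenvalues), 2L)

  # equal-variance branches are all kept
  b2 <- -0.5 + rnorm(n, sd = sd(Re(pair)))
  traj2 <- make_traj(cbind(pair, Conj(pair), b2))
  out2 <- exclude_spurious(traj2, variance_ratio = 5)
  expect_identical(out2$excluded, integer())
  expect_identical(ncol(out2$eigenvalues), 3L)
})

test_that("warnings need both a clear trend and a margin drop", {
  margins <- seq(-0.5, -0.04, length.out = 10) # Re(lambda): margin 0.5 -> 0.04
  traj <- make_traj(matrix(complex(real = margins), ncol = 1), times = 1:10)
  rep <- warning_report(traj)
  expect_true(rep$warning)
  expect_equal(rep$trend_statistic, -1)
  expect_identical(rep$transition_type, "real_crossing")

  const <- make_traj(matrix(complex(real = rep(-0.3, 8)), ncol = 1), times = 1:8)
  rep2 <- warning_report(const)
  expect_false(rep2$warning)
  expect_equal(rep2$trend_statistic, 0)
  expect_identical(rep2$transition_type, "none")

  # declining trend alone is not enough when the margin stays high
  shallow <- make_traj(matrix(complex(real = seq(-0.5, -0.4, length.out = 8)),
                              ncol = 1), times = 1:8)
  expect_false(warning_report(shallow)$warning)

  expect_error(warning_report(make_traj(matrix(complex(real = c(-1, -1, -1)),
                                               ncol = 1), times = 1:3)),
               class = "gm_usage_error")
})

test_that("warnings are causal under truncation", {
  set.seed(9)
  margins <- seq(-0.6, -0.1, length.out = 20) + rnorm(20, sd = 0.01)
  traj <- make_traj(matrix(complex(real = margins), ncol = 1), times = 1:20)
  rep <- warning_report(traj)
  expect_true(rep$warning)
  cut_at <- which(traj$times == rep$warning_time)
  cut <- make_traj(traj$eigenvalues[1:cut_at, , drop = FALSE], times = 1:cut_at)
  expect_equal(warning_report(cut)$warning_time, rep$warning_time)
})

test_that("the trend statistic is a rank statistic", {
  set.seed(21)
  m <- sort(runif(12), decreasing = TRUE)
  tau1 <- kendall_trend(m)
  tau2 <- kendall_trend(exp(3 * m)) # strictly increasing transform
  expect_equal(tau1, tau2)
  expect_equal(kendall_trend(rep(1, 10)), 0)
})

test_that("transition typing distinguishes pairs from real crossings", {
  pair_re <- seq(-0.2, -0.05, length.out = 6)
  pair_im <- seq(0.5, 0.45, length.out = 6)
  ev <- cbind(complex(real = pair_re, imaginary = pair_im),
              complex(real = pair_re, imaginary = -pair_im),
              complex(real = seq(-1, -0.9, length.out = 6)))
  expect_identical(classify_transition(make_traj(ev)), "hopf_pair")

  real_traj <- make_traj(matrix(complex(real = seq(-0.3, -0.05, length.out = 6)),
                                ncol = 1))
  expect_identical(classify_transition(real_traj), "real_crossing")

  map_traj <- make_traj(matrix(complex(real = seq(0.8, 0.98, length.out = 6)),
                               ncol = 1), time_mode = "discrete")
  expect_identical(classify_transition(map_traj), "real_crossing")
})

test_that("rolling baselines compute windowed variance and lag-1 correlation", {
  bl <- rolling_baseline(rep(3, 10), "variance", window = 4)
  expect_equal(bl$values, rep(0, 7))
  expect_length(bl$values, 10 - 4 + 1)

  alt <- rep(c(1, -1), 6)
  bl2 <- rolling_baseline(alt, "lag1_autocorrelation", window = 4)
  expect_equal(bl2$values, rep(-1, length(alt) - 3))

  expect_error(rolling_baseline(1:10, "variance", window = 2),
               class = "gm_usage_error")
  expect_error(rolling_baseline(1:10, "lag1_autocorrelation", window = 20),
               class = "gm_usage_error")

  # AR(1) recovery: mean windowed lag-1 correlation near the coefficient
  set.seed(14)
  n <- 10000
  x <- as.numeric(stats::arima.sim(list(ar = 0.6), n))
  bl3 <- rolling_baseline(x, "lag1_autocorrelation", window = 500)
  expect_lt(abs(mean(bl3$values) - 0.6), 0.05)
})

test_that("initial stability search keeps exactly the stable grid points", {
  # one-stock map: increment slope -m via a known linear loss,
  # so the map eigenvalue is 1 - m
  m <- gm_model("P",
                list(gm_process("loss", "loss", "P", depends_on = "P",
                                observability = "known_form",
                                form = list(kind = "linear", of = "P", rate = "m"))),
                time_mode = "discrete", known_constants = list(m = 0.5))
  set.seed(2)
  P <- 10 + cumsum(rnorm(8, sd = 0.05))
  obs <- gm_observations(0:7, states = list(P = P))
  res <- initial_stability_search(m, list(m = c(0.5, 1.5, 2.5)), obs)
  expect_setequal(res$m, c(0.5, 1.5)) # |1-m| < 1 for both, 2.5 excluded

  res2 <- initial_stability_search(m, list(m = c(2.5, 3.5)), obs)
  expect_identical(nrow(res2), 0L)
  expect_identical(attr(res2, "message"), "no stable parameterization in range")
})
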