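# Jacobian assembly, stability classification, eigenvalue matching.

test_that("a one-dimensional Jacobian is gain slope minus loss slope", {
  J <- build_jacobian(allee_model(), list(births.A = 0.5, deaths.A = 0.8),
                      at_time = 0)
  expect_equal(unname(J$matrix), matrix(-0.3), tolerance = 1e-12)
  expect_equal(Re(J$eigenvalues), -0.3)
})

test_that("a discrete-time Jacobian is identity plus increment slopes", {
  m <- gm_model("A",
                list(gm_process("G", "gain", "A", depends_on = "A",
                                observability = "observed",
                                assumptions = list(A = "free")),
                     gm_process("L", "loss", "A", depends_on = "A",
                                observability = "inferred_by_balance",
                                assumptions = list(A = "linear"))),
                time_mode = "discrete")
  J <- build_jacobian(m, list(G.A = 0.1, L.A = 0.05), at_time = 0)
  expect_equal(unname(J$matrix), matrix(1.05))
})

test_that("missing and non-finite entries raise the documented errors", {
  m <- allee_model()
  expect_error(build_jacobian(m, list(births.A = 0.5), 0),
               class = "gm_identifiability_error")
  expect_error(build_jacobian(m, list(births.A = 0.5, deaths.A = NaN), 0),
               class = "gm_numerical_error")
})

test_that("stability classification matches the textbook boundaries", {
  v <- classify_stability(c(-1, -0.5), "continuous")
  expect_true(v$stable)
  expect_equal(v$margin, 0.5)

  expect_true(classify_stability(c(0.95, 0.5), "discrete")$stable)
  expect_equal(classify_stability(c(0.95, 0.5), "discrete")$margin, 0.05)
  expect_false(classify_stability(c(1.05, 0.5), "discrete")$stable)

  v <- classify_stability(c(-0.2 + 0.5i, -0.2 - 0.5i, -1), "continuous")
  expect_true(v$stable)
  expect_equal(v$margin, 0.2)
  expect_setequal(v$dominant_eigenvalues, c(-0.2 + 0.5i, -0.2 - 0.5i))

  expect_error(classify_stability(complex(0), "continuous"),
               class = "gm_usage_error")
})

test_that("classification is invariant under permutation and conjugation", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(2:5, 1)
    ev <- complex(real = rnorm(n), imaginary = rnorm(n))
    mode <- sample(c("continuous", "discrete"), 1)
    base <- classify_stability(ev, mode)
    perm <- classify_stability(sample(ev), mode)
    conj <- classify_stability(Conj(ev), mode)
    expect_equal(perm$margin, base$margin)
    expect_equal(perm$stable, base$stable)
    expect_equal(conj$margin, base$margin)
  }
})

test_that("the margin is 1-Lipschitz in the eigenvalues", {
  set.seed(7)
  for (i in 1:40) {
    n <- sample(1:4, 1)
    ev <- complex(real = rnorm(n), imaginary = rnorm(n))
    eps <- runif(1, 0, 0.3)
    pert <- ev + complex(real = runif(n, -eps, eps) / sqrt(2),
                         imaginary = runif(n, -eps, eps) / sqrt(2))
    for (mode in c("continuous", "discrete")) {
      d <- abs(classify_stability(pert, mode)$margin -
                 classify_stability(ev, mode)$margin)
      expect_lte(d, eps + 1e-12)
    }
  }
})

test_that("eigenvalue matching is the exact optimal assignment", {
  expect_identical(match_eigenvalues(c(1 + 0i, 2 + 0i), c(1 + 0i, 2 + 0i)), c(1L, 2L))
  # conjugate pairs map to conjugate pairs
  prev <- c(-0.2 + 0.5i, -0.2 - 0.5i)
  cur <- c(-0.1 - 0.45i, -0.1 + 0.45i)
  perm <- match_eigenvalues(prev, cur)
  expect_identical(perm, c(2L, 1L))

  set.seed(11)
  for (i in 1:50) {
    n <- sample(2:4, 1)
    prev <- complex(real = rnorm(n), imaginary = rnorm(n))
    cur <- prev[sample(n)] + complex(real = rnorm(n, sd = 0.05),
                                     imaginary = rnorm(n, sd = 0.05))
    perm <- match_eigenvalues(prev, cur)
    oracle <- brute_force_assignment(prev, cur)
    expect_equal(sum(Mod(prev - cur[perm])), oracle$cost, tolerance = 1e-12)
  }
  expect_error(match_eigenvalues(c(1 + 0i), c(1 + 0i, 2 + 0i)),
               class = "gm_usage_error")
})

test_that("estimated Jacobians keep conjugate-symmetric spectra", {
  sim <- simulate_food_chain(food_chain_config(seed = 4, t_end = 60))
  series <- estimate_jacobian_series(food_chain_model(), sim$observations,
                                     smoothing = 5, floor = 0.03)
  for (J in series$jacobians) {
    ev <- J$eigenvalues
    expect_equal(sort(Im(ev)), sort(-Im(ev)), tolerance = 1e-8)
    expect_true(all(abs(Im(rowSums(J$matrix))) == 0)) # real matrix
  }
})
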