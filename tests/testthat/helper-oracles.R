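# Independent oracles used across the suite.

# exhaustive minimum-cost assignment, written independently of
# match_eigenvalues (recursive enumeration rather than a permutation table)
brute_force_assignment <- function(previous, current) {
  n <- length(previous)
  best <- list(cost = Inf, perm = NULL)
  recurse <- function(chosen, remaining, cost) {
    if (cost >= best$cost) return()
    if (!length(remaining)) {
      best <<- list(cost = cost, perm = chosen)
      return()
    }
    i <- length(chosen) + 1L
    for (j in remaining) {
      recurse(c(chosen, j), setdiff(remaining, j),
              cost + Mod(previous[i] - current[j]))
    }
  }
  recurse(integer(), seq_len(n), 0)
  best
}

# analytic per-capita birth rate and Jacobian of the Allee model
allee_percapita <- function(cfg) function(A) cfg$b * A / (A + cfg$h) * (1 - A / cfg$K)
allee_lambda <- function(cfg) {
  g <- allee_percapita(cfg)
  function(A, c) {
    h <- 1e-7
    Bp <- ((A + h) * g(A + h) - (A - h) * g(A - h)) / (2 * h)
    Bp - c
  }
}

# closed-form coexistence equilibrium of the food chain (independent of the
# package's internal helper: solved here from the nullclines directly)
chain_equilibrium <- function(cfg, mZ) {
  q <- mZ / cfg$e2
  if (q <= 0 || q >= cfg$a2) return(NULL)
  Y <- cfg$hY * sqrt(q / (cfg$a2 - q))
  X <- cfg$K * (1 - cfg$a1 * Y / cfg$r)
  if (X <= 0) return(NULL)
  Z <- Y * (cfg$e1 * cfg$a1 * X - cfg$mY) / q
  if (Z <= 0) return(NULL)
  c(X, Y, Z)
}

chain_jacobian_eigen <- function(cfg, state, mZ) {
  f <- food_chain_rhs(cfg)
  J <- pracma::jacobian(function(s) f(s, mZ), state)
  eigen(J, only.values = TRUE)$values
}

# small discrete-time model for balance tests: one stock with inferred
# recruitment, known linear mortality and an observed exogenous catch
mini_fishery_model <- function(mP = 0.1) {
  gm_model(
    variables = "P",
    processes = list(
      gm_process("recruitment", "gain", "P", depends_on = "P",
                 observability = "inferred_by_balance",
                 assumptions = list(P = "linear")),
      gm_process("natural_mortality", "loss", "P", depends_on = "P",
                 observability = "known_form",
                 form = list(kind = "linear", of = "P", rate = "mP")),
      gm_process("catch", "loss", "P", depends_on = character(),
                 observability = "observed")),
    time_mode = "discrete",
    known_constants = list(mP = mP))
}
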