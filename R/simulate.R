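# Stochastic simulators for the three test scenarios. Each integrates a
# fully specified model under a slow parameter ramp with additive noise,
# samples the observation channels a generalized model would see, and
# records ground truth: the fast-subsystem bifurcation point (by numerical
# continuation of the frozen system) and the collapse time.

#' Linear ramp schedule for a slowly drifting parameter
#'
#' The parameter is frozen at `start_value` before `start_time` and then
#' drifts linearly: `value(t) = start_value + rate * (t - start_time)`.
#'
#' @param parameter name of the ramped parameter.
#' @param start_value value at (and before) `start_time`.
#' @param rate change per year (finite; may be negative).
#' @param start_time time at which the drift begins (default 0).
#' @return object of class `gm_ramp`.
#' @export
ramp_schedule <- function(parameter, start_value, rate, start_time = 0) {
  if (!is.finite(rate)) gm_validation_error("ramp rate must be finite")
  structure(list(parameter = parameter, start_value = start_value,
                 rate = rate, start_time = start_time),
            class = "gm_ramp")
}

#' @rdname ramp_schedule
#' @param ramp a `gm_ramp`.
#' @param t time(s) at which to evaluate the ramp.
#' @export
ramp_value <- function(ramp, t) {
  ramp$start_value + ramp$rate * pmax(0, t - ramp$start_time)
}

# time at which the ramp reaches `value` (NA if never)
ramp_time_of <- function(ramp, value) {
  if (ramp$rate == 0) return(NA_real_)
  tt <- ramp$start_time + (value - ramp$start_value) / ramp$rate
  if (tt < ramp$start_time) NA_real_ else tt
}

# one independent N(0,1) stream per noise channel, derived from the master
# seed so that adding observation channels never perturbs process noise;
# the global RNG state is restored afterwards
channel_noise <- function(seed, channel_index, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  sub <- (as.numeric(seed) * 48271 + channel_index * 2654435) %% 2147483647
  set.seed(as.integer(sub))
  rnorm(n)
}

#' @export
print.gm_sim <- function(x, ...) {
  cat(sprintf("Simulation output (%s): %d dense points, %d observations\n",
              x$system, nrow(x$dense), length(x$observations$times)))
  if (!is.null(x$true_bifurcation)) {
    cat(sprintf("  true fast-subsystem bifurcation: %s = %.6g at t = %.4g\n",
                x$true_bifurcation$parameter, x$true_bifurcation$value,
                x$true_bifurcation$time))
  }
  cat(sprintf("  collapse time: %s", format(x$collapse_time)))
  if (!is.null(x$onset_time)) cat(sprintf("; oscillation onset: %s", format(x$onset_time)))
  cat("\n")
  invisible(x)
}

# --- Allee-effect population ----------------------------------------------

#' Configuration for the Allee-effect population simulator
#'
#' The model is `dA/dt = B(A) - c(t) * A + sigma * xi(t)` with the
#' Allee-type birth rate `B(A) = b * A^2 / (A + h) * (1 - A / K)`:
#' per-capita births rise with `A` at low density and the mortality is
#' exactly linear with a slowly rising coefficient `c(t)`, so the system
#' has a fold bifurcation at the maximum of the per-capita birth rate.
#'
#' @param b birth scale (1/yr).
#' @param h half-saturation of the Allee term (population units).
#' @param K carrying capacity (population units).
#' @param c0,c_rate,ramp_start mortality ramp `c(t)` (1/yr, 1/yr^2, yr).
#' @param sigma process noise standard deviation (population units per
#'   sqrt(yr)).
#' @param step Euler-Maruyama step (yr).
#' @param obs_times observation times (default 15 annual points).
#' @param obs_noise_sd observation noise on the sampled channels (default
#'   0: the recorded births are the exact yearly birth rate).
#' @param burn_in years simulated before `t = 0` at the frozen ramp value.
#' @param t_end end of the simulated span (yr).
#' @param init optional starting population (default: the upper
#'   equilibrium of the frozen system, found by root finding).
#' @param seed master seed; one named stream per noise channel is derived
#'   from it.
#' @return list of class `gm_allee_config`.
#' @export
allee_config <- function(b = 20, h = 0.2, K = 1, c0 = 8.337, c_rate = 0.005,
                         ramp_start = 0, sigma = 0.01, step = 1 / 64,
                         obs_times = 0:14, obs_noise_sd = 0, burn_in = 20,
                         t_end = 40, init = NULL, seed = 1) {
  stopifnot(b > 0, h > 0, K > 0, h < K, step > 0, burn_in >= 0)
  if (any(obs_times < -burn_in) || any(obs_times > t_end)) {
    gm_validation_error("observation times must lie within the simulated span")
  }
  structure(as.list(environment()), class = c("gm_allee_config", "gm_sim_config"))
}

# deterministic right-hand side of the Allee model, frozen mortality c
#' Deterministic skeletons of the simulators
#'
#' `allee_rhs`, `food_chain_rhs` and `fishery_annual_map` expose the
#' deterministic part of each simulator (the frozen fast subsystem) as a
#' function of state and the ramped parameter, for use with
#' [true_bifurcation_point()] and for analytic-Jacobian oracles.
#'
#' @param cfg the matching simulator configuration.
#' @return a function `f(state, parameter)` returning the time derivative
#'   (ODE systems) or the next state (the fishery's composed annual map).
#' @export
allee_rhs <- function(cfg = allee_config()) {
  function(A, c) {
    B <- cfg$b * A^2 / (A + cfg$h) * (1 - A / cfg$K)
    B - c * A
  }
}

#' Simulate an Allee-effect population under slowly rising mortality
#'
#' Fixed-step Euler-Maruyama integration with a reflecting floor at zero;
#' once a state is absorbed at zero its noise term is suppressed so the
#' population remains extinct. Observations record the population and the
#' yearly birth rate at the configured times.
#'
#' @param cfg an [allee_config()].
#' @return object of class `gm_sim` with elements `dense` (time, A),
#'   `observations` ([gm_observations()] with state `A` and rate
#'   `births`), `ramp_values`, `true_bifurcation` (parameter value and
#'   ramp time of the fold of the frozen system), `collapse_time` (first
#'   time `A` hits zero; `NA` if it never does), `seed`, `config`.
#' @examples
#' \donttest{
#' sim <- simulate_allee(allee_config(seed = 42))
#' sim$true_bifurcation$time < sim$collapse_time # bifurcation delay
#' }
#' @export
simulate_allee <- function(cfg = allee_config()) {
  stopifnot(inherits(cfg, "gm_allee_config"))
  ramp <- ramp_schedule("c", cfg$c0, cfg$c_rate, cfg$ramp_start)
  dt <- cfg$step
  n <- round((cfg$t_end + cfg$burn_in) / dt)
  times <- -cfg$burn_in + (0:n) * dt
  xi <- channel_noise(cfg$seed, 1L, n)
  birth <- function(A) cfg$b * A^2 / (A + cfg$h) * (1 - A / cfg$K)
  # start on the upper equilibrium branch of the frozen system
  g <- function(A) cfg$b * A / (A + cfg$h) * (1 - A / cfg$K)
  A0 <- cfg$init %||% tryCatch(stats::uniroot(function(A) g(A) - cfg$c0,
                                              c(cfg$K * 0.3, cfg$K), tol = 1e-12)$root,
                               error = function(e) cfg$K * 0.5)
  A <- numeric(n + 1); A[1] <- A0
  sqdt <- sqrt(dt)
  for (i in seq_len(n)) {
    a <- A[i]
    if (a <= 0) { A[i + 1] <- 0; next }
    drift <- (birth(a) - ramp_value(ramp, times[i]) * a) * dt
    if (abs(drift) > 0.5 * max(a, cfg$h)) {
      gm_numerical_error(sprintf(
        "integration step too large at t = %.3f (deterministic change %.3g vs state %.3g)",
        times[i], drift, a))
    }
    A[i + 1] <- max(0, a + drift + cfg$sigma * sqdt * xi[i])
  }
  obs_idx <- round((cfg$obs_times + cfg$burn_in) / dt) + 1L
  obs_times <- times[obs_idx] # snapped to the integration grid
  A_obs <- A[obs_idx]
  obs_sigma <- cfg$obs_noise_sd
  if (obs_sigma > 0) {
    A_obs <- pmax(0, A_obs + obs_sigma * channel_noise(cfg$seed, 2L, length(A_obs)))
  }
  B_obs <- birth(A_obs)
  tb <- tryCatch(
    true_bifurcation_point(allee_rhs(cfg),
                           par_range = c(cfg$c0, ramp_value(ramp, cfg$t_end)),
                           x0 = A0, time_mode = "continuous", ramp = ramp),
    gm_error = function(e) NULL)
  zero_idx <- which(A == 0 & times >= 0)
  structure(list(
    system = "allee",
    dense = data.frame(time = times, A = A),
    observations = gm_observations(obs_times,
                                   states = list(A = A_obs),
                                   rates = list(births = B_obs)),
    ramp_values = ramp_value(ramp, obs_times),
    ramp = ramp,
    true_bifurcation = tb,
    collapse_time = if (length(zero_idx)) times[zero_idx[1]] else NA_real_,
    onset_time = NULL,
    seed = cfg$seed, config = cfg), class = "gm_sim")
}

# --- tri-trophic food chain -----------------------------------------------

#' Configuration for the tri-trophic food-chain simulator
#'
#' Producer `X`, predator `Y` and top predator `Z`: logistic production,
#' mass-action grazing `a1 * X * Y`, a sigmoid (Holling type III)
#' per-capita top intake `a2 * Y^2 / (hY^2 + Y^2)`, linear intermediate
#' and top mortality, and a slow ramp on the top mortality `mZ(t)`.
#' Rising `mZ` releases the predator, and once its biomass passes the
#' inflection of the sigmoid response the predator/top-predator
#' interaction loses its stabilizing grip: the coexistence equilibrium
#' crosses a genuine Hopf bifurcation (complex-conjugate pair), growing
#' oscillations follow, and together with noise they carry the chain to
#' collapse.
#'
#' @param r,K producer growth rate (1/yr) and capacity.
#' @param a1 grazing (X -> Y) rate, mass-action (1/(biomass yr)).
#' @param a2,hY maximum per-capita top intake (1/yr) and the
#'   half-saturation biomass of the sigmoid response.
#' @param e1,e2 conversion efficiencies in (0, 1].
#' @param mY intermediate predator mortality (1/yr).
#' @param mZ0,mZ_rate,ramp_start top-mortality ramp.
#' @param sigma additive noise sd per state variable (length 3 or 1).
#' @param step Euler-Maruyama step (yr).
#' @param obs_dt observation spacing (yr).
#' @param burn_in,t_end simulated span around the ramp start.
#' @param init optional starting state (default: the coexistence
#'   equilibrium of the frozen system).
#' @param onset_window,onset_frac oscillation-onset detector: first time
#'   the producer deviates from its trailing `onset_window`-year linear
#'   fit by more than `onset_frac` times its mean pre-ramp level, i.e. the
#'   first clearly macroscopic departure from the drifting steady state.
#' @param seed master seed.
#' @return list of class `gm_food_chain_config`.
#' @export
food_chain_config <- function(r = 1, K = 2, a1 = 1.2, e1 = 0.6,
                              a2 = 1.5, hY = 0.15, e2 = 0.7, mY = 0.08,
                              mZ0 = 0.2, mZ_rate = 0.005, ramp_start = 0,
                              sigma = c(0.002, 0.002, 0.002), step = 1 / 64,
                              obs_dt = 1, burn_in = 30, t_end = 185,
                              onset_window = 10, onset_frac = 0.25,
                              init = NULL, seed = 1) {
  stopifnot(r > 0, K > 0, a1 > 0, a2 > 0, hY > 0, e1 > 0, e1 <= 1, e2 > 0,
            e2 <= 1, mY > 0, step > 0)
  sigma <- rep(sigma, length.out = 3L)
  structure(as.list(environment()), class = c("gm_food_chain_config", "gm_sim_config"))
}

#' @rdname allee_rhs
#' @export
food_chain_rhs <- function(cfg = food_chain_config()) {
  function(s, mZ) {
    X <- s[1]; Y <- s[2]; Z <- s[3]
    W1 <- cfg$a1 * X * Y
    W2 <- cfg$a2 * Y^2 / (cfg$hY^2 + Y^2) * Z
    c(cfg$r * X * (1 - X / cfg$K) - W1,
      cfg$e1 * W1 - W2 - cfg$mY * Y,
      cfg$e2 * W2 - mZ * Z)
  }
}

# coexistence equilibrium of the frozen food chain (sequential closed form)
food_chain_equilibrium <- function(cfg, mZ) {
  q <- mZ / cfg$e2
  if (q <= 0 || q >= cfg$a2) return(NULL)
  Y <- cfg$hY * sqrt(q / (cfg$a2 - q))
  X <- cfg$K * (1 - cfg$a1 * Y / cfg$r)
  if (X <= 0) return(NULL)
  Z <- Y * (cfg$e1 * cfg$a1 * X - cfg$mY) / q
  if (Z <= 0) return(NULL)
  c(X = X, Y = Y, Z = Z)
}

#' Simulate a tri-trophic food chain under rising top-predator mortality
#'
#' Euler-Maruyama integration of the [food_chain_rhs()] system with
#' additive noise per state; noise is suppressed for any variable after it
#' reaches zero, so extinct populations remain extinct. Observations
#' record the three biomasses and the top-predator mortality rate
#' `mZ(t) * Z(t)`.
#'
#' @param cfg a [food_chain_config()].
#' @return object of class `gm_sim`; `observations` carries states
#'   `X`, `Y`, `Z` and the rate channel `top_mortality`;
#'   `true_bifurcation` locates the Hopf point of the frozen system;
#'   `onset_time` is the oscillation-onset estimate and `collapse_time`
#'   the first extinction (both `NA` if not reached).
#' @export
simulate_food_chain <- function(cfg = food_chain_config()) {
  stopifnot(inherits(cfg, "gm_food_chain_config"))
  ramp <- ramp_schedule("mZ", cfg$mZ0, cfg$mZ_rate, cfg$ramp_start)
  dt <- cfg$step
  n <- round((cfg$t_end + cfg$burn_in) / dt)
  times <- -cfg$burn_in + (0:n) * dt
  rhs <- food_chain_rhs(cfg)
  xi <- vapply(1:3, function(j) channel_noise(cfg$seed, j, n), numeric(n))
  s0 <- cfg$init %||% food_chain_equilibrium(cfg, cfg$mZ0)
  if (is.null(s0)) {
    gm_numerical_error("no coexistence equilibrium at the ramp start value")
  }
  S <- matrix(0, n + 1L, 3L, dimnames = list(NULL, c("X", "Y", "Z")))
  S[1L, ] <- s0
  sqdt <- sqrt(dt)
  sig <- cfg$sigma
  for (i in seq_len(n)) {
    s <- S[i, ]
    drift <- rhs(s, ramp_value(ramp, times[i])) * dt
    too_big <- abs(drift) > 0.5 * pmax(s, 0.05) & s > 0
    if (any(too_big)) {
      gm_numerical_error(sprintf(
        "integration step too large at t = %.3f", times[i]))
    }
    s_new <- s + drift + sig * sqdt * xi[i, ] * (s > 0)
    s_new[s_new < 0 | s <= 0] <- 0
    S[i + 1L, ] <- s_new
  }
  obs_times <- seq(0, cfg$t_end, by = cfg$obs_dt)
  obs_idx <- round((obs_times + cfg$burn_in) / dt) + 1L
  obs_times <- times[obs_idx] # snapped to the integration grid
  mz_obs <- ramp_value(ramp, obs_times)
  tb <- tryCatch(
    true_bifurcation_point(rhs,
                           par_range = c(cfg$mZ0, ramp_value(ramp, cfg$t_end)),
                           x0 = s0, time_mode = "continuous", ramp = ramp),
    gm_error = function(e) NULL)
  ref_rows <- times >= cfg$ramp_start - 10 & times <= cfg$ramp_start
  onset <- oscillation_onset(times, S[, 1L], cfg$onset_window,
                             cfg$onset_frac * mean(S[ref_rows, 1L]),
                             from = cfg$ramp_start)
  zero_rows <- which(apply(S == 0, 1L, any) & times >= 0)
  structure(list(
    system = "food_chain",
    dense = data.frame(time = times, X = S[, 1], Y = S[, 2], Z = S[, 3]),
    observations = gm_observations(obs_times,
                                   states = list(X = S[obs_idx, 1],
                                                 Y = S[obs_idx, 2],
                                                 Z = S[obs_idx, 3]),
                                   rates = list(top_mortality = mz_obs * S[obs_idx, 3])),
    ramp_values = mz_obs,
    ramp = ramp,
    true_bifurcation = tb,
    collapse_time = if (length(zero_rows)) times[zero_rows[1]] else NA_real_,
    onset_time = onset,
    seed = cfg$seed, config = cfg), class = "gm_sim")
}

# first time the series deviates from its trailing linear fit by more than
# `threshold`: rolling OLS over fixed-length windows via cumulative sums
oscillation_onset <- function(times, x, window_years, threshold, from = 0) {
  dt <- times[2] - times[1]
  m <- max(4L, round(window_years / dt))
  n <- length(x)
  if (n <= m) return(NA_real_)
  cs <- cumsum(x)
  cjx <- cumsum(seq_along(x) * x)
  ends <- (m + 1L):n
  Sx <- cs[ends] - cs[ends - m]
  Sjx <- (cjx[ends] - cjx[ends - m]) - (ends - m) * Sx # positions 1..m
  xbar <- Sx / m
  Dm <- m * (m^2 - 1) / 12
  b_rel <- (Sjx - (m + 1) / 2 * Sx) / Dm
  fit_end <- xbar + b_rel * (m - 1) / 2
  resid <- x[ends] - fit_end
  hit <- which(abs(resid) > threshold & times[ends] >= from)
  if (length(hit)) times[ends[hit[1]]] else NA_real_
}

# --- fishery (annual map with hidden juvenile stage) ----------------------

#' Configuration for the detailed fishery simulator
#'
#' A three-state annual stock model in the spirit of whole-lake piscivore/
#' planktivore systems: adult piscivores `A`, juveniles `J` (hidden from
#' the observer) and planktivores `F`. Within each year the planktivore
#' pool follows `dF/dt = fin + rF * F * (1 - F / KF) - a * F * A`
#' (refuge influx, logistic growth, predation by adults), integrated with
#' `q` deterministic Euler substeps. At the year boundary juveniles mature
#' with survival `hJ / (hJ + F + cJA * A)` (foraging-arena predation by
#' planktivores plus cannibalism), adults suffer natural mortality `mP`
#' and harvest `h(t)`, and reproduce a new juvenile cohort `rP * A`.
#' Ramping the harvest fraction collapses the high-piscivore state in a
#' fold of the annual map. The observer sees only end-of-year `P` (= `A`),
#' `F` and the catch `H = h * A` -- neither the juvenile stage nor the
#' intra-annual dynamics, the deliberate structural mismatch with the
#' two-variable generalized model.
#'
#' @param mP adult natural mortality (fraction per yr).
#' @param rP reproduction rate (juveniles per adult per yr).
#' @param hJ juvenile survival half-saturation (planktivore units).
#' @param cJA cannibalism weight of adults in the juvenile survival term.
#' @param fin refuge influx (planktivore biomass/yr).
#' @param rF,KF planktivore growth rate (1/yr) and capacity.
#' @param a adult predation rate on planktivores (1/(piscivore yr)).
#' @param h0,h_rate,ramp_start harvest-fraction ramp (`h` in [0, 1)).
#' @param q intra-annual Euler substeps (>= 1).
#' @param sigma_P,sigma_F annual additive process noise sd.
#' @param years number of observed years (annual observations at
#'   `t = 0 .. years - 1`).
#' @param burn_in years at the frozen `h0` before observations start.
#' @param seed master seed.
#' @return list of class `gm_fishery_config`.
#' @export
fishery_config <- function(mP = 0.1, rP = 0.9, hJ = 0.3, cJA = 0.5,
                           fin = 0.05, rF = 1, KF = 1, a = 1,
                           h0 = 0, h_rate = 0.005, ramp_start = 0, q = 12,
                           sigma_P = 0.05, sigma_F = 0.005,
                           years = 80, burn_in = 15, seed = 1) {
  stopifnot(q >= 1, mP > 0, mP < 1, rP > 0, hJ > 0, fin >= 0, rF > 0, KF > 0,
            a > 0, h0 >= 0, h0 < 1, years >= 4)
  structure(as.list(environment()), class = c("gm_fishery_config", "gm_sim_config"))
}

#' @rdname allee_rhs
#' @export
fishery_annual_map <- function(cfg = fishery_config()) {
  function(s, h) {
    A <- s[1]; J <- s[2]; F_ <- s[3]
    dt <- 1 / cfg$q
    for (i in seq_len(cfg$q)) {
      F_ <- F_ + dt * (cfg$fin + cfg$rF * F_ * (1 - F_ / cfg$KF) - cfg$a * F_ * A)
      if (F_ < 0) F_ <- 0
    }
    srv <- cfg$hJ / (cfg$hJ + F_ + cfg$cJA * A)
    A2 <- A * (1 - cfg$mP - h) + J * srv
    c(max(A2, 0), cfg$rP * A, F_)
  }
}

#' Simulate the detailed fishery model under a harvest ramp
#'
#' See [fishery_config()] for the model. Observations expose only the
#' end-of-year adult piscivore stock `P`, the planktivore biomass `F` and
#' the annual catch `H` (recorded at the year in which it is taken, i.e.
#' the start of the annual step it enters).
#'
#' @param cfg a [fishery_config()].
#' @return object of class `gm_sim`; `dense` holds the yearly states
#'   including the hidden juvenile pool; `true_bifurcation` locates the
#'   fold (unit-eigenvalue crossing) of the frozen annual map;
#'   `collapse_time` is the first year the adult stock hits zero.
#' @export
simulate_fishery <- function(cfg = fishery_config()) {
  stopifnot(inherits(cfg, "gm_fishery_config"))
  ramp <- ramp_schedule("h", cfg$h0, cfg$h_rate, cfg$ramp_start)
  step <- fishery_annual_map(cfg)
  # deterministic fixed point at the frozen harvest as starting state
  s <- c(2, 1.8, 0.05)
  for (i in 1:500) s <- step(s, cfg$h0)
  years_all <- seq(-cfg$burn_in, cfg$years - 1)
  nY <- length(years_all)
  xiP <- channel_noise(cfg$seed, 1L, nY)
  xiF <- channel_noise(cfg$seed, 2L, nY)
  S <- matrix(0, nY, 3L, dimnames = list(NULL, c("A", "J", "F")))
  H <- numeric(nY)
  for (i in seq_len(nY)) {
    t <- years_all[i]
    h_t <- ramp_value(ramp, t)
    if (h_t >= 1) gm_validation_error("harvest fraction reached 1 during the run")
    S[i, ] <- s
    H[i] <- h_t * s[1]
    s <- step(s, h_t)
    if (s[1] > 0) s[1] <- max(0, s[1] + cfg$sigma_P * xiP[i])
    s[3] <- max(0, s[3] + cfg$sigma_F * xiF[i])
  }
  obs_sel <- years_all >= 0
  tb <- tryCatch(
    true_bifurcation_point(step,
                           par_range = c(cfg$h0, ramp_value(ramp, cfg$years)),
                           x0 = S[1, ], time_mode = "discrete", ramp = ramp,
                           min_state = 1e-4),
    gm_error = function(e) NULL)
  zero_idx <- which(S[, 1] == 0 & years_all >= 0)
  structure(list(
    system = "fishery",
    dense = data.frame(time = years_all, A = S[, 1], J = S[, 2], F = S[, 3],
                       catch = H),
    observations = gm_observations(years_all[obs_sel],
                                   states = list(P = S[obs_sel, 1],
                                                 F = S[obs_sel, 3]),
                                   rates = list(catch = H[obs_sel])),
    ramp_values = ramp_value(ramp, years_all[obs_sel]),
    ramp = ramp,
    true_bifurcation = tb,
    collapse_time = if (length(zero_idx)) years_all[zero_idx[1]] else NA_real_,
    onset_time = NULL,
    seed = cfg$seed, config = cfg), class = "gm_sim")
}
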