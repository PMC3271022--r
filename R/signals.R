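# From Jacobian trajectories to warnings: eigenvalue tracking, spurious
# branch exclusion, trend quantification, transition typing, and the
# statistical (variance / autocorrelation) baselines.

#' Track eigenvalue branches through a Jacobian series
#'
#' Index-aligns the eigenvalues of consecutive Jacobian estimates by
#' sequentially solving the optimal-assignment problem
#' ([match_eigenvalues()]), so each column of the result is a coherent
#' eigenvalue branch over time. Ordering at the first time point follows
#' the deterministic sort (descending real part for ODEs, descending
#' modulus for maps).
#'
#' @param x a `gm_jacobian_series` from [estimate_jacobian_series()], or a
#'   plain list of `gm_jacobian` objects of equal dimension (at least 2).
#' @return object of class `gm_eigen_trajectory`: `times`, complex matrix
#'   `eigenvalues` (time by branch), `time_mode`, `excluded` (empty).
#' @export
track_eigenvalues <- function(x) {
  jacobians <- if (inherits(x, "gm_jacobian_series")) x$jacobians else x
  if (length(jacobians) < 2L) {
    gm_usage_error("tracking needs at least two Jacobian estimates")
  }
  dims <- vapply(jacobians, function(j) nrow(j$matrix), integer(1))
  if (length(unique(dims)) != 1L) {
    gm_usage_error("Jacobian estimates have mismatched dimensions")
  }
  n <- dims[1]
  time_mode <- jacobians[[1]]$time_mode
  times <- vapply(jacobians, `[[`, numeric(1), "time")
  ev <- matrix(complex(1), length(jacobians), n)
  ev[1, ] <- jacobians[[1]]$eigenvalues
  for (i in seq_along(jacobians)[-1]) {
    cur <- jacobians[[i]]$eigenvalues
    perm <- match_eigenvalues(ev[i - 1L, ], cur)
    ev[i, ] <- cur[perm]
  }
  structure(list(times = times, eigenvalues = ev, time_mode = time_mode,
                 excluded = integer()),
            class = "gm_eigen_trajectory")
}

#' @export
print.gm_eigen_trajectory <- function(x, ...) {
  cat(sprintf("Eigenvalue trajectory: %d branches over %d times [%g, %g]",
              ncol(x$eigenvalues), nrow(x$eigenvalues),
              min(x$times), max(x$times)))
  if (length(x$excluded)) {
    cat(sprintf("; excluded branch(es): %s", paste(x$excluded, collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' Exclude spurious eigenvalue branches
#'
#' Noisy estimation can produce an eigenvalue branch that carries no
#' dynamical signal -- typically a purely real branch whose estimate
#' jitters wildly (in the food-chain setting, the fast response of the
#' producer to fluctuations on higher trophic levels). The rule removes a
#' real branch whose temporal variance of the real part is at least
#' `variance_ratio` times the median branch variance.
#'
#' Because such a jittery real eigenvalue can leapfrog the ordered
#' branches from one time to the next, a three-dimensional trajectory is
#' first re-threaded per time point into its natural spectral streams
#' (a real 3x3 matrix has either one conjugate pair plus one real
#' eigenvalue, or three real eigenvalues, in which case the one closest to
#' the running real stream is assigned to it); the variance rule is then
#' applied to the re-threaded streams. Other dimensions use the tracked
#' columns directly.
#'
#' @param traj a `gm_eigen_trajectory` with more than one branch.
#' @param variance_ratio relative-variance threshold (default 5).
#' @param iota_min eigenvalues with |Im| below this are considered real.
#' @return the trajectory with spurious branches removed and their column
#'   indices recorded in `$excluded`.
#' @export
exclude_spurious <- function(traj, variance_ratio = 5, iota_min = 1e-3) {
  stopifnot(inherits(traj, "gm_eigen_trajectory"))
  n <- ncol(traj$eigenvalues)
  if (n <= 1L) gm_usage_error("exclusion needs more than one branch")
  ev <- traj$eigenvalues
  m <- nrow(ev)
  if (n == 3L) {
    # re-thread: [pair+, pair-, real] per time
    streams <- matrix(complex(1), m, 3L)
    real_prev <- NA_complex_
    for (i in seq_len(m)) {
      v <- ev[i, ]
      cplx <- which(abs(Im(v)) > iota_min)
      if (length(cplx) == 2L) {
        r <- v[-cplx]
      } else {
        # three (near-)real values: the real stream keeps continuity
        vr <- Re(v)
        j <- if (is.na(real_prev)) which.min(vr) else which.min(abs(vr - Re(real_prev)))
        r <- v[j]
        cplx <- setdiff(1:3, j)
      }
      pp <- v[cplx]
      pp <- pp[order(-Im(pp))]
      streams[i, ] <- c(pp, r)
      real_prev <- r
    }
    re_var <- apply(streams, 2L, function(b) stats::var(Re(b)))
    is_real <- c(FALSE, FALSE, TRUE)
    med <- stats::median(re_var)
    if (med > 0 && re_var[3] >= variance_ratio * med) {
      traj$eigenvalues <- streams[, 1:2, drop = FALSE]
      traj$excluded <- c(traj$excluded, 3L)
      return(traj)
    }
    traj$eigenvalues <- streams
    return(traj)
  }
  re_var <- apply(ev, 2L, function(b) stats::var(Re(b)))
  is_real <- apply(ev, 2L, function(b) max(abs(Im(b))) <= iota_min)
  med <- stats::median(re_var)
  spurious <- which(is_real & re_var >= variance_ratio * med & med > 0)
  if (length(spurious) == n) {
    gm_usage_error("exclusion rule would remove every branch")
  }
  if (!length(spurious)) return(traj)
  traj$eigenvalues <- traj$eigenvalues[, -spurious, drop = FALSE]
  traj$excluded <- c(traj$excluded, spurious)
  traj
}

#' Kendall rank-correlation trend of a series against time
#'
#' The standard trend measure for early-warning indicators: invariant
#' under strictly increasing transformations of the values, in `[-1, 1]`,
#' `0` for a constant series.
#'
#' @param values numeric vector.
#' @param times optional time stamps (default: observation order).
#' @return Kendall's tau (0 when the series is constant).
#' @export
kendall_trend <- function(values, times = seq_along(values)) {
  if (length(values) < 2L || stats::sd(values) == 0) return(0)
  suppressWarnings(stats::cor(times, values, method = "kendall"))
}

#' Raise a warning when eigenvalues trend towards the stability boundary
#'
#' Computes the stability margin (distance of the dominant eigenvalue from
#' the boundary; [classify_stability()]) at every time point, its Kendall
#' trend over a trailing assessment window, and raises a warning at the
#' first time where both (i) the trend is at most `-tau_crit` (a clear
#' approach to the boundary) and (ii) the current margin has dropped to at
#' most `rho` times the first margin. The scan over expanding prefixes is
#' causal: truncating the trajectory after the warning time does not
#' change it.
#'
#' @param traj a `gm_eigen_trajectory` (at least 4 time points after any
#'   exclusion).
#' @param tau_crit trend threshold in (0, 1]; default 0.6.
#' @param rho margin-drop fraction in (0, 1]; default 0.5.
#' @param window trailing assessment window in time points (`NULL`: all
#'   points available at assessment time).
#' @param iota_min imaginary-part tolerance used when typing the
#'   transition.
#' @return object of class `gm_warning_report`: `times`, `margin_series`,
#'   `trend_statistic` (at the warning time if one fired, else over the
#'   final window), `warning`, `warning_time` (`NA` if none),
#'   `transition_type` (`"real_crossing"`, `"hopf_pair"`, or `"none"` when
#'   no warning fired), `excluded_indices`, and the thresholds used.
#' @export
warning_report <- function(traj, tau_crit = 0.6, rho = 0.5, window = NULL,
                           iota_min = 1e-3) {
  stopifnot(inherits(traj, "gm_eigen_trajectory"))
  m <- nrow(traj$eigenvalues)
  if (m < 4L) gm_usage_error("warning assessment needs at least 4 time points")
  margins <- vapply(seq_len(m), function(i) {
    classify_stability(traj$eigenvalues[i, ], traj$time_mode)$margin
  }, numeric(1))
  first_margin <- margins[1]
  tau_at <- function(i) {
    lo <- if (is.null(window)) 1L else max(1L, i - as.integer(window) + 1L)
    kendall_trend(margins[lo:i], traj$times[lo:i])
  }
  warning_time <- NA_real_
  trend_at_warning <- NA_real_
  fired_at <- NA_integer_
  for (i in 4L:m) {
    tau <- tau_at(i)
    if (is.na(tau)) next
    if (tau <= -tau_crit && margins[i] <= rho * first_margin) {
      warning_time <- traj$times[i]
      trend_at_warning <- tau
      fired_at <- i
      break
    }
  }
  fired <- !is.na(warning_time)
  # the transition is typed from what is known when the warning is raised
  # (trajectory truncated at the warning time), keeping the report causal
  type <- if (fired) {
    truncated <- traj
    truncated$eigenvalues <- traj$eigenvalues[seq_len(fired_at), , drop = FALSE]
    truncated$times <- traj$times[seq_len(fired_at)]
    classify_transition(truncated, iota_min)
  } else "none"
  structure(list(times = traj$times, margin_series = margins,
                 trend_statistic = if (fired) trend_at_warning else tau_at(m),
                 warning = fired, warning_time = warning_time,
                 transition_type = type,
                 excluded_indices = traj$excluded,
                 time_mode = traj$time_mode,
                 tau_crit = tau_crit, rho = rho, window = window,
                 iota_min = iota_min),
            class = "gm_warning_report")
}

#' @export
print.gm_warning_report <- function(x, ...) {
  if (x$warning) {
    cat(sprintf("WARNING raised at t = %g (%s): margin %.4g -> %.4g, trend %.3f\n",
                x$warning_time, x$transition_type, x$margin_series[1],
                x$margin_series[length(x$margin_series)], x$trend_statistic))
  } else {
    cat(sprintf("no warning (trend %.3f, margin %.4g -> %.4g)\n",
                x$trend_statistic, x$margin_series[1],
                x$margin_series[length(x$margin_series)]))
  }
  invisible(x)
}

#' @export
as.data.frame.gm_warning_report <- function(x, ...) {
  data.frame(time = x$times, margin = x$margin_series,
             warning = !is.na(x$warning_time) & x$times >= x$warning_time,
             transition_type = x$transition_type)
}

#' Classify the type of the impending transition
#'
#' Looks at the dominant (closest-to-boundary) branch at the latest time:
#' a complex-conjugate pair (|Im| above `iota_min`, with its mirror branch
#' present) indicates a Hopf bifurcation -- a transition from stationary
#' to oscillatory dynamics -- while a real dominant branch indicates a
#' real-eigenvalue crossing (fold-like transition, or unit-modulus
#' crossing for maps).
#'
#' @param traj a `gm_eigen_trajectory`.
#' @param iota_min imaginary-part tolerance (default 1e-3).
#' @return `"hopf_pair"`, `"real_crossing"` or `"none"`.
#' @export
classify_transition <- function(traj, iota_min = 1e-3) {
  stopifnot(inherits(traj, "gm_eigen_trajectory"))
  last <- traj$eigenvalues[nrow(traj$eigenvalues), ]
  key <- if (traj$time_mode == "discrete") Mod(last) else Re(last)
  dom <- last[which.max(key)]
  if (abs(Im(dom)) > iota_min) {
    has_partner <- any(Mod(last - Conj(dom)) <=
                         max(1e-8, 1e-6 * Mod(dom)) & seq_along(last) != which.max(key))
    if (has_partner) "hopf_pair" else "none"
  } else {
    "real_crossing"
  }
}

#' Rolling statistical early-warning baselines
#'
#' Classic model-free indicators of critical slowing down, computed over
#' trailing windows for comparison with the generalized-model signal:
#' sample variance, or lag-1 autocorrelation (Pearson correlation of the
#' window against itself shifted by one step), after optional within-window
#' linear detrending.
#'
#' @param series numeric vector.
#' @param statistic `"variance"` or `"lag1_autocorrelation"`.
#' @param window trailing window length (>= 3 for variance, >= 4 for
#'   autocorrelation; at most the series length).
#' @param detrending `"none"` or `"linear"` (within-window).
#' @param times optional time stamps aligned with `series`.
#' @return object of class `gm_baseline`: `values` (one per trailing
#'   window, length `length(series) - window + 1`), `end_times`, `window`,
#'   `statistic`, `detrending`.
#' @export
rolling_baseline <- function(series,
                             statistic = c("variance", "lag1_autocorrelation"),
                             window, detrending = c("none", "linear"),
                             times = seq_along(series)) {
  statistic <- match.arg(statistic)
  detrending <- match.arg(detrending)
  window <- as.integer(window)
  min_w <- if (statistic == "variance") 3L else 4L
  if (window < min_w) {
    gm_usage_error(sprintf("window must be >= %d for %s", min_w, statistic))
  }
  n <- length(series)
  if (window > n) gm_usage_error("window exceeds series length")
  stat_fun <- function(w) {
    if (detrending == "linear") {
      idx <- seq_along(w)
      w <- stats::residuals(stats::lm(w ~ idx))
    }
    if (statistic == "variance") {
      stats::var(w)
    } else {
      a <- w[-length(w)]; b <- w[-1]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
      stats::cor(a, b)
    }
  }
  ends <- window:n
  values <- vapply(ends, function(e) stat_fun(series[(e - window + 1L):e]),
                   numeric(1))
  structure(list(values = values, end_times = times[ends], window = window,
                 statistic = statistic, detrending = detrending),
            class = "gm_baseline")
}

#' @export
print.gm_baseline <- function(x, ...) {
  cat(sprintf("Rolling %s (window %d, detrending %s): %d values\n",
              x$statistic, x$window, x$detrending, length(x$values)))
  invisible(x)
}

#' Grid search for initially stable parameterizations
#'
#' When some rate constants of a generalized model are only weakly known,
#' a practical heuristic fixes them by requiring that the system's initial
#' state -- before any transition -- be dynamically stable. This function
#' evaluates a grid over the supplied constant ranges, estimates the
#' Jacobian from the first admissible stretch of the observations for each
#' combination, and returns the combinations whose initial Jacobian is
#' stable (all eigenvalue moduli < 1 for maps, all real parts < 0 for
#' ODEs).
#'
#' @param model a [gm_model()].
#' @param ranges named list of numeric vectors (grid values per known
#'   constant).
#' @param obs a [gm_observations()] covering the initial (pre-transition)
#'   period; only the first `use_points` observations are used.
#' @param use_points number of leading observations used (default 8, or
#'   fewer if the series is shorter).
#' @param smoothing optional smoothing window passed to the estimator.
#' @return data.frame with one row per stable grid point (constant values,
#'   `margin` of the first Jacobian estimate); zero rows with attribute
#'   `message = "no stable parameterization in range"` when none is
#'   stable.
#' @export
initial_stability_search <- function(model, ranges, obs, use_points = 8L,
                                     smoothing = NULL) {
  stopifnot(inherits(model, "gm_model"), inherits(obs, "gm_observations"))
  if (!length(ranges) || is.null(names(ranges))) {
    gm_usage_error("ranges must be a named list of grid values")
  }
  n_use <- min(length(obs$times), max(4L, use_points))
  head_obs <- gm_observations(obs$times[seq_len(n_use)],
                              states = lapply(obs$states, head, n_use),
                              rates = lapply(obs$rates, head, n_use))
  grid <- expand.grid(ranges, KEEP.OUT.ATTRS = FALSE)
  keep <- logical(nrow(grid))
  margins <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    m <- model
    for (cn in names(ranges)) m$known_constants[[cn]] <- grid[i, cn]
    js <- tryCatch(
      estimate_jacobian_series(m, head_obs, smoothing = smoothing),
      gm_error = function(e) NULL)
    if (is.null(js) || !length(js$jacobians)) next
    verdict <- classify_stability(js$jacobians[[1]]$eigenvalues, m$time_mode)
    keep[i] <- verdict$stable
    margins[i] <- verdict$margin
  }
  out <- cbind(grid[keep, , drop = FALSE], margin = margins[keep])
  rownames(out) <- NULL
  if (!nrow(out)) attr(out, "message") <- "no stable parameterization in range"
  out
}

#' Warning time of a statistical baseline indicator
#'
#' The mirror image of the eigenvalue-margin rule in [warning_report()]
#' for indicators that *rise* towards a transition (variance, lag-1
#' autocorrelation): scanning expanding prefixes of the baseline series, a
#' warning is declared at the first window end where the Kendall trend is
#' at least `tau_crit` and the current value has grown to at least
#' `1 / rho` times the first value.
#'
#' The growth reference is the running median of all earlier values --
#' a single window's variance estimate is far too noisy (a handful of
#' degrees of freedom) to anchor the comparison.
#'
#' @param baseline a `gm_baseline` from [rolling_baseline()].
#' @param tau_crit trend threshold (default 0.6).
#' @param rho growth threshold, as in [warning_report()] (default 0.5,
#'   i.e. a doubling over the running median).
#' @param trend_window number of most recent baseline values over which
#'   the Kendall trend is assessed (default 15), the usual rolling-window
#'   trend assessment for statistical indicators.
#' @param min_points baseline values required before the scan may fire
#'   (default 8): a single window's variance estimate has only a few
#'   degrees of freedom, so the reference history must be long enough to
#'   be meaningful.
#' @return the warning time, or `NA` if the indicator never fires.
#' @export
baseline_warning_time <- function(baseline, tau_crit = 0.6, rho = 0.5,
                                  trend_window = 15L, min_points = 8L) {
  stopifnot(inherits(baseline, "gm_baseline"))
  v <- baseline$values
  tt <- baseline$end_times
  if (length(v) < min_points) return(NA_real_)
  for (i in max(4L, min_points):length(v)) {
    lo <- max(1L, i - as.integer(trend_window) + 1L)
    tau <- kendall_trend(v[lo:i], tt[lo:i])
    ref <- stats::median(v[1:(i - 1L)])
    if (!is.na(tau) && tau >= tau_crit && v[i] >= ref / rho) {
      return(tt[i])
    }
  }
  NA_real_
}
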