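# The user-facing fit: estimate -> track -> (exclude) -> warn.

#' Fit a generalized-model early-warning signal
#'
#' Runs the full pipeline: validates identifiability of `model` against
#' the observation channels, optionally smooths the observations,
#' estimates the Jacobian at every admissible observation time
#' ([estimate_jacobian_series()]), tracks the eigenvalue branches
#' ([track_eigenvalues()]), optionally removes spurious branches
#' ([exclude_spurious()]), and assesses the warning
#' ([warning_report()]).
#'
#' @param model a [gm_model()] (or path to a model YAML file).
#' @param observations a [gm_observations()] (or path to a CSV file; state
#'   columns are taken from the model's variables).
#' @param smoothing trailing moving-average window applied to all channels
#'   before estimation (`NULL` = none).
#' @param exclude drop spurious (high-variance purely real) eigenvalue
#'   branches before the warning assessment; only relevant for dimension
#'   greater than one.
#' @param tau_crit,rho,window,iota_min warning thresholds, see
#'   [warning_report()].
#' @param variance_ratio threshold of [exclude_spurious()].
#' @param floor finite-difference spacing floor, see
#'   [estimate_jacobian_series()].
#' @return an object of class `gm_ews` with components `model`,
#'   `observations`, `series` (the `gm_jacobian_series`), `trajectory`
#'   (the possibly pruned `gm_eigen_trajectory`), `report` (the
#'   `gm_warning_report`) and `call`. Methods: `print`, `summary`,
#'   `coef` (the latest Jacobian estimate), `plot` (margin and eigenvalue
#'   branches).
#' @examples
#' \donttest{
#' sim <- simulate_allee(allee_config(seed = 3))
#' fit <- gm_ews(allee_model(), sim$observations)
#' fit
#' }
#' @export
gm_ews <- function(model, observations, smoothing = NULL, exclude = TRUE,
                   tau_crit = 0.6, rho = 0.5, window = NULL, iota_min = 1e-3,
                   variance_ratio = 5, floor = default_spacing_floor) {
  if (is.character(model)) model <- read_model(model)
  if (is.character(observations)) {
    observations <- read_observations(observations, state_names = model$variables)
  }
  series <- estimate_jacobian_series(model, observations, smoothing = smoothing,
                                     floor = floor)
  if (length(series$jacobians) < 4L) {
    gm_usage_error(sprintf(
      "only %d Jacobian estimates are available; the warning assessment needs at least 4",
      length(series$jacobians)))
  }
  traj <- track_eigenvalues(series)
  if (exclude && ncol(traj$eigenvalues) > 1L) {
    traj <- exclude_spurious(traj, variance_ratio = variance_ratio,
                             iota_min = iota_min)
  }
  report <- warning_report(traj, tau_crit = tau_crit, rho = rho,
                           window = window, iota_min = iota_min)
  structure(list(model = model, observations = observations, series = series,
                 trajectory = traj, report = report, smoothing = smoothing,
                 call = match.call()),
            class = "gm_ews")
}

#' @export
print.gm_ews <- function(x, ...) {
  cat("Generalized-model early-warning fit\n")
  cat(sprintf("  %d Jacobian estimates (%s time), %d eigenvalue branch(es)",
              length(x$series$jacobians), x$model$time_mode,
              ncol(x$trajectory$eigenvalues)))
  if (length(x$trajectory$excluded)) {
    cat(sprintf(" after excluding %d spurious", length(x$trajectory$excluded)))
  }
  cat("\n  ")
  print(x$report)
  invisible(x)
}

#' @export
summary.gm_ews <- function(object, ...) {
  r <- object$report
  out <- list(
    n_estimates = length(object$series$jacobians),
    n_skipped = nrow(object$series$skipped),
    time_mode = object$model$time_mode,
    excluded_branches = object$trajectory$excluded,
    first_margin = r$margin_series[1],
    last_margin = r$margin_series[length(r$margin_series)],
    trend_statistic = r$trend_statistic,
    warning = r$warning,
    warning_time = r$warning_time,
    transition_type = r$transition_type,
    negative_rate_flags = lengths(object$series$negative_rate_flags))
  class(out) <- "summary.gm_ews"
  out
}

#' @export
print.summary.gm_ews <- function(x, ...) {
  cat(sprintf("gm_ews fit (%s time): %d estimates (%d skipped)\n",
              x$time_mode, x$n_estimates, x$n_skipped))
  cat(sprintf("  margin: %.4g -> %.4g; trend statistic: %.3f\n",
              x$first_margin, x$last_margin, x$trend_statistic))
  if (length(x$excluded_branches)) {
    cat("  excluded branch indices:", paste(x$excluded_branches, collapse = ", "), "\n")
  }
  if (x$warning) {
    cat(sprintf("  WARNING at t = %g, transition type: %s\n",
                x$warning_time, x$transition_type))
  } else {
    cat("  no warning raised\n")
  }
  if (length(x$negative_rate_flags) && any(x$negative_rate_flags > 0)) {
    cat("  negative inferred-rate flags:",
        paste(sprintf("%s(%d)", names(x$negative_rate_flags),
                      x$negative_rate_flags), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.gm_ews <- function(object, ...) {
  jj <- object$series$jacobians
  jj[[length(jj)]]$matrix
}

#' Plot a generalized-model early-warning fit
#'
#' Two panels: the stability margin over time (with the warning time, if
#' any, marked), and the real parts of the tracked eigenvalue branches
#' with the stability boundary.
#'
#' @param x a `gm_ews` fit.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.gm_ews <- function(x, ...) {
  r <- x$report
  old <- par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(par(old))
  plot(r$times, r$margin_series, type = "b", pch = 16, cex = 0.7,
       xlab = "time (yr)", ylab = "stability margin",
       main = "distance to stability boundary", ...)
  abline(h = 0, lty = 2)
  if (r$warning) abline(v = r$warning_time, col = 2, lty = 3)
  ev <- x$trajectory$eigenvalues
  show <- if (x$model$time_mode == "discrete") Mod(ev) else Re(ev)
  matplot(x$trajectory$times, show, type = "b", pch = 1, cex = 0.6, lty = 1,
          xlab = "time (yr)",
          ylab = if (x$model$time_mode == "discrete") "|eigenvalue|" else "Re(eigenvalue)",
          main = "tracked eigenvalue branches")
  abline(h = if (x$model$time_mode == "discrete") 1 else 0, lty = 2)
  invisible(x)
}
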