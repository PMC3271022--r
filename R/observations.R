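# Observation series: time-stamped states and process-rate channels.

#' Construct an observation series
#'
#' Holds regularly or irregularly sampled observations of the state
#' variables (population sizes or biomasses) and of observable process
#' rates (e.g. yearly births, annual catch, top-predator mortality). For
#' continuous-time models rates are in state units per year; for
#' discrete-time models a rate recorded at time `t` refers to the annual
#' step from `t` to `t + 1`.
#'
#' @param times strictly increasing numeric vector (years).
#' @param states named list of numeric vectors (one per state variable),
#'   all the same length as `times`, non-negative.
#' @param rates named list of numeric vectors (one per observed process),
#'   same length as `times`.
#' @return object of class `gm_observations`.
#' @export
gm_observations <- function(times, states, rates = list()) {
  times <- as.numeric(times)
  if (length(times) < 2L) gm_validation_error("need at least two observations")
  if (any(!is.finite(times)) || any(diff(times) <= 0)) {
    bad <- which(c(FALSE, diff(times) <= 0) | !is.finite(times))[1]
    gm_validation_error(sprintf(
      "times must be finite and strictly increasing (violated at row %d)", bad))
  }
  check_channel <- function(x, nm, kind) {
    if (length(x) != length(times)) {
      gm_validation_error(sprintf(
        "%s channel '%s' has length %d but there are %d times",
        kind, nm, length(x), length(times)))
    }
    if (any(is.na(x))) {
      gm_validation_error(sprintf(
        "%s channel '%s': missing value at row %d", kind, nm, which(is.na(x))[1]))
    }
    if (kind == "state" && any(x < 0)) {
      gm_validation_error(sprintf(
        "state channel '%s': negative value at row %d", nm, which(x < 0)[1]))
    }
    as.numeric(x)
  }
  states <- mapply(check_channel, states, names(states),
                   MoreArgs = list(kind = "state"), SIMPLIFY = FALSE)
  rates <- mapply(check_channel, rates, names(rates) %||% character(),
                  MoreArgs = list(kind = "rate"), SIMPLIFY = FALSE)
  structure(list(times = times, states = states, rates = rates),
            class = "gm_observations")
}

#' @export
print.gm_observations <- function(x, ...) {
  cat(sprintf("Observation series: %d time points on [%g, %g]\n",
              length(x$times), min(x$times), max(x$times)))
  cat("  states:", paste(names(x$states), collapse = ", "), "\n")
  if (length(x$rates)) cat("  rates: ", paste(names(x$rates), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.gm_observations <- function(x, ...) {
  data.frame(time = x$times, as.data.frame(x$states),
             as.data.frame(x$rates), check.names = FALSE)
}

#' Read or write observations as CSV
#'
#' The file has a header row with a `time` column, one column per state
#' variable and one per observed rate. Values are written at full double
#' precision so the round-trip is lossless. Missing values, non-monotone
#' times and negative states are rejected with the offending row named.
#'
#' @param path CSV file path.
#' @param state_names which columns are states; the remainder are rates.
#'   When `NULL`, all columns are treated as states (suitable only for
#'   models without observed rate processes).
#' @param series a [gm_observations()].
#' @return `read_observations` returns a [gm_observations()];
#'   `write_observations` returns `path` invisibly.
#' @export
read_observations <- function(path, state_names = NULL) {
  if (!file.exists(path)) {
    gm_validation_error(sprintf("observations file '%s' does not exist", path))
  }
  df <- tryCatch(read.csv(path, check.names = FALSE),
                 error = function(e) gm_validation_error(
                   sprintf("observations file '%s': %s", path, conditionMessage(e))))
  if (!"time" %in% names(df)) {
    gm_validation_error(sprintf("observations file '%s': no 'time' column", path))
  }
  value_cols <- setdiff(names(df), "time")
  state_names <- state_names %||% value_cols
  missing_states <- setdiff(state_names, value_cols)
  if (length(missing_states)) {
    gm_validation_error(sprintf(
      "observations file '%s': missing state column(s): %s",
      path, paste(missing_states, collapse = ", ")))
  }
  rate_names <- setdiff(value_cols, state_names)
  for (cn in value_cols) {
    x <- df[[cn]]
    if (!is.numeric(x)) {
      gm_validation_error(sprintf(
        "observations file '%s': column '%s' is not numeric", path, cn))
    }
    if (any(is.na(x))) {
      gm_validation_error(sprintf(
        "observations file '%s': missing value in column '%s' at row %d",
        path, cn, which(is.na(x))[1]))
    }
  }
  if (any(duplicated(df$time))) {
    gm_validation_error(sprintf(
      "observations file '%s': duplicated time stamp at row %d",
      path, which(duplicated(df$time))[1]))
  }
  for (sn in state_names) {
    if (any(df[[sn]] < 0)) {
      gm_validation_error(sprintf(
        "observations file '%s': negative state in column '%s' at row %d",
        path, sn, which(df[[sn]] < 0)[1]))
    }
  }
  gm_observations(df$time,
                  states = as.list(df[state_names]),
                  rates = as.list(df[rate_names]))
}

#' @rdname read_observations
#' @export
write_observations <- function(series, path) {
  stopifnot(inherits(series, "gm_observations"))
  df <- as.data.frame(series)
  # full double precision, '.' decimal separator
  df[] <- lapply(df, function(x) format(x, digits = 17, scientific = FALSE,
                                        trim = TRUE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Smooth an observation series with a trailing moving average
#'
#' Replaces each state and rate channel by its trailing (causal) moving
#' average over `window` observations; the first `window - 1` points use
#' the average of the observations available so far, so series length and
#' times are unchanged and `window = 1` is the identity.
#'
#' @param obs a [gm_observations()].
#' @param window positive integer number of observations.
#' @return a smoothed [gm_observations()].
#' @export
smooth_observations <- function(obs, window) {
  stopifnot(inherits(obs, "gm_observations"))
  window <- as.integer(window)
  if (window < 1L) gm_usage_error("smoothing window must be >= 1")
  n <- length(obs$times)
  if (window > n) {
    gm_usage_error(sprintf("smoothing window %d exceeds series length %d",
                           window, n))
  }
  if (window == 1L) return(obs)
  ma <- function(x) {
    cs <- cumsum(x)
    out <- numeric(n)
    head_idx <- seq_len(min(window - 1L, n))
    out[head_idx] <- cs[head_idx] / head_idx
    if (n >= window) {
      idx <- window:n
      out[idx] <- (cs[idx] - c(0, cs)[idx - window + 1L]) / window
    }
    out
  }
  gm_observations(obs$times,
                  states = lapply(obs$states, ma),
                  rates = lapply(obs$rates, ma))
}
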