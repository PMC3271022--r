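# Estimating the unknown Jacobian entries from observations.
#
# Three estimators cooperate:
#   * one-sided (trailing) finite differences for processes whose magnitude
#     is known along the trajectory and that depend freely on one variable;
#   * balance inference for the single unobserved process in a variable's
#     gain/loss budget;
#   * assumption-based derivatives (linear / power-law) that convert a
#     process magnitude directly into a partial derivative.
# Trailing stencils are used throughout so that an estimate exists at the
# most recent observation time -- the estimate at index k never uses an
# observation later than k.

default_spacing_floor <- 1e-9

#' One-sided derivative estimate
#'
#' Backward-difference estimate `(f[k] - f[k-1]) / (x[k] - x[k-1])` of the
#' derivative of a process magnitude `f` with respect to a state `x`, using
#' only observations at and before index `k` so the estimate is available
#' at the most recent observation time. One-sided estimators trade some
#' accuracy for this causality, which matters when an imminent transition
#' is being predicted.
#'
#' @param x,f numeric vectors (state and magnitude along the trajectory).
#' @param k index of the later observation (R indexing: `k >= 2`).
#' @param floor relative spacing floor: `|x[k] - x[k-1]|` must be at least
#'   `floor * max(|x[k]|, 1)`, otherwise a degenerate-spacing error is
#'   raised (callers may widen the stencil to an earlier index).
#' @return list of class `gm_entry_estimate`: `value`, `method`
#'   (`"finite_difference"`), `indices_used`.
#' @examples
#' one_sided_derivative(c(1, 2), c(2, 4), k = 2)$value # 2
#' @export
one_sided_derivative <- function(x, f, k, floor = default_spacing_floor) {
  if (k < 2L || k > length(x)) {
    gm_usage_error("one_sided_derivative needs 2 <= k <= length(x)")
  }
  dx <- x[k] - x[k - 1L]
  if (abs(dx) < floor * max(abs(x[k]), 1)) {
    gm_stop("gm_degenerate_spacing",
            sprintf("degenerate spacing |dx| = %g at index %d", abs(dx), k))
  }
  value <- (f[k] - f[k - 1L]) / dx
  if (!is.finite(value)) {
    gm_numerical_error(sprintf("non-finite derivative estimate at index %d", k))
  }
  structure(list(value = value, method = "finite_difference",
                 indices_used = c(k - 1L, k)),
            class = "gm_entry_estimate")
}

#' Derivative of a process from a structural assumption
#'
#' If a process of magnitude `D` is assumed linear in a state `A`
#' (`D = m * A` with possibly time-varying coefficient `m`), then
#' `dD/dA = D / A`; under a power law with exponent `p` (`D` proportional
#' to `A^p`), `dD/dA = p * D / A`. Linear is the power law with `p = 1`.
#'
#' @param magnitude process magnitude at the evaluation time.
#' @param state state value (> 0).
#' @param assumption `"linear"` or a numeric power-law exponent.
#' @return list of class `gm_entry_estimate`.
#' @examples
#' derivative_from_assumption(3, 12, "linear")$value # 0.25
#' derivative_from_assumption(8, 4, 2)$value         # 4
#' @export
derivative_from_assumption <- function(magnitude, state, assumption = "linear") {
  if (!is.finite(state) || state <= 0) {
    gm_stop("gm_domain_error",
            sprintf("assumption-based derivative needs state > 0 (got %g)", state))
  }
  p <- if (identical(assumption, "linear")) 1 else as.numeric(assumption)
  if (!is.finite(p)) gm_usage_error("assumption must be \"linear\" or a finite exponent")
  structure(list(value = p * magnitude / state,
                 method = if (p == 1) "linear_assumption" else "power_law_assumption",
                 indices_used = NA_integer_),
            class = "gm_entry_estimate")
}

# --- process magnitudes ----------------------------------------------------
# Magnitude matrix M[k, process]:
#   ODE:  magnitude at observation k (balance-inferred ones need k >= 2,
#         using the backward difference (x[k]-x[k-1])/(t[k]-t[k-1]));
#   map:  magnitude of the step k-1 -> k, a function of the states at k-1
#         (rates recorded at time t refer to the step starting at t, so the
#         step k-1 -> k uses the rate recorded at index k-1). The "state
#         index" pairing a magnitude at row k is therefore k (ODE) or
#         k-1 (map).

state_index <- function(model, k) {
  if (model$time_mode == "discrete") k - 1L else k
}

eval_known_form <- function(p, model, obs, k_state) {
  consts <- model$known_constants
  f <- p$form
  switch(f$kind,
         constant = consts[[f$value]],
         linear = consts[[f$rate]] * obs$states[[f$of]][k_state],
         logistic = {
           x <- obs$states[[f$of]][k_state]
           consts[[f$r]] * x * (1 - x / consts[[f$K]])
         },
         gm_validation_error(sprintf("cannot evaluate form kind '%s'", f$kind)))
}

process_magnitudes <- function(model, obs) {
  n <- length(obs$times)
  pnames <- names(model$processes)
  M <- matrix(NA_real_, n, length(pnames), dimnames = list(NULL, pnames))
  discrete <- model$time_mode == "discrete"
  rows <- if (discrete) 2L:n else seq_len(n)
  done <- setNames(rep(FALSE, length(pnames)), pnames)
  negative_flags <- list()

  repeat {
    progressed <- FALSE
    for (p in model$processes) {
      if (done[[p$name]]) next
      if (p$observability == "observed") {
        ch <- obs$rates[[p$name]]
        if (is.null(ch)) {
          gm_identifiability_error(sprintf(
            "observed process '%s' has no rate channel in the observations",
            p$name))
        }
        M[rows, p$name] <- if (discrete) ch[rows - 1L] else ch[rows]
        done[[p$name]] <- TRUE; progressed <- TRUE
      } else if (p$observability == "known_form") {
        if (p$form$kind == "scaled_process") {
          base <- p$form$process
          if (!done[[base]]) next
          sc <- model$known_constants[[p$form$scale]]
          M[, p$name] <- if (identical(p$form$op, "divide")) M[, base] / sc
                         else M[, base] * sc
        } else {
          M[rows, p$name] <- vapply(rows, function(k)
            eval_known_form(p, model, obs, state_index(model, k)), numeric(1))
        }
        done[[p$name]] <- TRUE; progressed <- TRUE
      } else { # inferred_by_balance
        siblings <- Filter(function(q) q$target == p$target &&
                             q$name != p$name, model$processes)
        if (!all(vapply(siblings, function(q) done[[q$name]], logical(1)))) next
        x <- obs$states[[p$target]]
        ks <- 2L:n
        dx <- if (discrete) x[ks] - x[ks - 1L]
              else (x[ks] - x[ks - 1L]) / (obs$times[ks] - obs$times[ks - 1L])
        other <- rep(0, length(ks))
        for (q in siblings) {
          s <- if (q$sign == "gain") 1 else -1
          other <- other + s * M[ks, q$name]
        }
        s_p <- if (p$sign == "gain") 1 else -1
        vals <- s_p * (dx - other)
        M[ks, p$name] <- vals
        neg <- ks[which(vals < 0)]
        if (length(neg)) negative_flags[[p$name]] <- neg
        done[[p$name]] <- TRUE; progressed <- TRUE
      }
    }
    if (all(done)) break
    if (!progressed) {
      gm_identifiability_error(sprintf(
        "cannot resolve process magnitudes for: %s (circular or unresolvable dependencies)",
        paste(pnames[!done], collapse = ", ")))
    }
  }
  list(M = M, negative_flags = negative_flags)
}

#' Infer the magnitude of an unobserved process by balancing
#'
#' Solves a variable's discretized gain/loss budget for the single process
#' marked `inferred_by_balance`. In continuous time the balance at index
#' `k` is `(x[k] - x[k-1]) / (t[k] - t[k-1]) = gains - losses`; in discrete
#' time the one-step balance `x[k] = x[k-1] + gains - losses` is closed
#' exactly. A negative inferred magnitude (impossible for a biological
#' rate, but reachable under noise) is returned as-is with a warning flag.
#'
#' @param model a [gm_model()].
#' @param obs a [gm_observations()].
#' @param variable name of the state variable whose balance is solved.
#' @param k observation index (R indexing: `k >= 2`; for a map, `k` indexes
#'   the end of the step `k-1 -> k`).
#' @return list of class `gm_entry_estimate` with `value`, `method`
#'   (`"balance"`), `indices_used`, `process` and `negative` flag.
#' @examples
#' obs <- gm_observations(c(0, 1), states = list(A = c(10, 12)),
#'                        rates = list(births = c(4, 5)))
#' infer_by_balance(allee_model(), obs, "A", k = 2)$value # 5 - 2 = 3
#' @export
infer_by_balance <- function(model, obs, variable, k) {
  stopifnot(inherits(model, "gm_model"), inherits(obs, "gm_observations"))
  inferred <- Filter(function(p) p$target == variable &&
                       p$observability == "inferred_by_balance",
                     model$processes)
  if (length(inferred) != 1L) {
    gm_identifiability_error(sprintf(
      "balance of '%s' must contain exactly one inferred process (found %d)",
      variable, length(inferred)))
  }
  if (k < 2L || k > length(obs$times)) {
    gm_usage_error("infer_by_balance needs 2 <= k <= number of observations")
  }
  mg <- process_magnitudes(model, obs)
  value <- unname(mg$M[k, inferred[[1]]$name])
  if (!is.finite(value)) {
    gm_numerical_error(sprintf("balance at index %d is not computable", k))
  }
  structure(list(value = value, method = "balance",
                 indices_used = c(k - 1L, k),
                 process = inferred[[1]]$name, negative = value < 0),
            class = "gm_entry_estimate")
}

# --- entry estimation over the whole series --------------------------------

# free-variable derivative of process p at row k: difference the reduced
# coefficient C = M / prod(assumed states ^ p) against the free state,
# widening the stencil to the nearest earlier admissible row
free_entry <- function(p, M_p, obs, model, k, free_var, assumed, floor,
                       lowest) {
  si <- function(j) state_index(model, j)
  reduce <- function(j) {
    c_val <- M_p[j]
    for (v in names(assumed)) {
      c_val <- c_val / obs$states[[v]][si(j)]^assumed[[v]]
    }
    c_val
  }
  if (k - 1L < lowest) return(NULL)
  xk <- obs$states[[free_var]][si(k)]
  ck <- reduce(k)
  if (!is.finite(ck)) return(NULL)
  for (j in (k - 1L):lowest) {
    xj <- obs$states[[free_var]][si(j)]
    if (!is.finite(M_p[j])) next
    if (abs(xk - xj) < floor * max(abs(xk), 1)) next
    cj <- reduce(j)
    if (!is.finite(cj)) next
    scale <- 1
    for (v in names(assumed)) scale <- scale * obs$states[[v]][si(k)]^assumed[[v]]
    val <- scale * (ck - cj) / (xk - xj)
    if (!is.finite(val)) return(NULL)
    return(list(value = val, j = j))
  }
  NULL
}

known_form_entries <- function(p, model, obs, k, entry_list) {
  f <- p$form
  si <- state_index(model, k)
  out <- list()
  if (f$kind == "linear") {
    out[[paste(p$name, f$of, sep = ".")]] <-
      list(value = model$known_constants[[f$rate]], prov = "known_constant")
  } else if (f$kind == "logistic") {
    x <- obs$states[[f$of]][si]
    out[[paste(p$name, f$of, sep = ".")]] <- list(
      value = model$known_constants[[f$r]] *
        (1 - 2 * x / model$known_constants[[f$K]]),
      prov = "known_constant")
  } else if (f$kind == "scaled_process") {
    base <- model$processes[[f$process]]
    sc <- model$known_constants[[f$scale]]
    fac <- if (identical(f$op, "divide")) 1 / sc else sc
    for (v in base$depends_on) {
      src <- entry_list[[paste(base$name, v, sep = ".")]]
      if (is.null(src)) return(NULL)
      out[[paste(p$name, v, sep = ".")]] <-
        list(value = fac * src$value, prov = paste0(src$prov, "+known_constant"))
    }
  }
  out
}

#' Estimate a Jacobian trajectory from observations
#'
#' Runs the full entry-estimation recipe at every admissible observation
#' index: process magnitudes are obtained from rate channels, known forms
#' or balance inference; partial derivatives from structural assumptions
#' (magnitude/state, power laws) or trailing finite differences of the
#' reduced process coefficient against its free variable; and each
#' complete entry set is assembled into a [build_jacobian()] estimate.
#' For the Allee-type model this reproduces the textbook recipe: the birth
#' slope by one-sided differences of observed births against population,
#' the death rate by balance, its slope as death rate / population, and
#' the eigenvalue as the difference of the two slopes.
#'
#' Indices whose stencils are not yet complete (the first one or two
#' observations) or degenerate (spacing below `floor`, after widening) are
#' skipped and recorded, not fabricated.
#'
#' @param model a [gm_model()] that passes [validate_identifiability()]
#'   against the observation channels.
#' @param obs a [gm_observations()].
#' @param smoothing `NULL` for none, or a positive integer window for a
#'   trailing moving average applied to every channel before estimation
#'   (see [smooth_observations()]).
#' @param floor relative spacing floor for finite-difference stencils.
#' @param clip_negative clip balance-inferred magnitudes at zero for
#'   assumption-based derivatives (raw values are kept for the
#'   finite-difference coefficients and recorded in the flags).
#' @return object of class `gm_jacobian_series`: a list with `jacobians`
#'   (list of `gm_jacobian`), `skipped` (data.frame of index/time/reason),
#'   `negative_rate_flags`, `model` and `times`.
#' @export
estimate_jacobian_series <- function(model, obs, smoothing = NULL,
                                     floor = default_spacing_floor,
                                     clip_negative = TRUE) {
  stopifnot(inherits(model, "gm_model"), inherits(obs, "gm_observations"))
  rep_id <- validate_identifiability(model, names(obs$rates))
  if (!rep_id$pass) {
    gm_identifiability_error(paste(
      c("model is not identifiable from these observations:", rep_id$failures),
      collapse = "\n  "))
  }
  if (!is.null(smoothing) && !identical(smoothing, 1L) && !identical(smoothing, 1)) {
    obs <- smooth_observations(obs, smoothing)
  }
  mg <- process_magnitudes(model, obs)
  M <- mg$M
  n <- length(obs$times)
  first_row <- 2L # earliest row with balance magnitudes / map steps
  jacobians <- list()
  skipped <- data.frame(index = integer(), time = numeric(),
                        reason = character())

  for (k in first_row:n) {
    entry_list <- list()
    ok <- TRUE
    reason <- NULL
    # pass 1: direct (observed / inferred) processes
    for (p in model$processes) {
      if (!length(p$depends_on) || p$observability == "known_form") next
      m_k <- M[k, p$name]
      if (!is.finite(m_k)) { ok <- FALSE; reason <- paste0("magnitude of '", p$name, "' unavailable"); break }
      inferred <- p$observability == "inferred_by_balance"
      assumed <- list(); free_var <- NULL
      for (v in p$depends_on) {
        a <- p$assumptions[[v]]
        if (is.null(a) || identical(a, "free")) free_var <- v
        else assumed[[v]] <- if (identical(a, "linear")) 1 else as.numeric(a)
      }
      base_prov <- if (inferred) "balance+" else ""
      m_assump <- m_k
      if (inferred && clip_negative && m_k < 0) m_assump <- 0
      for (v in names(assumed)) {
        x_v <- obs$states[[v]][state_index(model, k)]
        if (!is.finite(x_v) || x_v <= 0) { ok <- FALSE; reason <- paste0("state '", v, "' not positive"); break }
        entry_list[[paste(p$name, v, sep = ".")]] <-
          list(value = assumed[[v]] * m_assump / x_v,
               prov = paste0(base_prov, "assumption"))
      }
      if (!ok) break
      if (!is.null(free_var)) {
        lowest <- if (model$time_mode == "continuous" &&
                      p$observability == "observed") 1L else first_row
        fe <- free_entry(p, M[, p$name], obs, model, k, free_var, assumed,
                         floor, lowest)
        if (is.null(fe)) { ok <- FALSE; reason <- paste0("no admissible stencil for '", p$name, "' vs '", free_var, "'"); break }
        entry_list[[paste(p$name, free_var, sep = ".")]] <-
          list(value = fe$value, prov = paste0(base_prov, "finite_difference"))
      }
    }
    # pass 2: known-form processes (scaled ones need pass-1 entries)
    if (ok) {
      pending <- Filter(function(p) p$observability == "known_form" &&
                          length(p$depends_on), model$processes)
      guard <- 0L
      while (length(pending) && guard < 10L) {
        guard <- guard + 1L
        still <- list()
        for (p in pending) {
          kf <- known_form_entries(p, model, obs, k, entry_list)
          if (is.null(kf)) still[[p$name]] <- p else entry_list <- c(entry_list, kf)
        }
        if (length(still) == length(pending)) { ok <- FALSE; reason <- "unresolvable known-form entries"; break }
        pending <- still
      }
    }
    if (!ok) {
      skipped <- rbind(skipped, data.frame(index = k, time = obs$times[k],
                                           reason = reason))
      next
    }
    values <- lapply(entry_list, `[[`, "value")
    provs <- vapply(entry_list, `[[`, character(1), "prov")
    jacobians[[length(jacobians) + 1L]] <-
      build_jacobian(model, values, at_time = obs$times[k], provenance = provs)
  }
  structure(list(jacobians = jacobians, skipped = skipped,
                 negative_rate_flags = mg$negative_flags,
                 model = model,
                 times = vapply(jacobians, `[[`, numeric(1), "time")),
            class = "gm_jacobian_series")
}

#' @export
print.gm_jacobian_series <- function(x, ...) {
  cat(sprintf("Jacobian series: %d estimates on [%g, %g] (%d skipped)\n",
              length(x$jacobians),
              if (length(x$times)) min(x$times) else NA,
              if (length(x$times)) max(x$times) else NA,
              nrow(x$skipped)))
  invisible(x)
}
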