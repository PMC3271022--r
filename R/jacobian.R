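# Jacobian assembly, stability classification and eigenvalue matching.

# deterministic ordering: descending real part (ODE) / descending modulus
# (map); ties broken by descending imaginary part
sort_eigenvalues <- function(values, time_mode) {
  key <- if (time_mode == "discrete") Mod(values) else Re(values)
  values[order(-key, -Im(values))]
}

#' Assemble a Jacobian estimate from per-entry partial derivatives
#'
#' For a continuous-time model the Jacobian entry (i, j) is the signed sum
#' over all processes targeting variable i of the partial derivative of the
#' process with respect to variable j. For a discrete-time model written in
#' increment form `X[t+1] = X[t] + gains - losses` the same signed sum gives
#' the increment derivative and the full map Jacobian is the identity plus
#' that sum.
#'
#' @param model a [gm_model()].
#' @param entries named list mapping `"process.variable"` to the estimated
#'   partial derivative of the process magnitude with respect to the
#'   variable (units: 1/time for ODE models, dimensionless per step for
#'   maps).
#' @param at_time observation time the estimate refers to.
#' @param provenance optional named character vector parallel to `entries`
#'   tagging how each entry was obtained (`finite_difference`, `balance`,
#'   `assumption`, `known_constant`).
#' @return object of class `gm_jacobian`: time, matrix, eigenvalues (sorted
#'   by descending real part for ODEs / descending modulus for maps), and
#'   an entry provenance matrix.
#' @examples
#' m <- allee_model()
#' J <- build_jacobian(m, list(births.A = 0.5, deaths.A = 0.8), at_time = 0)
#' J$eigenvalues # -0.3
#' @export
build_jacobian <- function(model, entries, at_time, provenance = NULL) {
  stopifnot(inherits(model, "gm_model"))
  vars <- model$variables
  n <- length(vars)
  J <- matrix(0, n, n, dimnames = list(vars, vars))
  prov <- matrix("", n, n, dimnames = list(vars, vars))
  for (p in model$processes) {
    i <- match(p$target, vars)
    s <- if (p$sign == "gain") 1 else -1
    for (v in p$depends_on) {
      key <- paste(p$name, v, sep = ".")
      e <- entries[[key]]
      if (is.null(e)) {
        gm_identifiability_error(sprintf(
          "missing Jacobian entry for process '%s' with respect to '%s'",
          p$name, v))
      }
      if (!is.finite(e)) {
        gm_numerical_error(sprintf(
          "non-finite Jacobian entry for process '%s' with respect to '%s'",
          p$name, v))
      }
      j <- match(v, vars)
      J[i, j] <- J[i, j] + s * e
      tag <- if (!is.null(provenance)) provenance[[key]] %||% "" else ""
      prov[i, j] <- if (nzchar(prov[i, j])) paste(prov[i, j], tag, sep = "+") else tag
    }
  }
  if (model$time_mode == "discrete") J <- diag(n) + J
  ev <- sort_eigenvalues(eigen(J, only.values = TRUE)$values, model$time_mode)
  structure(list(time = at_time, matrix = J, eigenvalues = ev,
                 provenance = prov, time_mode = model$time_mode),
            class = "gm_jacobian")
}

#' @export
print.gm_jacobian <- function(x, ...) {
  cat(sprintf("Jacobian estimate at t = %g (%s time)\n", x$time, x$time_mode))
  print(round(x$matrix, 6))
  cat("eigenvalues:", paste(format(x$eigenvalues, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Classify dynamical stability from eigenvalues
#'
#' A continuous-time steady state is stable when all eigenvalues of the
#' Jacobian have negative real part; a discrete-time fixed point is stable
#' when all eigenvalues lie inside the unit circle. The stability margin is
#' the distance of the dominant eigenvalue from the boundary: `-max(Re)`
#' for ODEs (units 1/time) and `1 - max(Mod)` for maps (dimensionless).
#'
#' @param eigenvalues complex (or numeric) vector, non-empty.
#' @param time_mode `"continuous"` or `"discrete"`.
#' @return list of class `gm_stability`: `stable`, `margin`,
#'   `dominant_eigenvalues` (all eigenvalues attaining the extremum).
#' @examples
#' classify_stability(c(-1, -0.5), "continuous")$margin # 0.5
#' classify_stability(c(0.95, 0.5), "discrete")$stable  # TRUE
#' @export
classify_stability <- function(eigenvalues,
                               time_mode = c("continuous", "discrete")) {
  time_mode <- match.arg(time_mode)
  if (length(eigenvalues) == 0L) {
    gm_usage_error("classify_stability needs at least one eigenvalue")
  }
  ev <- as.complex(eigenvalues)
  key <- if (time_mode == "discrete") Mod(ev) else Re(ev)
  extreme <- max(key)
  margin <- if (time_mode == "discrete") 1 - extreme else -extreme
  dom <- ev[abs(key - extreme) <= 1e-12 * max(1, abs(extreme))]
  structure(list(stable = margin > 0, margin = margin,
                 dominant_eigenvalues = dom, time_mode = time_mode),
            class = "gm_stability")
}

#' @export
print.gm_stability <- function(x, ...) {
  cat(sprintf("%s (%s time), margin %.6g; dominant: %s\n",
              if (x$stable) "stable" else "unstable", x$time_mode, x$margin,
              paste(format(x$dominant_eigenvalues, digits = 4), collapse = ", ")))
  invisible(x)
}

# all permutations of 1..n, in lexicographic order
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  out
}

#' Match eigenvalues between consecutive Jacobian estimates
#'
#' Finds the assignment of `current` onto `previous` minimizing the total
#' complex distance, so that eigenvalue branches can be tracked coherently
#' through time. The optimum is found exactly by enumeration (trajectories
#' here have dimension at most a handful); among equal-cost assignments the
#' lexicographically smallest is returned, which keeps conjugate pairs
#' matched to conjugate pairs.
#'
#' @param previous,current complex vectors of equal length.
#' @return integer permutation `p` such that `current[p]` aligns with
#'   `previous`.
#' @export
match_eigenvalues <- function(previous, current) {
  if (length(previous) != length(current)) {
    gm_usage_error("eigenvalue lists must have equal length")
  }
  n <- length(previous)
  if (n > 8L) gm_usage_error("eigenvalue matching supports dimension <= 8")
  if (n == 1L) return(1L)
  perms <- permutations(n)
  cost <- apply(perms, 1L, function(p) sum(Mod(as.complex(previous) - as.complex(current)[p])))
  best <- which.min(cost) # first minimum = lexicographically smallest
  as.integer(perms[best, ])
}
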