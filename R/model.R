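#' Describe one process of a generalized model
#'
#' A process is a gain or loss term in one state variable's balance
#' equation. Its functional form is left unspecified; what is recorded is
#' which variables it depends on, how its magnitude will be obtained
#' (`observed` from a rate channel, `inferred_by_balance` from the other
#' terms of the balance, or `known_form` from a declared parametric form),
#' and what is assumed about its dependence on each variable.
#'
#' @param name process name (also the rate-channel name when observed).
#' @param sign `"gain"` or `"loss"` in the target variable's balance.
#' @param target name of the state variable whose balance the process
#'   enters.
#' @param depends_on character vector of state variables the process may
#'   depend on (possibly empty for exogenous drivers such as a recorded
#'   catch).
#' @param observability `"observed"`, `"inferred_by_balance"` or
#'   `"known_form"`.
#' @param assumptions named list over `depends_on`: `"linear"` (process
#'   proportional to that variable, so the partial derivative is
#'   magnitude/state), a numeric power-law exponent `p` (derivative
#'   `p * magnitude / state`; `"linear"` is `p = 1`), or `"free"` (no
#'   assumption; the derivative is estimated by one-sided finite
#'   differences). At most one dependency may be `"free"`.
#' @param drifting is this the process through which the slowly changing
#'   external forcing acts (e.g. a rising mortality, a harvest ramp)? A
#'   drifting process needs assumptions on *all* of its dependencies:
#'   finite differences of its magnitude against a state cannot separate
#'   the state dependence from the temporal drift. (An assumption such as
#'   "linear" still permits the coefficient itself to drift.)
#' @param form for `known_form` processes, a list describing the parametric
#'   form: `list(kind = "linear", of = <var>, rate = <constant name>)`,
#'   `list(kind = "logistic", of = <var>, r = <constant>, K = <constant>)`,
#'   `list(kind = "constant", value = <constant>)`, or
#'   `list(kind = "scaled_process", process = <process>, scale = <constant>,
#'   op = "multiply"|"divide")` for a process tied to another one through a
#'   known conversion factor (e.g. predation loss = predator intake /
#'   conversion efficiency).
#' @return an object of class `gm_process`.
#' @seealso [gm_model()]
#' @export
gm_process <- function(name, sign = c("gain", "loss"), target,
                       depends_on = character(),
                       observability = c("observed", "inferred_by_balance",
                                         "known_form"),
                       assumptions = list(), drifting = FALSE,
                       form = NULL) {
  sign <- match.arg(sign)
  observability <- match.arg(observability)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    gm_validation_error("process name must be a non-empty string")
  }
  bad <- setdiff(names(assumptions), depends_on)
  if (length(bad)) {
    gm_validation_error(sprintf(
      "process '%s': assumptions refer to variables not in depends_on: %s",
      name, paste(bad, collapse = ", ")))
  }
  for (v in names(assumptions)) {
    a <- assumptions[[v]]
    ok <- (is.character(a) && a %in% c("linear", "free")) ||
      (is.numeric(a) && length(a) == 1L && is.finite(a))
    if (!ok) {
      gm_validation_error(sprintf(
        "process '%s': assumption on '%s' must be \"linear\", \"free\" or a numeric exponent",
        name, v))
    }
  }
  n_free <- sum(vapply(depends_on, function(v) {
    identical(assumptions[[v]], "free") || is.null(assumptions[[v]])
  }, logical(1)))
  if (observability != "known_form" && n_free > 1L) {
    gm_identifiability_error(sprintf(
      "process '%s' leaves %d of %d dependencies unconstrained; assumptions are required on all but one",
      name, n_free, length(depends_on)))
  }
  if (observability == "known_form" && is.null(form)) {
    gm_validation_error(sprintf("process '%s': known_form requires a form", name))
  }
  structure(
    list(name = name, sign = sign, target = target,
         depends_on = as.character(depends_on),
         observability = observability,
         assumptions = assumptions, drifting = isTRUE(drifting), form = form),
    class = "gm_process")
}

#' Construct a generalized model
#'
#' A generalized model fixes the structure of a dynamical system -- its
#' state variables and the signed processes entering each variable's
#' balance -- without committing to functional forms. In continuous time
#' the balance reads `dX/dt = gains - losses`; in discrete time the model
#' is written in increment form `X[t+1] = X[t] + gains - losses`, so the
#' map Jacobian is the identity plus the derivative of the increments and
#' the stability boundary is unit eigenvalue modulus.
#'
#' @param variables character vector of state-variable names (unique).
#' @param processes list of [gm_process()] objects.
#' @param time_mode `"continuous"` (ODE) or `"discrete"` (annual map).
#' @param known_constants named list of known rate constants (e.g. a
#'   natural mortality rate per year, a conversion efficiency, a refuge
#'   influx in biomass per year) referenced by `known_form` processes or
#'   kept for documentation.
#' @return an object of class `gm_model`.
#' @examples
#' allee_model()
#' @export
gm_model <- function(variables, processes,
                     time_mode = c("continuous", "discrete"),
                     known_constants = list()) {
  time_mode <- match.arg(time_mode)
  if (anyDuplicated(variables)) {
    gm_validation_error("variable names must be unique")
  }
  if (!length(processes)) gm_validation_error("a model needs at least one process")
  for (p in processes) {
    if (!inherits(p, "gm_process")) {
      gm_validation_error("processes must be built with gm_process()")
    }
    if (!p$target %in% variables) {
      gm_validation_error(sprintf(
        "process '%s' targets unknown variable '%s'", p$name, p$target))
    }
    if (length(setdiff(p$depends_on, variables))) {
      gm_validation_error(sprintf(
        "process '%s' depends on unknown variables: %s", p$name,
        paste(setdiff(p$depends_on, variables), collapse = ", ")))
    }
  }
  nm <- vapply(processes, `[[`, character(1), "name")
  if (anyDuplicated(nm)) gm_validation_error("process names must be unique")
  names(processes) <- nm
  structure(
    list(variables = as.character(variables), processes = processes,
         time_mode = time_mode, known_constants = known_constants),
    class = "gm_model")
}

#' @export
print.gm_model <- function(x, ...) {
  cat(sprintf("Generalized model (%s time): %d variable(s), %d process(es)\n",
              x$time_mode, length(x$variables), length(x$processes)))
  cat("  variables:", paste(x$variables, collapse = ", "), "\n")
  for (p in x$processes) {
    dep <- if (length(p$depends_on)) paste(p$depends_on, collapse = ",") else "-"
    cat(sprintf("  %-18s %-4s -> %-3s deps(%s) [%s]\n",
                p$name, p$sign, p$target, dep, p$observability))
  }
  if (length(x$known_constants)) {
    cat("  known constants:",
        paste(sprintf("%s=%g", names(x$known_constants),
                      unlist(x$known_constants)), collapse = ", "), "\n")
  }
  invisible(x)
}

# which constant / process names a known_form references
form_constants <- function(form) {
  switch(form$kind,
         linear = form$rate,
         logistic = c(form$r, form$K),
         constant = form$value,
         scaled_process = form$scale,
         gm_validation_error(sprintf("unknown form kind '%s'", form$kind)))
}

#' Check that a generalized model is identifiable from the observed channels
#'
#' Verifies the structural rules under which the unknown Jacobian entries
#' can be recovered from data: (a) each variable's balance contains at most
#' one process inferred by balancing, and all other processes in that
#' balance are observed or of known form; (b) every observed or inferred
#' process with `n` dependencies carries non-free assumptions on at least
#' `n - 1` of them; (c) every `known_form` process references only declared
#' known constants, existing channels/variables, and (for scaled forms)
#' processes that are themselves resolvable without circularity.
#'
#' @param model a [gm_model()].
#' @param observed_channels character vector of the rate channels present in
#'   the observations.
#' @return a list of class `gm_identifiability_report` with elements `pass`
#'   (logical) and `failures` (character vector naming each violated rule).
#' @examples
#' validate_identifiability(allee_model(), "births")
#' @export
validate_identifiability <- function(model, observed_channels = character()) {
  stopifnot(inherits(model, "gm_model"))
  failures <- character()

  # rule (a): at most one inferred process per balance, remainder resolvable
  for (v in model$variables) {
    procs <- Filter(function(p) p$target == v, model$processes)
    inferred <- Filter(function(p) p$observability == "inferred_by_balance", procs)
    unobserved_other <- Filter(function(p) {
      p$observability == "observed" && !(p$name %in% observed_channels)
    }, procs)
    if (length(inferred) > 1L) {
      failures <- c(failures, sprintf(
        "rule (a): balance of '%s' has %d processes inferred by balance (%s); at most one is identifiable",
        v, length(inferred),
        paste(vapply(inferred, `[[`, character(1), "name"), collapse = ", ")))
    }
    if (length(inferred) >= 1L && length(unobserved_other)) {
      failures <- c(failures, sprintf(
        "rule (a): balance of '%s' infers '%s' but process(es) %s lack an observation channel",
        v, inferred[[1]]$name,
        paste(sQuote(vapply(unobserved_other, `[[`, character(1), "name")),
              collapse = ", ")))
    }
  }

  # rule (b): assumptions on all but one dependency (on every dependency
  # for the process carrying the external drift, whose finite differences
  # against a state would confound state dependence with the drift)
  for (p in model$processes) {
    if (p$observability == "known_form") next
    n <- length(p$depends_on)
    if (n == 0L) next
    n_constrained <- sum(vapply(p$depends_on, function(v) {
      a <- p$assumptions[[v]]
      !is.null(a) && !identical(a, "free")
    }, logical(1)))
    required <- if (isTRUE(p$drifting)) n else n - 1L
    if (n_constrained < required) {
      failures <- c(failures, sprintf(
        "rule (b): process '%s'%s depends on %d variable(s) but carries only %d assumption(s); at least %d required",
        p$name, if (isTRUE(p$drifting)) " (drifting)" else "",
        n, n_constrained, required))
    }
  }

  # rule (c): known_form references resolve, without circular scaling
  resolvable <- function(pname, seen = character()) {
    p <- model$processes[[pname]]
    if (is.null(p)) return(FALSE)
    if (pname %in% seen) return(FALSE)
    switch(p$observability,
           observed = pname %in% observed_channels,
           inferred_by_balance = TRUE, # checked under rule (a)
           known_form = {
             if (p$form$kind == "scaled_process") {
               base <- p$form$process
               if (is.null(model$processes[[base]])) return(FALSE)
               bp <- model$processes[[base]]
               if (bp$observability == "known_form") {
                 resolvable(base, c(seen, pname))
               } else TRUE
             } else TRUE
           })
  }
  for (p in model$processes) {
    if (p$observability != "known_form") next
    consts <- form_constants(p$form)
    missing_const <- setdiff(consts, names(model$known_constants))
    if (length(missing_const)) {
      failures <- c(failures, sprintf(
        "rule (c): known_form process '%s' references undeclared constant(s): %s",
        p$name, paste(missing_const, collapse = ", ")))
    }
    if (p$form$kind %in% c("linear", "logistic") &&
        !(p$form$of %in% model$variables)) {
      failures <- c(failures, sprintf(
        "rule (c): known_form process '%s' references unknown variable '%s'",
        p$name, p$form$of))
    }
    if (p$form$kind == "scaled_process" && !resolvable(p$name)) {
      failures <- c(failures, sprintf(
        "rule (c): known_form process '%s' scales process '%s', which is missing, circular, or unresolvable",
        p$name, p$form$process))
    }
  }

  # observed processes must actually have a channel (when not in a balance
  # with an inferred process this is not fatal for the balance but the
  # Jacobian entries for that process cannot be formed)
  for (p in model$processes) {
    if (p$observability == "observed" && length(p$depends_on) &&
        !(p$name %in% observed_channels)) {
      already <- any(grepl(sprintf("'%s' lack", p$name), failures, fixed = TRUE))
      if (!already) {
        failures <- c(failures, sprintf(
          "rule (a): observed process '%s' has no matching observation channel",
          p$name))
      }
    }
  }

  structure(list(pass = length(failures) == 0L, failures = failures),
            class = "gm_identifiability_report")
}

#' @export
print.gm_identifiability_report <- function(x, ...) {
  if (x$pass) {
    cat("Identifiability: PASS\n")
  } else {
    cat("Identifiability: FAIL\n")
    for (f in x$failures) cat("  -", f, "\n")
  }
  invisible(x)
}

# --- model file round-trip -------------------------------------------------

#' Read or write a generalized model description file
#'
#' Models are stored as YAML with keys `variables`, `time_mode`,
#' `known_constants` and `processes` (each with `name`, `sign`, `target`,
#' `depends_on`, `observability`, `assumptions`, and `form` for known-form
#' processes). The round-trip `read_model(write_model(m, f))` is lossless.
#'
#' @param model a [gm_model()].
#' @param path file path.
#' @return `read_model` returns a [gm_model()]; `write_model` returns
#'   `path` invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "gm_model"))
  procs <- lapply(unname(model$processes), function(p) {
    out <- list(name = p$name, sign = p$sign, target = p$target,
                depends_on = as.list(p$depends_on),
                observability = p$observability)
    if (length(p$assumptions)) out$assumptions <- p$assumptions
    if (isTRUE(p$drifting)) out$drifting <- TRUE
    if (!is.null(p$form)) out$form <- p$form
    out
  })
  obj <- list(variables = as.list(model$variables),
              time_mode = model$time_mode,
              known_constants = model$known_constants,
              processes = procs)
  yaml::write_yaml(obj, path, precision = 17L)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) {
    gm_validation_error(sprintf("model file '%s' does not exist", path))
  }
  obj <- tryCatch(yaml::read_yaml(path), error = function(e) {
    gm_validation_error(sprintf("model file '%s': %s", path, conditionMessage(e)))
  })
  for (key in c("variables", "time_mode", "processes")) {
    if (is.null(obj[[key]])) {
      gm_validation_error(sprintf("model file '%s': missing key '%s'", path, key))
    }
  }
  procs <- lapply(obj$processes, function(p) {
    gm_process(name = p$name, sign = p$sign, target = p$target,
               depends_on = unlist(p$depends_on) %||% character(),
               observability = p$observability,
               assumptions = p$assumptions %||% list(),
               drifting = isTRUE(p$drifting),
               form = p$form)
  })
  gm_model(variables = unlist(obj$variables), processes = procs,
           time_mode = obj$time_mode,
           known_constants = obj$known_constants %||% list())
}
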