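# Ground truth: locate the bifurcation of a frozen (fast-subsystem) model
# by continuing its equilibrium branch in the ramped parameter.

newton_solve <- function(fn, x0, tol = 1e-11, maxit = 60L) {
  x <- x0
  for (i in seq_len(maxit)) {
    fx <- fn(x)
    if (any(!is.finite(fx))) return(NULL)
    if (max(abs(fx)) < tol) return(x)
    J <- pracma::jacobian(fn, x)
    dx <- tryCatch(solve(J, fx), error = function(e) NULL)
    if (is.null(dx)) return(NULL)
    x <- x - dx
    if (any(!is.finite(x))) return(NULL)
  }
  if (max(abs(fn(x))) < 1e-7) x else NULL
}

# equilibrium (ODE: f = 0; map: f(x) = x) continued from x_prev, with a
# jump guard so the branch is not silently exchanged for another attractor
solve_branch_point <- function(fun, p, x_prev, time_mode, min_state, jump_guard) {
  g <- if (time_mode == "discrete") function(x) fun(x, p) - x else function(x) fun(x, p)
  x <- newton_solve(g, x_prev)
  if (is.null(x)) return(NULL)
  if (any(x < min_state)) return(NULL)
  if (max(abs(x - x_prev)) > jump_guard * max(max(abs(x_prev)), 0.1)) return(NULL)
  J <- pracma::jacobian(function(s) fun(s, p), x)
  ev <- eigen(J, only.values = TRUE)$values
  margin <- if (time_mode == "discrete") 1 - max(Mod(ev)) else -max(Re(ev))
  list(x = x, margin = margin, eigenvalues = ev)
}

#' Locate the fast-subsystem bifurcation of a frozen model
#'
#' Continues the equilibrium branch of the frozen (parameter held fixed)
#' model across the parameter range by Newton steps from the previous
#' solution, monitoring the stability margin of the analytic Jacobian
#' (computed numerically from the supplied right-hand side). The returned
#' parameter is the first value where the margin crosses zero -- either
#' smoothly (a Hopf or real-eigenvalue crossing on a persisting branch)
#' or because the branch terminates in a fold -- bisected to `tol`
#' relative accuracy. If a ramp schedule is supplied the corresponding
#' calendar time is attached.
#'
#' @param fun frozen model: `fun(state, parameter)` returning the time
#'   derivative (`time_mode = "continuous"`) or the next state
#'   (`time_mode = "discrete"`).
#' @param par_range length-2 numeric, scanned from the first to the second
#'   element (direction may be decreasing).
#' @param x0 equilibrium (or nearby state) at `par_range[1]`.
#' @param time_mode `"continuous"` or `"discrete"`.
#' @param ramp optional [ramp_schedule()] translating the parameter into a
#'   time.
#' @param n_steps continuation grid resolution.
#' @param tol relative bisection tolerance on the parameter.
#' @param min_state components below this are treated as loss of the
#'   (positive) branch.
#' @param jump_guard relative step size beyond which a Newton solution is
#'   treated as having jumped to a different branch.
#' @return `NULL` when no crossing lies in the range (reported via
#'   `attr(, "message")` is not set; the caller receives `NULL`), else a
#'   list: `parameter` (name from the ramp if given), `value`, `time`
#'   (`NA` without a ramp), `margin_before`, `eigenvalues_before` (at the
#'   last clearly stable point), `kind` (`"smooth_crossing"` or
#'   `"branch_fold"`).
#' @examples
#' # dA/dt = A * (c - A): the extinct state A = 0 has eigenvalue c and
#' # loses stability exactly at c = 0
#' tb <- true_bifurcation_point(function(A, c) A * (c - A),
#'                              par_range = c(-1, 1), x0 = 0,
#'                              min_state = -Inf)
#' abs(tb$value) < 1e-6
#' @export
true_bifurcation_point <- function(fun, par_range, x0,
                                   time_mode = c("continuous", "discrete"),
                                   ramp = NULL, n_steps = 120L, tol = 1e-6,
                                   min_state = 1e-8, jump_guard = 0.5) {
  time_mode <- match.arg(time_mode)
  ps <- seq(par_range[1], par_range[2], length.out = n_steps + 1L)
  sol <- solve_branch_point(fun, ps[1], x0, time_mode, min_state, jump_guard)
  if (is.null(sol) || sol$margin <= 0) {
    gm_numerical_error("no stable equilibrium branch at the start of the parameter range")
  }
  x_last <- sol$x
  last_stable <- sol
  bracket <- NULL
  kind <- NULL
  for (i in 2L:length(ps)) {
    s <- solve_branch_point(fun, ps[i], x_last, time_mode, min_state, jump_guard)
    if (is.null(s)) {
      bracket <- c(ps[i - 1L], ps[i]); kind <- "branch_fold"; break
    }
    if (s$margin <= 0) {
      bracket <- c(ps[i - 1L], ps[i]); kind <- "smooth_crossing"; break
    }
    x_last <- s$x
    last_stable <- s
  }
  if (is.null(bracket)) return(NULL)
  lo <- bracket[1]; hi <- bracket[2]
  x_lo <- x_last
  scale <- max(abs(lo), abs(hi), 1e-8)
  while (abs(hi - lo) > tol * scale) {
    mid <- (lo + hi) / 2
    s <- solve_branch_point(fun, mid, x_lo, time_mode, min_state, jump_guard)
    if (!is.null(s) && s$margin > 0) {
      lo <- mid; x_lo <- s$x; last_stable <- s
    } else {
      hi <- mid
      if (!is.null(s) && kind == "branch_fold") kind <- "smooth_crossing"
    }
  }
  value <- (lo + hi) / 2
  list(parameter = if (!is.null(ramp)) ramp$parameter else NA_character_,
       value = value,
       time = if (!is.null(ramp)) ramp_time_of(ramp, value) else NA_real_,
       margin_before = last_stable$margin,
       eigenvalues_before = last_stable$eigenvalues,
       kind = kind)
}
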