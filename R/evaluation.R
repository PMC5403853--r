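#' Relative error of a solution value, in percent
#'
#' \deqn{e = \frac{|\check x - x|}{|\check x|} \cdot 100\ [\%]}
#' where \eqn{\check x} is the reference value. Deliberately asymmetric:
#' the reference alone sets the scale.
#'
#' @param x_ref reference value (nonzero).
#' @param x value under evaluation.
#' @return Percent error (vectorized).
#' @export
relative_error <- function(x_ref, x) {
  if (any(x_ref == 0)) stop("relative_error: zero reference value")
  abs(x_ref - x) / abs(x_ref) * 100
}

#' Monolithic tight-tolerance reference solution
#'
#' Solves the combined (un-split) system with a variable-step stiff solver
#' (\pkg{deSolve}, `lsoda`) at tolerance `tol` (default 1e-12) and returns
#' the trajectory on `t_grid` with a quadratic-interpolation accessor.
#'
#' @param problem an `mr_problem` exposing `$monolithic` (`rhs`, `x0`).
#' @param t_grid output times (s), starting at the initial time.
#' @param tol relative and absolute solver tolerance.
#' @return List of class `mr_reference`: `times`, `states` (matrix), `tol`,
#'   and `at(t)` returning the interpolated state row.
#' @export
compute_reference <- function(problem, t_grid, tol = 1e-12) {
  rhs <- problem$monolithic$rhs
  x0 <- problem$monolithic$x0
  out <- deSolve::lsoda(y = x0, times = t_grid,
                        func = function(t, y, p) list(rhs(t, y)),
                        rtol = tol, atol = tol, maxsteps = 1e6)
  if (attr(out, "istate")[1L] < 0)
    stop("compute_reference: stiff solver failed")
  times <- out[, 1L]
  states <- unname(out[, -1L, drop = FALSE])
  at <- function(t) {
    idx <- hist_near(times, t, 3L)
    poly2_eval(times[idx], states[idx, , drop = FALSE], t)
  }
  structure(list(times = times, states = states, tol = tol, at = at),
            class = "mr_reference")
}

#' Empirical convergence order from accuracy-cost points
#'
#' Least-squares slope of `log(error)` versus `log(cost)`, reported as a
#' positive decline order: 2 means the error falls two decades per decade
#' of additional right-hand-side evaluations.
#'
#' @param errors positive errors (>= 3 values).
#' @param costs positive costs (same length), spanning a nontrivial range.
#' @return Positive slope estimate.
#' @export
convergence_order <- function(errors, costs) {
  if (length(errors) < 2L || length(errors) != length(costs))
    stop("convergence_order: need >= 2 matched error/cost points")
  if (any(errors <= 0) || any(costs <= 0))
    stop("convergence_order: errors and costs must be positive")
  lx <- log10(costs)
  if (diff(range(lx)) < 1e-8)
    stop("convergence_order: degenerate cost spread")
  -unname(stats::coef(stats::lm(log10(errors) ~ lx))[2L])
}

#' Tolerance sweep: accuracy at a fixed time versus computational cost
#'
#' Runs the engine once per tolerance, measures the relative error of the
#' configured observables at `t_eval` against a monolithic tight-tolerance
#' reference, and records cost counters (one row per tolerance): accepted
#' micro and macro steps, rejections, rhs evaluations inclusive and
#' exclusive of finite-difference Jacobian columns, and ordering switches.
#'
#' @param problem an `mr_problem`.
#' @param tolerances relative tolerances to sweep.
#' @param cfg an [mr_config()]; its `t_end` bounds the runs.
#' @param t_eval evaluation time (s), default 2.
#' @param observables names from `problem$observables` to report (default
#'   all).
#' @param reference optional precomputed [compute_reference()] result.
#' @return `data.frame`, one row per tolerance, with error columns
#'   `err_<observable>` in percent. A failed run yields a row of `NA`s with
#'   `status` recording the failure.
#' @export
run_sweep <- function(problem, tolerances, cfg, t_eval = 2,
                      observables = names(problem$observables),
                      reference = NULL) {
  if (is.null(reference))
    reference <- compute_reference(problem, c(0, t_eval / 2, t_eval))
  x_ref <- reference$at(t_eval)
  rows <- lapply(tolerances, function(tol) {
    base <- data.frame(reltol = tol, micros = NA_integer_,
                       macros = NA_integer_, rejected = NA_integer_,
                       discarded = NA_integer_,
                       rhs_calls = NA_integer_, rhs_calls_no_jac = NA_integer_,
                       switches = NA_integer_, status = "failed",
                       stringsAsFactors = FALSE)
    for (ob in observables) base[[paste0("err_", ob)]] <- NA_real_
    res <- tryCatch({
      comps <- problem_components(problem, reltol = tol)
      mr_run(comps, cfg)
    }, error = function(e) NULL)
    if (is.null(res) || res$status != "ok") return(base)
    base$micros <- sum(res$counters$accepted - res$counters$discarded)
    base$macros <- res$macros
    base$rejected <- sum(res$counters$rejected)
    base$discarded <- sum(res$counters$discarded)
    base$rhs_calls <- sum(res$counters$rhs_evals + res$counters$jac_evals)
    base$rhs_calls_no_jac <- sum(res$counters$rhs_evals)
    base$switches <- res$switches
    base$status <- "ok"
    for (ob in observables) {
      obs <- problem$observables[[ob]]
      tr <- res$trajectories[[obs$component]]
      val <- sample_trajectory(tr, t_eval)[1L, obs$index]
      ref_idx <- observable_ref_index(problem, obs)
      base[[paste0("err_", ob)]] <- relative_error(x_ref[ref_idx], val)
    }
    base
  })
  do.call(rbind, rows)
}

# map an observable's (component, index) to its position in the monolithic
# state vector via problem$monolithic$split
observable_ref_index <- function(problem, obs) {
  problem$monolithic$split[[obs$component]][obs$index]
}
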