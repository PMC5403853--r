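#' Engine configuration
#'
#' @param strategy Gauss-Seidel organization: `"fast-first"` solves the
#'   faster subset across each slower micro step before the slower corrector
#'   step; `"slow-first"` steps the slower component first (extrapolating
#'   its faster partners) and then advances the faster subset by
#'   interpolation of the already-computed slow values.
#' @param communication `"synchronous"` shrinks each faster component's last
#'   micro step to land exactly on the enclosing interval endpoint, so every
#'   slower grid is a subset of the faster grids; `"asynchronous"` lets the
#'   last micro step overshoot the endpoint (by at most one predicted step)
#'   and obtains endpoint values by interpolation, keeping the overshot
#'   history for the next interval.
#' @param mode `"multirate"` gives each component its own adaptive step;
#'   `"singlerate"` forces one shared (time-varying) step for all
#'   components, reproducing the reference coupling method.
#' @param t_end end of the integration interval (s).
#' @param controller a [controller_settings()] list.
#' @param max_rejections consecutive rejections tolerated per step before
#'   aborting with a diagnostic.
#' @param keep_trace record one log row per accepted/rejected step attempt
#'   (component, times, errors, approximation kinds).
#' @return List of class `mr_config`.
#' @export
mr_config <- function(strategy = c("slow-first", "fast-first"),
                      communication = c("asynchronous", "synchronous"),
                      mode = c("multirate", "singlerate"),
                      t_end = 1,
                      controller = controller_settings(),
                      max_rejections = 20L,
                      keep_trace = TRUE) {
  strategy <- match.arg(strategy)
  communication <- match.arg(communication)
  mode <- match.arg(mode)
  stopifnot(t_end >= 0)
  structure(list(strategy = strategy, communication = communication,
                 mode = mode, t_end = t_end, controller = controller,
                 max_rejections = as.integer(max_rejections),
                 keep_trace = isTRUE(keep_trace)),
            class = "mr_config")
}

#' Order components slowest to fastest
#'
#' Stable sort by predicted step size, descending (largest predicted step =
#' slowest component first). Ties keep the prior order.
#'
#' @param comps list of components, each with a predicted step `h`.
#' @return The reordered list.
#' @export
order_components <- function(comps) {
  hs <- vapply(comps, function(c) c$h, numeric(1))
  comps[order(-hs)] # order() is a stable sort
}

tiny_rel <- function(t) 1e-12 * max(1, abs(t))

# Gather frozen exchanged inputs for component index r at time t.
# `solved` is a logical vector marking partners already advanced past the
# current interval (interpolated on the bracketing window); others are
# extrapolated from their newest samples.
gather_exchanged <- function(comps, r, t, solved, want_kinds = FALSE) {
  u <- list()
  kinds <- character(0)
  for (s in seq_along(comps)) {
    if (s == r) next
    src <- comps[[s]]
    n <- length(src$xs_times)
    idx <- if (solved[s]) hist_near(src$xs_times, t, 3L)
           else seq.int(max(1L, n - 2L), n)
    u[[src$id]] <- poly2_eval(src$xs_times[idx],
                              src$xs_vals[idx, , drop = FALSE], t)
    if (want_kinds)
      kinds[src$id] <- classify_query(src$xs_times[idx], t)
  }
  attr(u, "kinds") <- kinds
  u
}

# one local step attempt of a component: BDF1 if only one history point,
# else non-uniform BDF2; returns stepper output plus the local error
attempt_step <- function(comp, h, u) {
  nh <- length(comp$hist$times)
  res <- if (nh < 2L) {
    tryCatch(
      bdf1_startup_step(comp$x, comp$t, h, comp$rhs, u,
                        rtol = comp$reltol, atol = comp$abstol,
                        cache = comp$newton_cache),
      error = function(e) NULL)
  } else {
    bdf2_step(comp$hist, h, comp$rhs, u,
              rtol = comp$reltol, atol = comp$abstol,
              cache = comp$newton_cache)
  }
  if (is.null(res)) return(NULL)
  comp$nrhs <- comp$nrhs + res$report$rhs_evals
  comp$njac <- comp$njac + res$report$jac_evals
  if (!res$report$converged) return(NULL)
  err <- estimate_local_error(res$x, res$x_pred, comp$reltol, comp$abstol)
  c(res, list(local = err$local_scalar))
}

trace_add <- function(state, comp, t0, t1, h, local, combined, accepted, kinds) {
  if (!state$cfg$keep_trace) return(invisible(NULL))
  state$trace[[length(state$trace) + 1L]] <-
    list(comp$id, t0, t1, h, local, combined, accepted,
         paste(names(kinds), kinds, sep = ":", collapse = ";"))
  invisible(NULL)
}

finalize_trace <- function(rows) {
  if (length(rows) == 0L) return(NULL)
  col <- function(i, cast) cast(vapply(rows, function(r) r[[i]],
                                       FUN.VALUE = cast(NA)))
  data.frame(component = col(1L, as.character), t0 = col(2L, as.numeric),
             t1 = col(3L, as.numeric), h = col(4L, as.numeric),
             local = col(5L, as.numeric), combined = col(6L, as.numeric),
             accepted = col(7L, as.logical), kinds = col(8L, as.character),
             stringsAsFactors = FALSE)
}

#' Recursively advance an ordered component set across an interval
#'
#' The multirate recursion: component `r` (the slowest of `comps[r..p]`)
#' takes adaptive micro steps across `[comps[[r]]$t, t1]`. For each micro
#' step, exchanged inputs from already-solved partners are interpolated and
#' from not-yet-solved partners extrapolated; the faster subset is advanced
#' over the micro step by a recursive call; the component's combined error
#' (its own local error maximized with the faster subset's accepted errors
#' over the overlapping interval) gates acceptance. A rejection rolls back
#' the component and all faster components to their pre-step snapshots.
#'
#' Called by [mr_run()]; exposed for testing. `single_step = TRUE` makes the
#' outermost component take exactly one accepted step (the macro step).
#'
#' @param comps components ordered slowest to fastest.
#' @param r index of the current component.
#' @param t1 interval end (s).
#' @param state engine state environment (config, trace, counters).
#' @param single_step take one accepted step instead of stepping to `t1`.
#' @return Invisibly, the max combined error of the accepted steps taken.
#' @keywords internal
solve_interval <- function(comps, r, t1, state, single_step = FALSE) {
  comp <- comps[[r]]
  p <- length(comps)
  cfg <- state$cfg
  slow_first <- cfg$strategy == "slow-first"
  sync <- cfg$communication == "synchronous"
  # which partners count as already solved while component r steps:
  # slower ones once they have stepped ahead (slow-first), faster ones after
  # the recursive call (fast-first)
  max_combined <- 0
  while (comp$t < t1 - tiny_rel(t1)) {
    h_try <- min(comp$h, comp$h_max)
    if (single_step || sync || r == 1L) h_try <- min(h_try, t1 - comp$t)
    n_rej <- 0L
    repeat {
      t_new <- comp$t + h_try
      snaps <- lapply(comps[r:p], component_snapshot)
      ok <- TRUE
      if (!slow_first && r < p) {
        # fast-first: faster subset first, across [comp$t, t_new]
        solve_interval(comps, r + 1L, t_new, state)
      }
      solved <- rep(FALSE, p)
      if (r > 1L) solved[seq_len(r - 1L)] <- slow_first
      if (r < p) solved[seq.int(r + 1L, p)] <- !slow_first
      u <- gather_exchanged(comps, r, t_new, solved, want_kinds = cfg$keep_trace)
      res <- attempt_step(comp, h_try, u)
      if (is.null(res)) {
        # Newton failure: treat as a rejection, halve the step
        component_restore_all(comps, r, p, snaps)
        comp$n_rej <- comp$n_rej + 1L
        n_rej <- n_rej + 1L
        if (n_rej > cfg$max_rejections)
          stop(sprintf("component '%s': implicit solve failed repeatedly near t = %g",
                       comp$id, comp$t))
        h_try <- h_try / 2
        next
      }
      local <- res$local
      if (slow_first && r < p && local <= 1) {
        # commit tentatively so the faster subset can interpolate the new
        # value, then recurse across the accepted-candidate interval
        component_commit(comp, t_new, res$x, local, local, comp$h)
        solve_interval(comps, r + 1L, t_new, state)
        # update the tentative log entry's combined value now that the
        # faster subset's errors over the interval are known
        faster <- err_for_interval(comps[[r + 1L]], comp$t - h_try, t_new)
        combined <- combine_with_faster(local, faster)
        set_last_combined(comp, combined)
      } else if (slow_first && r < p) {
        combined <- local # early reject on the component's own error
      } else if (r < p) {
        faster <- err_for_interval(comps[[r + 1L]], comp$t, t_new)
        combined <- combine_with_faster(local, faster)
      } else {
        combined <- local
      }
      if (accept_step(combined)) {
        # prediction uses the component's own local error; the combined
        # error gates acceptance and drives the retry step after a
        # rejection (see the methods vignette on controller wiring)
        h_next <- predict_step(local, h_try, cfg$controller)
        if (slow_first && r < p) {
          comp$h <- h_next
          comp$last_err <- combined
        } else {
          component_commit(comp, t_new, res$x, local, combined, h_next)
        }
        trace_add(state, comp, t_new - h_try, t_new, h_try, local, combined,
                  TRUE, attr(u, "kinds"))
        max_combined <- max(max_combined, combined)
        break
      }
      # rejection: roll back this component and every faster one
      component_restore_all(comps, r, p, snaps)
      comp$n_rej <- comp$n_rej + 1L
      n_rej <- n_rej + 1L
      trace_add(state, comp, comp$t, t_new, h_try, local, combined,
                FALSE, attr(u, "kinds"))
      if (n_rej > cfg$max_rejections)
        stop(sprintf("component '%s': %d consecutive rejections near t = %g",
                     comp$id, n_rej, comp$t))
      h_try <- min(predict_step(combined, h_try, cfg$controller), h_try)
    }
    if (single_step) break
    if (!sync && r > 1L && comp$t >= t1 - tiny_rel(t1)) break
  }
  invisible(max_combined)
}

component_restore_all <- function(comps, r, p, snaps) {
  for (i in seq.int(r, p)) component_restore(comps[[i]], snaps[[i - r + 1L]])
}

#' Run a coupled multirate (or singlerate) simulation
#'
#' Outermost loop of the algorithm: components are (re)ordered slowest to
#' fastest before each macro step, the macro interval is set to the slowest
#' component's predicted step, and the ordered set is advanced by the
#' recursive interval solver. In singlerate mode all components share one
#' adaptive step per macro interval instead.
#'
#' @param comps list of components created by [new_component()].
#' @param cfg an [mr_config()].
#' @param t0 start time (s).
#' @param h0 optional named numeric of initial steps per component id;
#'   defaults to the [initial_step()] heuristic.
#' @return An object of class `mr_result`: per-component trajectories
#'   (`$trajectories`, each with `times` and a state matrix), `$counters`
#'   (per-component data frame of rhs evaluations, Jacobian evaluations,
#'   accepted/rejected/discarded steps), run totals (`$macros`,
#'   `$switches`), the step `$trace` (if kept), `$status`
#'   (`"ok"`/`"aborted"`) and the echoed `$config`.
#' @export
mr_run <- function(comps, cfg, t0 = 0, h0 = NULL) {
  stopifnot(inherits(cfg, "mr_config"))
  ids <- vapply(comps, function(c) c$id, character(1))
  if (anyDuplicated(ids)) stop("mr_run: duplicate component ids")
  state <- new.env(parent = emptyenv())
  state$cfg <- cfg
  state$trace <- list()
  for (comp in comps) component_init(comp, t0)
  # initial exchanged guesses: partners at their initial values
  for (r in seq_along(comps)) {
    comp <- comps[[r]]
    u0 <- gather_exchanged(comps, r, t0, solved = rep(FALSE, length(comps)))
    f0 <- comp$rhs(t0, comp$x, u0)
    comp$nrhs <- comp$nrhs + 1L
    comp$h <- if (!is.null(h0) && comp$id %in% names(h0)) h0[[comp$id]]
              else initial_step(f0, comp$x, cfg$t_end - t0, comp$reltol, comp$abstol)
  }
  macros <- 0L
  switches <- 0L
  prev_order <- ids
  status <- "ok"
  message_txt <- NULL
  run_core <- function() {
    while (min(vapply(comps, function(c) c$t, numeric(1))) <
           cfg$t_end - tiny_rel(cfg$t_end)) {
      comps <<- order_components(comps)
      cur_order <- vapply(comps, function(c) c$id, character(1))
      if (!identical(cur_order, prev_order)) {
        switches <<- switches + 1L
        prev_order <<- cur_order
      }
      if (cfg$mode == "singlerate") {
        singlerate_macro_step(comps, state)
      } else {
        # the macro interval is the slowest component's next accepted step:
        # solve_interval clips its attempt to t_end and stops after one
        # accepted step, so a rejection shrinks the macro interval itself
        solve_interval(comps, 1L, cfg$t_end, state, single_step = TRUE)
      }
      macros <<- macros + 1L
    }
  }
  err <- tryCatch({ run_core(); NULL }, error = function(e) conditionMessage(e))
  if (!is.null(err)) { status <- "aborted"; message_txt <- err }
  counters <- do.call(rbind, lapply(comps, function(c)
    data.frame(component = c$id, rhs_evals = c$nrhs, jac_evals = c$njac,
               accepted = c$n_acc, rejected = c$n_rej,
               discarded = c$n_discarded, stringsAsFactors = FALSE)))
  trajectories <- lapply(comps, component_trajectory)
  names(trajectories) <- vapply(comps, function(c) c$id, character(1))
  structure(list(trajectories = trajectories, counters = counters,
                 macros = macros, switches = switches,
                 trace = if (cfg$keep_trace) finalize_trace(state$trace) else NULL,
                 components = comps, status = status, message = message_txt,
                 config = cfg),
            class = "mr_result")
}

# one shared-step macro step: every component takes the same step h (the
# smallest predicted), solved in Gauss-Seidel order per the strategy;
# the shared combined error gates all of them jointly
singlerate_macro_step <- function(comps, state) {
  cfg <- state$cfg
  p <- length(comps)
  ord <- if (cfg$strategy == "fast-first") rev(seq_len(p)) else seq_len(p)
  h_try <- min(vapply(comps, function(c) min(c$h, c$h_max), numeric(1)))
  t_now <- comps[[1L]]$t
  h_try <- min(h_try, cfg$t_end - t_now)
  n_rej <- 0L
  repeat {
    t_new <- t_now + h_try
    snaps <- lapply(comps, component_snapshot)
    locals <- numeric(p)
    stepped <- rep(FALSE, p)
    failed <- FALSE
    results <- vector("list", p)
    for (k in ord) {
      comp <- comps[[k]]
      u <- gather_exchanged(comps, k, t_new, solved = stepped,
                            want_kinds = cfg$keep_trace)
      res <- attempt_step(comp, h_try, u)
      if (is.null(res)) { failed <- TRUE; break }
      results[[k]] <- res
      locals[k] <- res$local
      # commit immediately so later components in the order interpolate it
      component_commit(comp, t_new, res$x, res$local, res$local, comp$h)
      stepped[k] <- TRUE
      trace_add(state, comp, t_now, t_new, h_try, res$local, NA, NA,
                attr(u, "kinds"))
    }
    combined <- if (failed) Inf else max(locals)
    if (!failed && accept_step(combined)) {
      h_next <- predict_step(combined, h_try, cfg$controller)
      for (k in seq_len(p)) {
        comps[[k]]$h <- h_next
        set_last_combined(comps[[k]], combined)
      }
      return(invisible(combined))
    }
    for (k in seq_len(p)) component_restore(comps[[k]], snaps[[k]])
    for (k in seq_len(p)) comps[[k]]$n_rej <- comps[[k]]$n_rej + 1L
    n_rej <- n_rej + 1L
    if (n_rej > cfg$max_rejections)
      stop(sprintf("singlerate: %d consecutive rejections near t = %g",
                   n_rej, t_now))
    h_try <- if (failed) h_try / 2
             else min(predict_step(combined, h_try, cfg$controller), h_try)
  }
}

#' Standalone adaptive BDF2 solve of a single uncoupled system
#'
#' Reference single-system integrator built from the same primitives as the
#' engine (BDF1 startup, non-uniform BDF2 corrector, quadratic predictor
#' error estimate, elementary controller). The multirate engine run on a
#' single component degenerates to exactly this loop.
#'
#' @param rhs derivative function `f(t, x, u)`; `u` is passed as `NULL`.
#' @param x0 initial state.
#' @param t0,t_end integration window (s).
#' @param reltol,abstol tolerances.
#' @param controller a [controller_settings()] list.
#' @param h0 optional initial step; defaults to [initial_step()].
#' @param h_max step-size cap (finite for discontinuous forcing, so pulses
#'   shorter than the grown step cannot be silently stepped over).
#' @param max_rejections rejection cap per step.
#' @return List with `times`, `states` (matrix), `nrhs`, `njac`,
#'   `accepted`, `rejected`.
#' @export
bdf2_solve <- function(rhs, x0, t0 = 0, t_end = 1, reltol = 1e-6,
                       abstol = reltol * 1e-3,
                       controller = controller_settings(), h0 = NULL,
                       h_max = Inf, max_rejections = 20L) {
  comp <- new_component("standalone", rhs, x0, reltol = reltol, abstol = abstol)
  comp$h_max <- h_max
  component_init(comp, t0)
  f0 <- rhs(t0, comp$x, NULL)
  comp$nrhs <- comp$nrhs + 1L
  comp$h <- if (is.null(h0)) initial_step(f0, comp$x, t_end - t0, reltol, comp$abstol)
            else h0
  while (comp$t < t_end - tiny_rel(t_end)) {
    h_try <- min(comp$h, comp$h_max)
    h_try <- min(h_try, t_end - comp$t)
    n_rej <- 0L
    repeat {
      res <- attempt_step(comp, h_try, NULL)
      if (is.null(res)) {
        comp$n_rej <- comp$n_rej + 1L
        n_rej <- n_rej + 1L
        if (n_rej > max_rejections)
          stop(sprintf("bdf2_solve: implicit solve failed repeatedly near t = %g", comp$t))
        h_try <- h_try / 2
        next
      }
      if (accept_step(res$local)) {
        component_commit(comp, comp$t + h_try, res$x, res$local, res$local,
                         predict_step(res$local, h_try, controller))
        break
      }
      comp$n_rej <- comp$n_rej + 1L
      n_rej <- n_rej + 1L
      if (n_rej > max_rejections)
        stop(sprintf("bdf2_solve: %d consecutive rejections near t = %g",
                     n_rej, comp$t))
      h_try <- min(predict_step(res$local, h_try, controller), h_try)
    }
  }
  tr <- component_trajectory(comp)
  list(times = tr$times, states = tr$states,
       nrhs = comp$nrhs, njac = comp$njac,
       accepted = comp$n_acc, rejected = comp$n_rej)
}

#' Sample a trajectory on a user grid
#'
#' Quadratic interpolation of a stored trajectory (the nearest three
#' accepted points around each query time).
#'
#' @param traj a trajectory (`times` + `states`) from an `mr_result`.
#' @param times query times within the trajectory span.
#' @return Matrix with one row per query time.
#' @export
sample_trajectory <- function(traj, times) {
  out <- matrix(NA_real_, length(times), ncol(traj$states))
  for (i in seq_along(times)) {
    idx <- hist_near(traj$times, times[i], 3L)
    out[i, ] <- poly2_eval(traj$times[idx], traj$states[idx, , drop = FALSE],
                           times[i])
  }
  out
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result> %s | %s %s %s | macros %d, switches %d, status %s\n",
              paste(names(x$trajectories), collapse = " + "),
              x$config$mode, x$config$strategy, x$config$communication,
              x$macros, x$switches, x$status))
  print(x$counters, row.names = FALSE)
  invisible(x)
}
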