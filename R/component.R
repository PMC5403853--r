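#' Create a co-simulation component
#'
#' A component is one subsystem of the coupled problem: a right-hand side
#' `rhs(t, x, u)` taking its own state `x` and the exchanged inputs `u` (a
#' named list keyed by partner component id), an output (transformation)
#' function `g(x)` producing the vector communicated to partners, and its
#' own tolerances and adaptive step state. Components are mutable
#' environments: the engine advances them in place and snapshots them for
#' rollback.
#'
#' @param id character id, unique within a simulation.
#' @param rhs derivative function `f(t, x, u)`.
#' @param g output function of the state; defaults to the identity.
#' @param x0 initial state vector.
#' @param reltol scalar relative tolerance.
#' @param abstol absolute tolerance, scalar or vector (recycled).
#' @param retain history retention length (see [mr_history()]).
#' @return An environment of class `mr_component`.
#' @export
new_component <- function(id, rhs, x0, g = identity, reltol = 1e-6,
                          abstol = reltol * 1e-3, retain = 8L) {
  stopifnot(is.character(id), length(id) == 1L, reltol > 0, all(abstol > 0))
  e <- new.env(parent = baseenv())
  e$id <- id
  e$rhs <- rhs
  e$g <- g
  e$x <- as.numeric(x0)
  e$t <- NA_real_
  e$reltol <- reltol
  e$abstol <- rep_len(as.numeric(abstol), length(x0))
  e$h <- NA_real_          # predicted next step
  e$h_max <- Inf           # step cap (finite when the forcing is
                           # discontinuous, e.g. a pulse protocol)
  e$hist <- mr_history(length(x0), retain = retain)
  e$xs_times <- numeric(0) # exchange-sample window
  e$xs_vals <- NULL
  e$xs_retain <- as.integer(retain)
  # dense accepted trajectory + accepted-step error log, kept in
  # preallocated buffers (rollback only rewinds the fill counters)
  e$traj_t <- numeric(256L)
  e$traj_x <- matrix(NA_real_, 256L, length(x0))
  e$traj_n <- 0L
  e$log_mat <- matrix(NA_real_, 256L, 4L) # t0, t1, local, combined
  e$log_n <- 0L
  e$newton_cache <- new.env(parent = emptyenv()) # reused Jacobian
  e$nrhs <- 0L             # rhs evaluations inside Newton iterations
  e$njac <- 0L             # rhs evaluations spent on finite-difference Jacobians
  e$n_acc <- 0L            # locally accepted steps (monotone)
  e$n_rej <- 0L            # rejected step attempts
  e$n_discarded <- 0L      # accepted micro steps discarded by a slower rollback
  e$last_err <- NA_real_
  class(e) <- "mr_component"
  e
}

#' @export
print.mr_component <- function(x, ...) {
  cat(sprintf("<mr_component '%s'> dim %d, t = %s, h = %s, accepted %d, rejected %d\n",
              x$id, length(x$x),
              format(x$t), format(x$h), x$n_acc, x$n_rej))
  invisible(x)
}

# in-place buffered appends (avoids copying the buffers on each step)
push_traj <- function(comp, t, x) {
  n <- comp$traj_n + 1L
  if (n > length(comp$traj_t)) {
    add <- length(comp$traj_t)
    comp$traj_t <- c(comp$traj_t, numeric(add))
    comp$traj_x <- rbind(comp$traj_x, matrix(NA_real_, add, ncol(comp$traj_x)))
  }
  eval(substitute({traj_t[n] <- t; traj_x[n, ] <- x; traj_n <- n},
                  list(n = n, t = t, x = x)), comp)
  invisible(NULL)
}

push_log <- function(comp, t0, t1, local, combined) {
  n <- comp$log_n + 1L
  if (n > nrow(comp$log_mat))
    comp$log_mat <- rbind(comp$log_mat,
                          matrix(NA_real_, nrow(comp$log_mat), 4L))
  eval(substitute({log_mat[n, ] <- v; log_n <- n},
                  list(n = n, v = c(t0, t1, local, combined))), comp)
  invisible(NULL)
}

set_last_combined <- function(comp, combined) {
  eval(substitute(log_mat[n, 4L] <- v,
                  list(n = comp$log_n, v = combined)), comp)
  comp$last_err <- combined
  invisible(NULL)
}

# initialize time-dependent fields at t0 (history, exchange sample, traj)
component_init <- function(comp, t0) {
  comp$t <- t0
  comp$hist <- append_state(comp$hist, t0, comp$x)
  exchange_append(comp, t0, comp$g(comp$x))
  push_traj(comp, t0, comp$x)
  invisible(comp)
}

exchange_append <- function(comp, t, v) {
  v <- as.numeric(v)
  if (is.null(comp$xs_vals)) comp$xs_vals <- matrix(numeric(0), 0L, length(v))
  comp$xs_times <- c(comp$xs_times, t)
  comp$xs_vals <- rbind(comp$xs_vals, v, deparse.level = 0L)
  n <- length(comp$xs_times)
  if (n > comp$xs_retain) {
    keep <- seq.int(n - comp$xs_retain + 1L, n)
    comp$xs_times <- comp$xs_times[keep]
    comp$xs_vals <- comp$xs_vals[keep, , drop = FALSE]
  }
  invisible(comp)
}

# record an accepted step in the component (history, exchange, traj, log)
component_commit <- function(comp, t_new, x_new, local, combined, h_next) {
  t_prev <- comp$t
  comp$hist <- append_state(comp$hist, t_new, x_new)
  exchange_append(comp, t_new, comp$g(x_new))
  push_traj(comp, t_new, x_new)
  push_log(comp, t_prev, t_new, local, combined)
  comp$t <- t_new
  comp$x <- x_new
  comp$h <- h_next
  comp$last_err <- combined
  comp$n_acc <- comp$n_acc + 1L
  invisible(comp)
}

component_snapshot <- function(comp) {
  list(t = comp$t, x = comp$x, h = comp$h, hist = comp$hist,
       xs_times = comp$xs_times, xs_vals = comp$xs_vals,
       traj_n = comp$traj_n, log_n = comp$log_n,
       last_err = comp$last_err)
}

component_restore <- function(comp, snap) {
  discarded <- comp$log_n - snap$log_n
  if (discarded > 0L) comp$n_discarded <- comp$n_discarded + discarded
  comp$t <- snap$t
  comp$x <- snap$x
  comp$h <- snap$h
  comp$hist <- snap$hist
  comp$xs_times <- snap$xs_times
  comp$xs_vals <- snap$xs_vals
  comp$traj_n <- snap$traj_n
  comp$log_n <- snap$log_n
  comp$last_err <- snap$last_err
  invisible(comp)
}

# max combined error over accepted micro steps of `comp` whose interval
# [t0, t1] overlaps (a, b); with asynchronous communication a step that
# straddles the interval boundary is attributed to both intervals
err_for_interval <- function(comp, a, b) {
  out <- numeric(0)
  lm <- comp$log_mat
  for (i in rev(seq_len(comp$log_n))) {
    if (lm[i, 2L] <= a) break # log times increase; earlier steps end before a
    if (lm[i, 1L] < b) out <- c(out, lm[i, 4L])
  }
  out
}

component_trajectory <- function(comp) {
  idx <- seq_len(comp$traj_n)
  list(times = comp$traj_t[idx], states = comp$traj_x[idx, , drop = FALSE])
}

#' Query exchanged variables of a partner component at a time
#'
#' Returns the partner's exchanged (output) vector approximated at `t` by a
#' second-order polynomial through its stored exchange samples. A source
#' that has already been solved past `t` is interpolated on the bracketing
#' sample window; a source that has not yet advanced is extrapolated from
#' its newest three samples. The returned value is the frozen `u` passed to
#' the implicit step.
#'
#' @param source a component with at least one exchange sample.
#' @param t query time (s).
#' @param role `"already-solved"` or `"not-yet-solved"`.
#' @return List with `value` (vector) and `kind`
#'   (`"interpolation"`/`"extrapolation"`, from [classify_query()]).
#' @export
exchange_at <- function(source, t, role = c("not-yet-solved", "already-solved")) {
  role <- match.arg(role)
  n <- length(source$xs_times)
  if (n == 0L) stop(sprintf("exchange_at: component '%s' has no samples", source$id))
  if (role == "already-solved") {
    idx <- hist_near(source$xs_times, t, 3L)
  } else {
    idx <- seq.int(max(1L, n - 2L), n)
  }
  list(value = poly2_eval(source$xs_times[idx],
                          source$xs_vals[idx, , drop = FALSE], t),
       kind = classify_query(source$xs_times[idx], t))
}

#' Exchanged value of a fast component at a macro-interval endpoint
#'
#' With synchronous communication the fast component's last micro step was
#' shrunk to land exactly on the macro endpoint, so the stored sample is
#' returned. With asynchronous communication the fast grid is allowed to
#' overshoot the endpoint and the value is obtained by quadratic
#' interpolation on the bracketing micro points; the overshot history is
#' kept for the next macro interval.
#'
#' @param fast a component advanced at least to `t_end_macro`.
#' @param t_end_macro macro-interval endpoint (s).
#' @param communication `"synchronous"` or `"asynchronous"`.
#' @return The exchanged vector at `t_end_macro`.
#' @export
align_macro_end <- function(fast, t_end_macro,
                            communication = c("asynchronous", "synchronous")) {
  communication <- match.arg(communication)
  if (fast$t < t_end_macro - tiny_rel(t_end_macro))
    stop(sprintf("align_macro_end: component '%s' at t = %g has not reached %g",
                 fast$id, fast$t, t_end_macro))
  if (communication == "synchronous") {
    i <- which(abs(fast$xs_times - t_end_macro) <= tiny_rel(t_end_macro))
    if (length(i) == 0L)
      stop("align_macro_end: no synchronous sample at the macro endpoint")
    return(fast$xs_vals[max(i), ])
  }
  exchange_at(fast, t_end_macro, "already-solved")$value
}
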