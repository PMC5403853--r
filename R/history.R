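#' Time-stamped state history
#'
#' A `mr_history` stores a window of `(t, x)` pairs for one component: the
#' BDF history used by the stepper plus the stencil from which exchanged
#' variables and predictor values are approximated. Times are strictly
#' increasing; all state vectors share one dimension; at most `retain`
#' entries are kept (oldest dropped first).
#'
#' @param dim state-vector dimension.
#' @param retain maximum number of retained entries (default 8; never below
#'   3, since both the BDF2 stencil and the quadratic approximant need up to
#'   three points, and asynchronous communication interpolates across macro
#'   boundaries).
#' @return An object of class `mr_history`.
#' @export
mr_history <- function(dim, retain = 8L) {
  stopifnot(is.numeric(dim), length(dim) == 1L, dim >= 1)
  retain <- as.integer(retain)
  if (retain < 3L) stop("retain must be >= 3")
  structure(
    list(times = numeric(0),
         states = matrix(numeric(0), nrow = 0L, ncol = as.integer(dim)),
         retain = retain),
    class = "mr_history")
}

#' Append a state to a history
#'
#' Appends `(t, x)` and drops the oldest entries beyond the retention limit.
#' Time must be strictly greater than the last stored time.
#'
#' @param history an [mr_history()].
#' @param t time (s), strictly greater than the newest stored time.
#' @param x state vector of the history's dimension.
#' @return The updated `mr_history`.
#' @export
append_state <- function(history, t, x) {
  stopifnot(inherits(history, "mr_history"))
  n <- length(history$times)
  if (n > 0L && t <= history$times[n])
    stop(sprintf("append_state: t = %.17g does not exceed last stored time %.17g",
                 t, history$times[n]))
  if (length(x) != ncol(history$states))
    stop(sprintf("append_state: state dimension %d != history dimension %d",
                 length(x), ncol(history$states)))
  history$times <- c(history$times, t)
  history$states <- rbind(history$states, as.numeric(x), deparse.level = 0L)
  if (length(history$times) > history$retain) {
    keep <- seq.int(length(history$times) - history$retain + 1L,
                    length(history$times))
    history$times <- history$times[keep]
    history$states <- history$states[keep, , drop = FALSE]
  }
  history
}

#' @export
print.mr_history <- function(x, ...) {
  cat(sprintf("<mr_history> %d/%d entries, dim %d",
              length(x$times), x$retain, ncol(x$states)))
  if (length(x$times))
    cat(sprintf(", t in [%g, %g]", x$times[1L], x$times[length(x$times)]))
  cat("\n")
  invisible(x)
}

#' Quadratic (or lower) polynomial evaluation through sampled points
#'
#' Evaluates at `t_query` the unique polynomial through up to three
#' `(time, vector)` samples: a quadratic for three samples, the linear
#' interpolant for two, the constant for one. Works both inside the sample
#' span (interpolation) and outside it (extrapolation). The polynomial is
#' evaluated in Newton divided-difference form, which stays well conditioned
#' on strongly non-uniform spacings.
#'
#' @param times sample times (1 to 3, distinct).
#' @param values numeric matrix with one row per sample (a numeric vector is
#'   accepted for scalar samples).
#' @param t_query evaluation time.
#' @return Numeric vector: the polynomial value at `t_query`.
#' @export
poly2_eval <- function(times, values, t_query) {
  if (is.null(dim(values))) values <- matrix(values, nrow = length(times))
  n <- length(times)
  if (n == 0L) stop("poly2_eval: no samples")
  if (n > 3L) stop("poly2_eval: more than 3 samples")
  if (n != nrow(values)) stop("poly2_eval: times/values length mismatch")
  if (anyDuplicated(times)) stop("poly2_eval: duplicate sample times")
  if (n == 1L) return(values[1L, ])
  # Newton form: c0 + c1 (t - t1) + c2 (t - t1)(t - t2)
  c0 <- values[1L, ]
  c1 <- (values[2L, ] - values[1L, ]) / (times[2L] - times[1L])
  if (n == 2L) return(c0 + c1 * (t_query - times[1L]))
  d12 <- (values[3L, ] - values[2L, ]) / (times[3L] - times[2L])
  c2 <- (d12 - c1) / (times[3L] - times[1L])
  c0 + (t_query - times[1L]) * (c1 + c2 * (t_query - times[2L]))
}

#' Classify a query time against a sample span
#'
#' Returns `"extrapolation"` iff `t_query` lies strictly outside the closed
#' interval spanned by the sample times; a query exactly at an endpoint
#' counts as interpolation. Used for diagnostics of the Gauss-Seidel
#' strategies (which partner values were extrapolated versus interpolated).
#'
#' @param times sample times (non-empty).
#' @param t_query query time.
#' @return `"interpolation"` or `"extrapolation"`.
#' @export
classify_query <- function(times, t_query) {
  if (length(times) == 0L) stop("classify_query: no samples")
  if (t_query < min(times) || t_query > max(times)) "extrapolation"
  else "interpolation"
}

# Newest-`k` stencil of a history (times + rows), helper shared by the
# predictor and the exchanged-variable approximation.
hist_tail <- function(history, k = 3L) {
  n <- length(history$times)
  if (n == 0L) stop("history is empty")
  idx <- seq.int(max(1L, n - k + 1L), n)
  list(times = history$times[idx], states = history$states[idx, , drop = FALSE])
}

# Stencil of up to `k` consecutive samples chosen nearest to `t` (used when
# interpolating an already-advanced partner whose newest samples may lie
# beyond `t`): picks the window of consecutive indices bracketing `t` when
# possible, otherwise the nearest end window.
hist_near <- function(times, t, k = 3L) {
  n <- length(times)
  if (n == 0L) stop("history is empty")
  k <- min(k, n)
  # first index with time >= t
  j <- findInterval(t, times, left.open = FALSE) # last index with time <= t
  lo <- j - (k %/% 2L)
  lo <- max(1L, min(lo, n - k + 1L))
  seq.int(lo, lo + k - 1L)
}
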