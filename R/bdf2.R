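#' Non-uniform BDF2 coefficients
#'
#' Coefficients of the second-order backward differentiation formula on a
#' non-uniform grid,
#' \deqn{x_{n+1} = \alpha_1 x_n + \alpha_2 x_{n-1} + \beta h_{n+1} f(t_{n+1}, x_{n+1}),}
#' parameterized by the step ratio \eqn{\gamma = h_{n+1}/h_n}:
#' \eqn{\alpha_2 = -\gamma^2/(2\gamma+1)}, \eqn{\alpha_1 = 1 - \alpha_2},
#' \eqn{\beta = (\gamma+1)/(2\gamma+1)}. At \eqn{\gamma = 1} these reduce to
#' the classic equidistant BDF2 values (4/3, -1/3, 2/3).
#'
#' @param h_next upcoming step \eqn{h_{n+1}} (s), positive.
#' @param h_prev previous step \eqn{h_n} (s), positive.
#' @return List with `gamma`, `alpha1`, `alpha2`, `beta`.
#' @export
bdf2_coefficients <- function(h_next, h_prev) {
  if (!is.finite(h_next) || h_next <= 0) stop("bdf2_coefficients: h_next must be > 0")
  if (!is.finite(h_prev) || h_prev <= 0) stop("bdf2_coefficients: h_prev must be > 0")
  gamma <- h_next / h_prev
  alpha2 <- -gamma^2 / (2 * gamma + 1)
  list(gamma = gamma,
       alpha1 = 1 - alpha2,
       alpha2 = alpha2,
       beta = (gamma + 1) / (2 * gamma + 1))
}

# Damped (modified) Newton iteration for the implicit relation
# x = base + c * f(t, x, u). The Jacobian of f is formed by forward
# differences (perturbation sqrt(eps) scaled per component) and reused both
# across iterations and - through the optional `cache` environment - across
# steps, as in standard stiff-solver practice; only the iteration matrix
# I - c*J is refactored each step. If the iteration fails to converge on a
# stale Jacobian it is rebuilt once at the current point and the iteration
# restarted before failure is reported. Convergence:
# max_i |dx_i| / (rtol*|x_i| + atol_i) <= 0.1, i.e. the nonlinear-solve
# error is kept an order below the discretization tolerance. Every f call
# is counted; Jacobian columns are tallied separately so cost metrics can
# be reported inclusive or exclusive of differencing.
newton_solve <- function(base, cfac, t_new, rhs, u, x_guess, rtol, atol,
                         max_iter = 10L, cache = NULL) {
  n <- length(x_guess)
  nrhs <- 0L
  njac <- 0L

  fd_jacobian <- function(x, fx) {
    J <- matrix(0, n, n)
    pert <- sqrt(.Machine$double.eps) * pmax(abs(x), atol, 1e-8)
    for (j in seq_len(n)) {
      xp <- x
      xp[j] <- xp[j] + pert[j]
      J[, j] <- (rhs(t_new, xp, u) - fx) / pert[j]
      njac <<- njac + 1L
    }
    J
  }

  iterate <- function(J, x0, f0) {
    A <- diag(n) - cfac * J
    Alu <- tryCatch(lu_factor(A), error = function(e) NULL)
    if (is.null(Alu))
      return(list(x = x0, converged = FALSE, iterations = 0L, residual = Inf))
    x <- x0
    g <- x - base - cfac * f0
    converged <- FALSE
    iter <- 0L
    while (iter < max_iter) {
      iter <- iter + 1L
      dx <- lu_solve(Alu, -g)
      lambda <- 1
      g_norm <- sqrt(sum(g^2))
      for (try in 1:5) { # damping: halve until the residual norm decreases
        x_try <- x + lambda * dx
        f_try <- rhs(t_new, x_try, u); nrhs <<- nrhs + 1L
        g_try <- x_try - base - cfac * f_try
        if (sqrt(sum(g_try^2)) <= g_norm || g_norm == 0) break
        lambda <- lambda / 2
      }
      scaled <- max(abs(lambda * dx) / (rtol * abs(x_try) + atol))
      x <- x_try
      g <- g_try
      if (scaled <= 0.1) { converged <- TRUE; break }
    }
    list(x = x, converged = converged, iterations = iter,
         residual = max(abs(g)))
  }

  fx <- rhs(t_new, x_guess, u); nrhs <- nrhs + 1L
  have_cached <- !is.null(cache) && !is.null(cache$J) && nrow(cache$J) == n
  J <- if (have_cached) cache$J else fd_jacobian(x_guess, fx)
  res <- iterate(J, x_guess, fx)
  if (!res$converged && have_cached) {
    # stale Jacobian: rebuild at the current point and retry once
    fx2 <- rhs(t_new, res$x, u); nrhs <- nrhs + 1L
    J <- fd_jacobian(res$x, fx2)
    res <- iterate(J, res$x, fx2)
  }
  if (!is.null(cache)) cache$J <- J
  c(res, list(rhs_evals = nrhs, jac_evals = njac))
}

lu_factor <- function(A) {
  n <- nrow(A)
  if (n == 1L) {
    if (A[1L] == 0) stop("singular")
    return(list(n = 1L, a = A[1L]))
  }
  if (n == 2L) {
    det <- A[1L, 1L] * A[2L, 2L] - A[1L, 2L] * A[2L, 1L]
    if (det == 0) stop("singular")
    return(list(n = 2L, A = A, det = det))
  }
  # reusable decomposition for the general case
  list(n = n, qr = qr(A, LAPACK = TRUE))
}

lu_solve <- function(fac, b) {
  if (fac$n == 1L) return(b / fac$a)
  if (fac$n == 2L) {
    A <- fac$A
    c(A[2L, 2L] * b[1L] - A[1L, 2L] * b[2L],
      A[1L, 1L] * b[2L] - A[2L, 1L] * b[1L]) / fac$det
  } else solve.qr(fac$qr, b)
}

#' One implicit BDF2 step on a non-uniform grid
#'
#' Advances a component from its newest history point by `h`, solving the
#' decoupled implicit relation
#' \eqn{x_{n+1} = \alpha_1 x_n + \alpha_2 x_{n-1} + \beta h f(t_{n+1}, x_{n+1}, u)}
#' with a damped Newton iteration. Exchanged inputs `u` are frozen at their
#' \eqn{t_{n+1}} approximation for the whole solve: the coupling enters only
#' through the supplied values, never through a joint implicit system.
#'
#' @param history an [mr_history()] with at least 2 entries.
#' @param h step size (s), positive.
#' @param rhs function `f(t, x, u)` returning the state derivative.
#' @param u exchanged inputs at `t_new` (passed through to `rhs`).
#' @param rtol,atol tolerances scaling the Newton convergence test.
#' @param x_guess optional Newton starting point; defaults to the quadratic
#'   extrapolation of the newest history entries (the predictor).
#' @return List with `x` (the new state), `t` (the new time), `x_pred` (the
#'   polynomial predictor at `t_new`, reused by the error estimate) and
#'   `report` (`converged`, `iterations`, `residual`, `rhs_evals`,
#'   `jac_evals`).
#' @export
bdf2_step <- function(history, h, rhs, u = NULL, rtol = 1e-6,
                      atol = 1e-9, x_guess = NULL, cache = NULL) {
  n <- length(history$times)
  if (n < 2L) stop("bdf2_step: history needs at least 2 entries")
  if (!is.finite(h) || h <= 0) stop("bdf2_step: h must be > 0")
  t_n <- history$times[n]
  h_prev <- t_n - history$times[n - 1L]
  co <- bdf2_coefficients(h, h_prev)
  t_new <- t_n + h
  x_n <- history$states[n, ]
  x_nm1 <- history$states[n - 1L, ]
  st <- hist_tail(history, 3L)
  x_pred <- poly2_eval(st$times, st$states, t_new)
  if (is.null(x_guess)) x_guess <- x_pred
  atol <- rep_len(atol, length(x_n))
  base <- co$alpha1 * x_n + co$alpha2 * x_nm1
  sol <- newton_solve(base, co$beta * h, t_new, rhs, u, x_guess, rtol, atol,
                      cache = cache)
  list(x = sol$x, t = t_new, x_pred = x_pred,
       report = sol[c("converged", "iterations", "residual",
                      "rhs_evals", "jac_evals")])
}

#' Backward-Euler startup step
#'
#' BDF2 needs two history points; the very first step of every component is
#' taken with the implicit Euler rule
#' \eqn{x_{1} = x_0 + h f(t_0 + h, x_{1}, u)}, solved by the same damped
#' Newton iteration.
#'
#' @param x0 initial state vector.
#' @param t0 initial time (s).
#' @param h step size (s), positive.
#' @inheritParams bdf2_step
#' @return Same shape as [bdf2_step()]; `x_pred` is the constant predictor
#'   `x0`.
#' @export
bdf1_startup_step <- function(x0, t0, h, rhs, u = NULL, rtol = 1e-6,
                              atol = 1e-9, cache = NULL) {
  if (!is.finite(h) || h <= 0) stop("bdf1_startup_step: h must be > 0")
  t_new <- t0 + h
  atol <- rep_len(atol, length(x0))
  sol <- newton_solve(x0, h, t_new, rhs, u, x0, rtol, atol, cache = cache)
  if (!sol$converged)
    stop("bdf1_startup_step: Newton iteration failed to converge")
  list(x = sol$x, t = t_new, x_pred = x0,
       report = sol[c("converged", "iterations", "residual",
                      "rhs_evals", "jac_evals")])
}
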