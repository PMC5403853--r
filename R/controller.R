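#' Normalized local discretization error (predictor-corrector)
#'
#' Component-wise normalized difference between the implicit BDF2 corrector
#' and the second-order polynomial predictor:
#' \deqn{\epsilon_i = \frac{|x_i - \hat x_i|}{relTOL\,|x_i| + absTOL_i},}
#' with the scalar estimate the maximum over components. A value of 1 marks
#' the acceptance boundary.
#'
#' @param x_corrected corrector (accepted candidate) state vector.
#' @param x_predicted predictor state vector, same dimension.
#' @param reltol scalar relative tolerance (> 0).
#' @param abstol absolute tolerance, scalar or per-variable vector (> 0).
#' @return List with `componentwise` (vector) and `local_scalar` (max).
#' @export
estimate_local_error <- function(x_corrected, x_predicted, reltol, abstol) {
  if (length(x_corrected) != length(x_predicted))
    stop("estimate_local_error: dimension mismatch")
  if (reltol < 0 || any(abstol <= 0))
    stop("estimate_local_error: tolerances must be positive")
  abstol <- rep_len(abstol, length(x_corrected))
  cw <- abs(x_corrected - x_predicted) /
    (reltol * abs(x_corrected) + abstol)
  list(componentwise = cw, local_scalar = max(cw))
}

#' Combine a component's local error with its faster neighbours' errors
#'
#' The coupled error rule: a slower component's step is gated not only by
#' its own local error but by the maximum accepted error of the next-faster
#' component over the overlapping time interval. The combined value is the
#' maximum of the two; the fastest component (empty `faster_errors`) keeps
#' its local value.
#'
#' @param local_scalar scalar local error of the current component.
#' @param faster_errors numeric vector of accepted micro-step errors of the
#'   next-faster component over the overlapping interval (may be empty).
#' @return Scalar combined error.
#' @export
combine_with_faster <- function(local_scalar, faster_errors = numeric(0)) {
  if (length(faster_errors) == 0L) return(local_scalar)
  max(local_scalar, max(faster_errors))
}

#' Step acceptance rule
#'
#' A step is accepted iff its combined normalized error is at most 1.
#'
#' @param combined scalar combined error (>= 0).
#' @return `TRUE` (accept) or `FALSE` (reject).
#' @export
accept_step <- function(combined) {
  stopifnot(combined >= 0)
  combined <= 1
}

#' Default controller settings
#'
#' The elementary step-size controller for a second-order method: exponent
#' `1/(order+1) = 1/3`, safety 0.9, growth clamps `[0.2, 2]`. The clamps
#' keep consecutive step ratios (and hence the BDF2 coefficients) well
#' conditioned and the step sequence smooth.
#'
#' @param safety safety factor in (0, 1].
#' @param facmin,facmax step-ratio clamps, `0 < facmin < 1 < facmax`.
#' @param k exponent denominator (method order + 1).
#' @return List of controller settings.
#' @export
controller_settings <- function(safety = 0.9, facmin = 0.2, facmax = 2,
                                k = 3) {
  stopifnot(safety > 0, safety <= 1, facmin > 0, facmin < 1, facmax > 1)
  list(safety = safety, facmin = facmin, facmax = facmax, k = k)
}

#' Predict the next step size
#'
#' Elementary controller: \eqn{h_{next} = h \cdot
#' \mathrm{clamp}(safety \cdot \epsilon^{-1/k}, facmin, facmax)} with
#' \eqn{k = 3} for BDF2. A zero error takes the maximum growth factor.
#' After a rejection the caller additionally caps `h_next <= h_current`.
#'
#' @param combined scalar combined error of the attempted step.
#' @param h_current attempted step size (s), positive.
#' @param settings a [controller_settings()] list.
#' @return Next step size (s).
#' @export
predict_step <- function(combined, h_current, settings = controller_settings()) {
  stopifnot(h_current > 0, combined >= 0)
  fac <- if (combined == 0) settings$facmax
         else settings$safety * combined^(-1 / settings$k)
  fac <- min(settings$facmax, max(settings$facmin, fac))
  h_current * fac
}

#' Initial step size heuristic
#'
#' \eqn{h_0 = \min(10^{-4} T_{total}, h_{curv})} where the curvature term
#' scales the tolerance against the initial derivative:
#' \eqn{h_{curv} = \sqrt{tol} / \max_i(|f_i(t_0,x_0)| / s_i)} with scale
#' \eqn{s_i = reltol |x_i| + abstol_i}. Deliberately conservative; the
#' controller grows the step geometrically afterwards.
#'
#' @param f0 derivative at the initial state.
#' @param x0 initial state.
#' @param t_total total integration time (s).
#' @param reltol,abstol component tolerances.
#' @return Initial step (s).
#' @export
initial_step <- function(f0, x0, t_total, reltol, abstol) {
  abstol <- rep_len(abstol, length(x0))
  scale <- reltol * abs(x0) + abstol
  rate <- max(abs(f0) / scale, .Machine$double.eps)
  min(1e-4 * t_total, sqrt(reltol + min(abstol)) / rate)
}
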