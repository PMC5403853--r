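#' Synthetic two-timescale coupled benchmark problem
#'
#' A desk-scale linear stand-in for the electrical-chemical coupling
#' structure: a slow relaxation component mutually coupled to a stiff fast
#' component driven by a sinusoidal forcing. The fast component carries two
#' states - the stiff driven state \eqn{y} and a low-pass filtered copy
#' \eqn{z} - and its output exposes either of them. Exposing \eqn{y}
#' (`signal_speed = "fast"`) mimics a flux-like, rapidly varying exchanged
#' signal; exposing \eqn{z} (`"slow"`) mimics a concentration-like smooth
#' signal. The contrast reproduces, at desk scale, the coupling-efficiency
#' phenomenology of the two coupling variants of the electrical-chemical
#' test case (a fast exchanged signal drags the slow component's
#' controller to small steps).
#'
#' \deqn{\dot x = (-(x - c\,u_f))/\tau_{slow}}
#' \deqn{\dot y = (-(y - c\,x - A\,F(t)))/\tau_{fast}, \quad
#'       \dot z = -(z - y)/\tau_{filt}}
#'
#' The drive is \eqn{F(t) = \sin(2\pi f t) + a_r \sin(2\pi f_r t)}: a
#' resolvable carrier plus a small-amplitude, much faster ripple. The
#' ripple emulates the high-frequency content of a flux-like exchanged
#' signal: it is orders of magnitude below the carrier, so an adaptive
#' integrator consuming the raw signal `y` samples it at effectively
#' arbitrary phase unless its tolerance forces resolution, while the
#' filtered output `z` is clean of it. With `ripple_amp = 0` the drive is
#' a plain sinusoid.
#'
#' @param stiffness_ratio \eqn{\tau_{slow}/\tau_{fast}} (> 1; default 1000).
#' @param coupling_strength mutual coupling constant \eqn{c} (default 0.5;
#'   0 decouples the pair, for which the closed-form solution is exact).
#' @param signal_speed which fast state the fast component communicates.
#' @param tau_slow slow time constant (s).
#' @param tau_filt filter time constant of the smoothed output (s).
#' @param forcing_amplitude,forcing_freq carrier amplitude and frequency
#'   (Hz) of the drive.
#' @param ripple_amp,ripple_freq amplitude (relative to the carrier) and
#'   frequency (Hz) of the fast ripple.
#' @param x0 initial states, named list with `slow` (scalar) and `fast`
#'   (length 2).
#' @return A problem object (class `mr_problem`): `$components` (specifications for
#'   [new_component()]), `$monolithic` (combined rhs + initial state for
#'   reference solves), `$observables` (name -> component/index map),
#'   `$closed_form` (exact `x`/`y` when `coupling_strength = 0`, else
#'   `NULL`) and `$t_end`.
#' @export
make_synthetic_problem <- function(stiffness_ratio = 1000,
                                   coupling_strength = 0.5,
                                   signal_speed = c("slow", "fast"),
                                   tau_slow = 1,
                                   tau_filt = 0.2,
                                   forcing_amplitude = 1,
                                   forcing_freq = 20,
                                   ripple_amp = 5e-4,
                                   ripple_freq = 300,
                                   x0 = list(slow = 1, fast = c(0, 0))) {
  signal_speed <- match.arg(signal_speed)
  stopifnot(stiffness_ratio >= 1, tau_slow > 0, tau_filt > 0, ripple_amp >= 0)
  tau_fast <- tau_slow / stiffness_ratio
  cc <- coupling_strength
  omega <- 2 * pi * forcing_freq
  omega_r <- 2 * pi * ripple_freq
  A <- forcing_amplitude
  ar <- ripple_amp
  drive <- if (ar == 0) function(t) sin(omega * t)
           else function(t) sin(omega * t) + ar * sin(omega_r * t)

  slow_rhs <- function(t, x, u) {
    uf <- if (is.null(u$fast)) 0 else u$fast[1L]
    (-(x - cc * uf)) / tau_slow
  }
  fast_rhs <- function(t, x, u) {
    us <- if (is.null(u$slow)) 0 else u$slow[1L]
    c((-(x[1L] - cc * us - A * drive(t))) / tau_fast,
      -(x[2L] - x[1L]) / tau_filt)
  }
  g_fast <- if (signal_speed == "fast") function(x) x[1L] else function(x) x[2L]

  mono_rhs <- function(t, x) {
    uf <- if (signal_speed == "fast") x[2L] else x[3L]
    c((-(x[1L] - cc * uf)) / tau_slow,
      (-(x[2L] - cc * x[1L] - A * drive(t))) / tau_fast,
      -(x[3L] - x[2L]) / tau_filt)
  }

  closed_form <- NULL
  if (cc == 0) {
    # decoupled: x and y are scalar linear ODEs with known solutions
    # (superposition of the particular responses to each sinusoid)
    closed_form <- function(t) {
      part <- function(s, a, w) a * (sin(w * s) - w * tau_fast * cos(w * s)) /
        (1 + (w * tau_fast)^2)
      yp <- function(s) A * (part(s, 1, omega) + part(s, ar, omega_r))
      list(slow = x0$slow * exp(-t / tau_slow),
           fast_y = (x0$fast[1L] - yp(0)) * exp(-t / tau_fast) + yp(t))
    }
  }

  structure(list(
    components = list(
      list(id = "slow", rhs = slow_rhs, g = function(x) x[1L],
           x0 = x0$slow, scale = 1),
      list(id = "fast", rhs = fast_rhs, g = g_fast,
           x0 = x0$fast, scale = 1)),
    monolithic = list(rhs = mono_rhs, x0 = c(x0$slow, x0$fast),
                      split = list(slow = 1L, fast = 2:3)),
    observables = list(x_slow = list(component = "slow", index = 1L),
                       y_fast = list(component = "fast", index = 1L),
                       z_filt = list(component = "fast", index = 2L)),
    closed_form = closed_form,
    signal_speed = signal_speed,
    t_end = 2),
    class = "mr_problem")
}

#' Build engine components from a problem specification
#'
#' @param problem an `mr_problem`.
#' @param reltol relative tolerance applied to every component.
#' @param abstol_factor absolute tolerance as a fraction of `reltol` times
#'   the component's typical scale.
#' @return List of [new_component()] environments.
#' @export
problem_components <- function(problem, reltol = 1e-6, abstol_factor = 1e-3) {
  lapply(problem$components, function(sp) {
    comp <- new_component(sp$id, sp$rhs, sp$x0, g = sp$g, reltol = reltol,
                          abstol = reltol * abstol_factor *
                            rep_len(if (is.null(sp$scale)) 1 else sp$scale,
                                    length(sp$x0)))
    if (!is.null(sp$h_max)) comp$h_max <- sp$h_max
    comp
  })
}
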