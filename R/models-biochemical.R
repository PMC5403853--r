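#' Default biochemical-model parameters
#'
#' Reduced calcium-activated MAPK cascade with positive feedback, and a
#' potassium-channel phosphorylation cycle downstream of active MAPK. The
#' network is a deliberately small bistable representation of the
#' signalling events triggered by spine calcium: sustained elevated calcium
#' switches phosphorylated MAPK (P-MAPK) from a low to a high fixed point
#' on a timescale of tens of seconds, which in turn phosphorylates (and so
#' inactivates) the spine potassium channels. All rate constants are this
#' package's own defaults and overridable.
#'
#' Units: concentrations uM, time s.
#'
#' @param ... named overrides.
#' @return Named list of parameters.
#' @export
biochemical_params <- function(...) {
  p <- list(
    mapk_tot = 0.5,  # total MAPK (uM), conserved
    k_tot = 0.2,     # total potassium channel (uM), conserved
    k_base = 8e-4,   # basal MAPK activation rate (uM/s)
    k_fb = 1e-2,     # positive-feedback activation Vmax (uM/s)
    kd_fb = 0.15,    # feedback half-activation (uM P-MAPK)
    k_cam = 1e-2,    # calcium-driven activation Vmax (uM/s)
    kd_ca = 0.3,     # calcium half-activation (uM), Hill coefficient 4
    km_act = 0.1,    # Michaelis constant of the activation step (uM)
    v_ph = 6e-3,     # phosphatase Vmax (uM/s)
    km_ph = 0.1,     # phosphatase Michaelis constant (uM)
    k_phos = 0.05,   # channel phosphorylation rate (1/(uM s))
    k_deph = 0.01,   # channel dephosphorylation rate (1/s)
    ca_rest = 0.05,  # resting calcium seen when no input supplied (uM)
    # TC-fast only: calcium pool solved on the biochemical side
    tau_ca = 0.05,   # calcium decay time (s)
    n_spine = 0.0166)# uM per molecule in the spine volume (flux conversion)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown))
    stop("biochemical_params: unknown parameter(s): ",
         paste(unknown, collapse = ", "))
  p[names(ov)] <- ov
  p
}

# state layout: M (inactive MAPK), P (P-MAPK), K_A (active channel),
# K_P (phosphorylated channel) [, Ca for TC-fast]
bioch_layout <- function(variant) {
  list(m = 1L, p = 2L, ka = 3L, kp = 4L,
       ca = if (variant == "TC-fast") 5L else NA_integer_,
       dim = 4L + (variant == "TC-fast"))
}

#' Biochemical (MAPK cascade) right-hand side
#'
#' Mass-action / Michaelis-Menten kinetics of the reduced network. The
#' calcium input activates MAPK through a steep (Hill 4) term; active
#' P-MAPK feeds back on its own activation (bistability) and drives the
#' channel phosphorylation cycle. Both conserved pairs (MAPK phosphoforms,
#' channel forms) have derivative sums of exactly zero by construction.
#'
#' In the `TC-slow` variant `u_elec` is the spine calcium concentration
#' (uM); in `TC-fast` it is the calcium flux (molecules/s), converted to a
#' concentration rate by the spine-volume factor, and calcium is a state of
#' this component.
#'
#' @param t time (s).
#' @param x state vector (`M`, `P`, `K_A`, `K_P`[, `Ca`]).
#' @param u_elec exchanged electrical input (scalar or NULL for basal).
#' @param p parameters from [biochemical_params()].
#' @param variant `"TC-slow"` or `"TC-fast"`.
#' @return State derivative vector.
#' @export
biochemical_rhs <- function(t, x, u_elec, p = biochemical_params(),
                            variant = c("TC-slow", "TC-fast")) {
  variant <- match.arg(variant)
  L <- bioch_layout(variant)
  # grossly negative concentrations are a caller error; tiny transient
  # undershoots during implicit iterations are tolerated
  if (any(x[c(L$m, L$p, L$ka, L$kp)] < -1e-3))
    stop("biochemical_rhs: negative concentration in input state")
  m <- x[L$m]; pp <- x[L$p]; ka <- x[L$ka]; kp <- x[L$kp]
  if (variant == "TC-slow") {
    ca <- if (is.null(u_elec) || !length(u_elec)) p$ca_rest else u_elec[1L]
  } else {
    ca <- x[L$ca]
  }
  ca <- max(ca, 0)
  hill <- ca^4 / (p$kd_ca^4 + ca^4)
  act <- (p$k_base + p$k_fb * pp^2 / (p$kd_fb^2 + pp^2) + p$k_cam * hill) *
    m / (p$km_act + m)
  deact <- p$v_ph * pp / (p$km_ph + pp)
  dp <- act - deact
  dkp <- p$k_phos * pp * ka - p$k_deph * kp
  out <- numeric(L$dim)
  out[L$m] <- -dp
  out[L$p] <- dp
  out[L$ka] <- -dkp
  out[L$kp] <- dkp
  if (variant == "TC-fast") {
    flux <- if (is.null(u_elec) || !length(u_elec)) 0 else max(u_elec[1L], 0)
    out[L$ca] <- p$n_spine * flux - (x[L$ca] - p$ca_rest) / p$tau_ca
  }
  out
}

#' Basal steady state of the biochemical model
#'
#' Low-P-MAPK fixed point at resting calcium, found by relaxing the system
#' from a low-activity initial guess.
#'
#' @inheritParams biochemical_rhs
#' @return State vector at the basal fixed point.
#' @export
biochemical_rest_state <- function(p = biochemical_params(),
                                   variant = c("TC-slow", "TC-fast")) {
  variant <- match.arg(variant)
  L <- bioch_layout(variant)
  x <- numeric(L$dim)
  x[L$m] <- p$mapk_tot
  x[L$p] <- 0
  x[L$ka] <- p$k_tot
  x[L$kp] <- 0
  if (variant == "TC-fast") x[L$ca] <- p$ca_rest
  out <- deSolve::lsoda(x, c(0, 2000),
                        function(t, y, parms)
                          list(biochemical_rhs(t, y, NULL, p, variant)),
                        rtol = 1e-10, atol = 1e-12)
  unname(out[nrow(out), -1L])
}
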