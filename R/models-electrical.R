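#' Default electrical-model parameters
#'
#' Parameters of the multi-compartment regular-spiking neuron: a soma with
#' minimal Hodgkin-Huxley spiking currents (fast Na, delayed-rectifier K,
#' slow non-inactivating M-type K for spike-frequency adaptation), a
#' passive 15-segment dendrite, and a spine head carrying a high-threshold
#' calcium conductance plus a potassium conductance whose availability is
#' set by the biochemical partner. The spiking-current kinetics and passive
#' constants follow the published minimal regular-spiking cortical
#' formulation (Traub-style rate functions with spike threshold parameter
#' `vt`); morphology lumping, the spine conductances and the
#' phenomenological calcium pool are this package's own defaults, and every
#' value can be overridden.
#'
#' Units: membrane potential mV, time s, specific conductances mS/cm^2,
#' capacitance uF/cm^2, currents uA/cm^2, calcium uM.
#'
#' @param ... named overrides of any default parameter.
#' @return Named list of parameters.
#' @export
electrical_params <- function(...) {
  p <- list(
    n_dend = 15L,       # dendrite segments between soma and spine
    cm = 1,             # membrane capacitance (uF/cm^2)
    g_na = 56,  e_na = 50,    # fast sodium
    g_kd = 6,   e_k = -90,    # delayed rectifier
    g_m = 0.075, tau_max = 0.608, # M-current (tau_max in s)
    g_leak = 0.0205, e_leak = -70.3,
    vt = -56.2,         # spike threshold shift (mV)
    g_axial = 1.5,      # inter-compartment coupling (mS, relative to soma area)
    area_soma = 1,      # relative compartment areas: axial currents are
    area_dend = 0.5,    # divided by the receiving compartment's area, so
    area_spine = 0.05,  # small compartments follow their neighbour tightly
    g_ca = 1, e_ca = 120,     # spine low-threshold calcium conductance
    ca_half = -45, ca_slope = 6, # activation midpoint/slope (mV)
    g_ks = 0.5,         # spine potassium conductance at full availability
    tau_ca = 0.2,       # calcium pool decay time (s)
    ca_rest = 0.05,     # resting spine calcium (uM)
    k_ca = 5e-3,        # calcium influx gain (uM per uA/cm^2 per ms)
    flux_scale = 300,   # calcium-current to molecule-flux gain (molecules/s per uA/cm^2)
    u_rest = 0.95)      # basal potassium-channel availability fraction
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown))
    stop("electrical_params: unknown parameter(s): ",
         paste(unknown, collapse = ", "))
  p[names(ov)] <- ov
  p
}

# Traub-style rate functions (1/ms in the published formulation; converted
# to 1/s). The V - vt shifts set the spike threshold.
hh_rates <- function(v, vt) {
  vm <- v - vt
  am <- 1e3 * (-0.32) * (vm - 13) / (expm1(-(vm - 13) / 4))
  bm <- 1e3 * 0.28 * (vm - 40) / (expm1((vm - 40) / 5))
  ah <- 1e3 * 0.128 * exp(-(vm - 17) / 18)
  bh <- 1e3 * 4 / (1 + exp(-(vm - 40) / 5))
  an <- 1e3 * (-0.032) * (vm - 15) / (expm1(-(vm - 15) / 5))
  bn <- 1e3 * 0.5 * exp(-(vm - 10) / 40)
  list(am = am, bm = bm, ah = ah, bh = bh, an = an, bn = bn)
}

# state-vector layout helper: V over compartments, soma gating, spine Ca
elec_layout <- function(p, variant) {
  nc <- p$n_dend + 2L # soma + dendrite + spine
  list(nc = nc, v = seq_len(nc), soma = 1L, spine = nc,
       m = nc + 1L, h = nc + 2L, n = nc + 3L, p = nc + 4L,
       ca = if (variant == "TC-slow") nc + 5L else NA_integer_,
       dim = nc + 4L + (variant == "TC-slow"))
}

#' Electrical (neuron) right-hand side
#'
#' Cable-coupled compartment chain soma - dendrite - spine. The soma
#' carries the spiking currents; the spine carries the calcium conductance
#' and the biochemically modulated potassium conductance. `u_bioch` is the
#' scaled active-potassium availability fraction communicated by the
#' biochemical component (falls back to the resting fraction when absent).
#' In the `TC-slow` variant spine calcium is a state of this component
#' (phenomenological single pool driven by the calcium current); in
#' `TC-fast` calcium lives on the biochemical side and this component only
#' exports the calcium flux.
#'
#' @param t time (s).
#' @param x state vector (see layout: compartment potentials, soma gating
#'   m/h/n/p, spine calcium for TC-slow).
#' @param u_bioch potassium availability fraction in `[0, 1]` (scalar or
#'   NULL).
#' @param p parameter list from [electrical_params()].
#' @param i_inj injected somatic current (uA/cm^2).
#' @param variant `"TC-slow"` or `"TC-fast"`.
#' @return State derivative vector.
#' @export
electrical_rhs <- function(t, x, u_bioch, p = electrical_params(),
                           i_inj = 0, variant = c("TC-slow", "TC-fast")) {
  variant <- match.arg(variant)
  L <- elec_layout(p, variant)
  v <- x[L$v]
  m <- x[L$m]; hh <- x[L$h]; nn <- x[L$n]; pp <- x[L$p]
  u <- if (is.null(u_bioch) || !length(u_bioch)) p$u_rest else u_bioch[1L]

  # membrane currents per compartment (uA/cm^2), leak everywhere
  i_mem <- p$g_leak * (v - p$e_leak)
  vs <- v[L$soma]
  i_mem[L$soma] <- i_mem[L$soma] +
    p$g_na * m^3 * hh * (vs - p$e_na) +
    p$g_kd * nn^4 * (vs - p$e_k) +
    p$g_m * pp * (vs - p$e_k) - i_inj
  vsp <- v[L$spine]
  mca <- 1 / (1 + exp(-(vsp - p$ca_half) / p$ca_slope))
  i_ca <- p$g_ca * mca^2 * (vsp - p$e_ca)
  i_mem[L$spine] <- i_mem[L$spine] + i_ca + p$g_ks * u * (vsp - p$e_k)

  # axial coupling along the chain; net inflow divided by compartment area
  ax <- p$g_axial * diff(v) # current proportional to neighbour difference
  i_ax <- numeric(L$nc)
  i_ax[-L$nc] <- ax
  i_ax[-1L] <- i_ax[-1L] - ax
  areas <- c(p$area_soma, rep(p$area_dend, p$n_dend), p$area_spine)

  dv <- 1e3 * (-i_mem + i_ax / areas) / p$cm # mV/s

  r <- hh_rates(vs, p$vt)
  dm <- r$am * (1 - m) - r$bm * m
  dh <- r$ah * (1 - hh) - r$bh * hh
  dn <- r$an * (1 - nn) - r$bn * nn
  p_inf <- 1 / (1 + exp(-(vs + 35) / 10))
  tau_p <- p$tau_max / (3.3 * exp((vs + 35) / 20) + exp(-(vs + 35) / 20))
  dp <- (p_inf - pp) / tau_p

  out <- numeric(L$dim)
  out[L$v] <- dv
  out[c(L$m, L$h, L$n, L$p)] <- c(dm, dh, dn, dp)
  if (variant == "TC-slow") {
    ca <- x[L$ca]
    # phenomenological single-pool calcium: influx from the (inward)
    # calcium current, first-order return to rest
    out[L$ca] <- -(ca - p$ca_rest) / p$tau_ca + 1e3 * p$k_ca * pmax(-i_ca, 0)
  }
  out
}

#' Resting state of the electrical model
#'
#' All compartments at the leak reversal adjusted for the spine
#' conductances, gating variables at their steady state, calcium at rest.
#' Accurate enough to start an adaptive solve; the integrator relaxes the
#' remaining imbalance in the first few milliseconds.
#'
#' @inheritParams electrical_rhs
#' @return State vector at approximate rest.
#' @export
electrical_rest_state <- function(p = electrical_params(),
                                  variant = c("TC-slow", "TC-fast")) {
  variant <- match.arg(variant)
  L <- elec_layout(p, variant)
  v0 <- p$e_leak
  r <- hh_rates(v0, p$vt)
  x <- numeric(L$dim)
  x[L$v] <- v0
  x[L$m] <- r$am / (r$am + r$bm)
  x[L$h] <- r$ah / (r$ah + r$bh)
  x[L$n] <- r$an / (r$an + r$bn)
  x[L$p] <- 1 / (1 + exp(-(v0 + 35) / 10))
  if (variant == "TC-slow") x[L$ca] <- p$ca_rest
  x
}

#' Pulse current protocol
#'
#' Deterministic piecewise-constant injected current driving the two firing
#' regimes of the test case over 5 s: a regular-spiking phase in which
#' brief suprathreshold pulses elicit single spikes at the pulse rate, and
#' a burst phase with a sustained strong current driving fast tonic firing.
#'
#' @param t time (s), vectorized.
#' @param regular_until end of the regular-spiking phase (s).
#' @param pulse_rate pulse repetition rate in the regular phase (Hz).
#' @param pulse_width pulse duration (s).
#' @param pulse_amp pulse amplitude (uA/cm^2).
#' @param burst_amp sustained current in the burst phase (uA/cm^2).
#' @param t_end end of the protocol (s); zero current afterwards.
#' @return Injected current (uA/cm^2).
#' @export
pulse_current_protocol <- function(t, regular_until = 2.5, pulse_rate = 2,
                                   pulse_width = 0.003, pulse_amp = 25,
                                   burst_amp = 4, t_end = 5) {
  amp <- numeric(length(t))
  # pulses at 0.05, 0.05 + 1/rate, ... within the regular phase
  reg <- t >= 0.05 & t < regular_until
  amp[reg] <- ifelse(((t[reg] - 0.05) %% (1 / pulse_rate)) < pulse_width,
                     pulse_amp, 0)
  amp[t >= regular_until & t <= t_end] <- burst_amp
  amp
}

#' Detect spikes and firing rates in a voltage trace
#'
#' A spike is an upward crossing of 0 mV. Firing rate of a phase is the
#' spike count divided by the phase duration.
#'
#' @param times trace times (s).
#' @param v membrane potential (mV).
#' @param phases named list of `c(start, end)` windows (s).
#' @return List with `spike_times` and `rates` (Hz, one per phase).
#' @export
spike_stats <- function(times, v, phases = list(regular = c(0, 2.5),
                                                burst = c(2.5, 5))) {
  up <- which(v[-1L] >= 0 & v[-length(v)] < 0)
  # linear interpolation of the crossing time
  st <- times[up] + (0 - v[up]) / (v[up + 1L] - v[up]) *
    (times[up + 1L] - times[up])
  rates <- vapply(phases, function(w)
    sum(st >= w[1L] & st < w[2L]) / (w[2L] - w[1L]), numeric(1))
  list(spike_times = st, rates = rates)
}
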