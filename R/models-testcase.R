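#' Electrical-chemical multiscale test case
#'
#' Builds the coupled two-component problem: the multi-compartment
#' regular-spiking neuron (electrical component, sub-millisecond dynamics)
#' mutually coupled to the reduced bistable MAPK cascade (biochemical
#' component, tens-of-seconds dynamics) in the spine. Two coupling variants
#' differ in the electrical-to-biochemical exchanged signal:
#'
#' * `TC-fast`: the calcium **flux** (molecules/s, following the
#'   sub-millisecond spike dynamics) is communicated; the calcium pool is a
#'   state of the biochemical component.
#' * `TC-slow`: the calcium **concentration** (uM, smoothed by the pool
#'   time constant) is solved on the electrical side and communicated.
#'
#' The biochemical-to-electrical signal is in both variants the active
#' (non-phosphorylated) potassium-channel concentration scaled to an
#' availability fraction, `g(x) = C1 * K_A` with `C1 = 1/k_tot`.
#'
#' @param variant `"TC-slow"` or `"TC-fast"`.
#' @param elec parameters from [electrical_params()].
#' @param bioch parameters from [biochemical_params()].
#' @param protocol named list of [pulse_current_protocol()] arguments
#'   overriding its defaults (empty list for the default 2 Hz / burst
#'   protocol).
#' @param t_end problem end time (s).
#' @return An `mr_problem` (see [make_synthetic_problem()] for the shape)
#'   with observables `V` (spine potential), `Ca`, `K_A` and `P_MAPK`.
#' @export
make_testcase <- function(variant = c("TC-slow", "TC-fast"),
                          elec = electrical_params(),
                          bioch = biochemical_params(),
                          protocol = list(),
                          t_end = 5) {
  variant <- match.arg(variant)
  Le <- elec_layout(elec, variant)
  Lb <- bioch_layout(variant)
  inj <- function(t) do.call(pulse_current_protocol, c(list(t), protocol))
  c1 <- 1 / bioch$k_tot

  e_rhs <- function(t, x, u)
    electrical_rhs(t, x, u$biochemical, elec, i_inj = inj(t), variant = variant)
  e_g <- if (variant == "TC-slow") {
    function(x) x[Le$ca]
  } else {
    function(x) {
      vsp <- x[Le$spine]
      mca <- 1 / (1 + exp(-(vsp - elec$ca_half) / elec$ca_slope))
      elec$flux_scale * max(-(elec$g_ca * mca^2 * (vsp - elec$e_ca)), 0)
    }
  }
  b_rhs <- function(t, x, u)
    biochemical_rhs(t, x, u$electrical, bioch, variant = variant)
  b_g <- function(x) c1 * x[Lb$ka]

  e0 <- electrical_rest_state(elec, variant)
  b0 <- biochemical_rest_state(bioch, variant)

  # per-variable absolute-tolerance scales (mV for potentials, 1 for
  # gating, uM for concentrations)
  e_scale <- numeric(Le$dim)
  e_scale[Le$v] <- 100
  e_scale[c(Le$m, Le$h, Le$n, Le$p)] <- 1
  if (variant == "TC-slow") e_scale[Le$ca] <- 1
  b_scale <- rep(bioch$mapk_tot, Lb$dim)
  if (variant == "TC-fast") b_scale[Lb$ca] <- 1

  ne <- Le$dim
  mono_rhs <- function(t, x) {
    xe <- x[seq_len(ne)]
    xb <- x[-seq_len(ne)]
    c(electrical_rhs(t, xe, c1 * xb[Lb$ka], elec, i_inj = inj(t),
                     variant = variant),
      biochemical_rhs(t, xb, e_g(xe), bioch, variant = variant))
  }

  structure(list(
    components = list(
      list(id = "biochemical", rhs = b_rhs, g = b_g, x0 = b0,
           scale = b_scale),
      list(id = "electrical", rhs = e_rhs, g = e_g, x0 = e0,
           scale = e_scale,
           # cap below the pulse width so the protocol's current steps
           # cannot fall between two accepted time points
           h_max = 1.5e-3)),
    monolithic = list(rhs = mono_rhs, x0 = c(e0, b0),
                      split = list(electrical = seq_len(ne),
                                   biochemical = ne + seq_len(Lb$dim))),
    observables = list(
      V = list(component = "electrical", index = Le$spine),
      Ca = if (variant == "TC-slow")
        list(component = "electrical", index = Le$ca)
      else list(component = "biochemical", index = Lb$ca),
      K_A = list(component = "biochemical", index = Lb$ka),
      P_MAPK = list(component = "biochemical", index = Lb$p)),
    variant = variant,
    elec = elec, bioch = bioch,
    layout = list(electrical = Le, biochemical = Lb),
    t_end = t_end),
    class = "mr_problem")
}

#' Adaptive BDF2 simulation of the standalone electrical component
#'
#' Runs the neuron alone for the full pulse protocol with the potassium
#' availability frozen at its basal fraction, using the package's adaptive
#' BDF2 stack, and reports the firing statistics of the two protocol
#' phases.
#'
#' @param t_end simulated time (s).
#' @param reltol,abstol_factor solver tolerances (see
#'   [problem_components()]).
#' @param elec electrical parameters.
#' @param protocol protocol overrides as in [make_testcase()].
#' @return List with `solution` (times/states), `stats` (from
#'   [spike_stats()]) and the solver counters.
#' @export
simulate_electrical <- function(t_end = 5, reltol = 1e-4,
                                abstol_factor = 0.1,
                                elec = electrical_params(),
                                protocol = list()) {
  Le <- elec_layout(elec, "TC-slow")
  inj <- function(t) do.call(pulse_current_protocol, c(list(t), protocol))
  rhs <- function(t, x, u)
    electrical_rhs(t, x, NULL, elec, i_inj = inj(t), variant = "TC-slow")
  scale <- numeric(Le$dim)
  scale[Le$v] <- 100
  scale[c(Le$m, Le$h, Le$n, Le$p)] <- 1
  scale[Le$ca] <- 1
  sol <- bdf2_solve(rhs, electrical_rest_state(elec, "TC-slow"),
                    t0 = 0, t_end = t_end, reltol = reltol,
                    abstol = reltol * abstol_factor * scale,
                    h_max = 1.5e-3)
  reg_until <- if (!is.null(protocol$regular_until)) protocol$regular_until
               else 2.5
  phases <- list()
  if (reg_until > 0) phases$regular <- c(0, min(reg_until, t_end))
  if (t_end > reg_until) phases$burst <- c(reg_until, t_end)
  stats <- spike_stats(sol$times, sol$states[, Le$soma], phases)
  list(solution = sol, stats = stats,
       counters = sol[c("nrhs", "njac", "accepted", "rejected")])
}
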