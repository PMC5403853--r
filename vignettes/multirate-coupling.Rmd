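---
title: "Multirate co-simulation with decoupled BDF2: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multirate co-simulation with decoupled BDF2: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multirate)
```

## The problem

Multiscale models in neuroscience couple subsystems whose intrinsic
timescales differ by orders of magnitude: the membrane potential of a
spiking neuron evolves on sub-millisecond scales, while the biochemical
cascades it drives respond over seconds to minutes. Written as ordinary
differential equations, the coupled pair has the form

$$
\dot x_1 = f_1(t, x_1, g_2(x_2)), \qquad
\dot x_2 = f_2(t, g_1(x_1), x_2),
$$

where each component sees the other only through a transformation
(output) function $g$ of its state — the *exchanged variable*. In a
co-simulation setting the two components may live in different solvers or
processes, so data exchange must be restricted to discrete communication
points; no intermediate queries are possible. `multirate` implements an
integration engine for this setting: every component advances with its own
adaptive step size between communication points, exchanged variables are
approximated by low-order polynomials, and a coupled error rule keeps the
overall accuracy under control.

## Decoupled BDF2 on non-uniform grids

Each component is advanced by the second-order backward differentiation
formula. Because adaptive stepping makes the grid non-uniform, the
coefficients depend on the step ratio
$\gamma_{n+1} = h_{n+1}/h_n$:

$$
x_{n+1} = \alpha_1 x_n + \alpha_2 x_{n-1} + \beta\, h_{n+1}
  f(t_{n+1}, x_{n+1}), \quad
\alpha_2 = \frac{-\gamma_{n+1}^2}{2\gamma_{n+1}+1},\;
\alpha_1 = 1-\alpha_2,\;
\beta = \frac{\gamma_{n+1}+1}{2\gamma_{n+1}+1}.
$$

At $\gamma = 1$ these reduce to the classic equidistant BDF2
($4/3, -1/3, 2/3$), and the formula is exact for solutions that are
polynomials of degree $\le 2$ on any grid — both facts are pinned by unit
tests. The formula is *decoupled*: the partner's exchanged variables are
frozen at their approximated value at $t_{n+1}$ for the whole implicit
solve, so each component solves only its own implicit system.

Startup uses one backward-Euler step (BDF2 needs two history points; the
initial step is deliberately tiny, so its first-order error is
immaterial). The implicit relation is solved by a damped Newton iteration
with a forward-difference Jacobian (perturbation $\sqrt{\varepsilon}$
scaled per component). The Jacobian is reused across iterations *and*
across steps in the usual modified-Newton fashion; only the iteration
matrix $I - \beta h J$ is refactored each step, and a failed iteration
rebuilds the Jacobian at the current point and retries once before the
step is declared failed (the caller then halves the step). The iteration
stops when the tolerance-scaled update norm falls below $0.1$, keeping the
nonlinear-solve error an order below the discretization tolerance. Every
right-hand-side evaluation is counted, with Jacobian columns tallied
separately, so the "number of ODE calls" cost metric can be reported
inclusive or exclusive of differencing.

## Error control

The local error of each accepted candidate step is estimated by a
predictor–corrector difference: the predictor is the quadratic through the
newest three history points extrapolated to $t_{n+1}$ (it doubles as the
Newton starting guess), and the estimate is normalized per variable,

$$
\epsilon = \max_i
\frac{|x_i - \hat x_i|}{\mathrm{relTOL}\,|x_i| + \mathrm{absTOL}_i},
$$

with acceptance iff $\epsilon \le 1$. For a slower component the *combined*
error additionally takes the maximum over the accepted micro-step errors of
its faster neighbour on the overlapping time interval — in asynchronous
mode a micro step straddling the interval boundary is attributed to both
intervals. This combined value gates acceptance and is what a rejection
recomputes the retry step from (additionally capped at the rejected step).

**Controller wiring.** The next step after an *accepted* step is predicted
from the component's *own* local error with the elementary controller
$h_{\text{next}} = h \cdot \mathrm{clamp}(0.9\,\epsilon^{-1/3},\,0.2,\,2)$.
Routing the combined error into the prediction instead is a tempting
reading of the coupled rule, but it is structurally inert: for any
controller of the form $h' = h\,C(\epsilon)$, the faster component's
equilibrium accepted error is exactly the point where $C = 1$, so the
slower component's step would be marginally stationary forever — the
macro/micro step separation that motivates multirate integration could
never develop (we verified this numerically; the slow component froze at a
~2× ratio). With local-error prediction and combined-error gating, the
slow component's step grows until its own error budget binds, while the
faster component's errors still veto any slow step whose interval they
contaminated — the gating inequality is asserted on full run traces in the
test suite.

Further controller details: a zero error takes the maximum growth factor;
the initial step is $\min(10^{-4} T, h_{\text{curv}})$ with a curvature
heuristic scaled by the tolerances; at most 20 consecutive rejections per
step before the run aborts with a diagnostic; an optional per-component
step cap `h_max` exists for discontinuous forcing (the pulse protocol),
because a purely error-driven controller can otherwise grow its step over
a pulse that is narrower than the step and never see it.

## Gauss-Seidel strategies and communication modes

Components are ordered slowest to fastest by predicted step before each
outermost interval (a stable sort; the ordering switch count is reported).
The interval solver is recursive: the current component takes adaptive
micro steps across its interval; each accepted micro step becomes the
interval for the remaining faster subset.

* **slow-first**: the current component steps first, extrapolating its
  faster partners' exchanged variables from their newest three samples,
  then the faster subset is solved across the accepted candidate interval,
  interpolating the already-computed slow values.
* **fast-first**: the faster subset is solved across the candidate
  interval first (extrapolating the slow values), then the current
  component steps using the faster partners' values at its endpoint.

A rejection rolls the current component *and* every faster component back
to their pre-step snapshots (bitwise, asserted in tests); in fast-first
mode this discards completed fast micro work, which is the known cost of
that strategy.

With **synchronous** communication the last micro step of each faster
component is shrunk to land exactly on the enclosing interval endpoint, so
slower grids are subsets of faster grids. With **asynchronous**
communication (the default) the last micro step may overshoot the endpoint
by at most one predicted step; endpoint values are obtained by quadratic
interpolation on the bracketing micro samples, and the overshot history is
kept — nothing is recomputed when the next interval begins. Interpolation
of a partner's exchanged signal happens only at the consuming component's
own step endpoints, which coincide with the macro endpoints of the
recursive subset; this matches the macro-endpoint-only communication
discipline of co-simulation.

All approximation of exchanged variables uses the unique polynomial
through at most three samples, evaluated in Newton divided-difference form
for stability on strongly non-uniform spacings. A query exactly at a
sample endpoint counts as interpolation. The retained history window is 8
entries — three are needed for the BDF stencil and predictor, the rest
support interpolation across macro boundaries in asynchronous mode.

In **singlerate** mode all components share one adaptive step per macro
interval (the reference coupling method): components step in Gauss-Seidel
order, the shared error is the maximum of the per-component locals, and
acceptance is joint. A single-component run degenerates, bitwise, to the
standalone adaptive BDF2 solver `bdf2_solve()` — this equivalence is a
test.

## The synthetic two-timescale benchmark

`make_synthetic_problem()` is a first-class fixture generator: a linear
slow relaxation (time constant $\tau_{slow} = 1$ s) mutually coupled to a
stiff fast component ($\tau_{fast} = \tau_{slow}/1000$) driven by a unit
20 Hz carrier plus a $5\times10^{-4}$ relative ripple at 300 Hz. The fast
component carries a low-pass filtered copy ($\tau_{filt} = 0.2$ s) of its
stiff state, and its output exposes either the raw state
(`signal_speed = "fast"`, a flux-like exchanged signal with
high-frequency content) or the filtered one (`"slow"`, a
concentration-like smooth signal). Coupling strength defaults to $0.5$;
at $0$ the problem decouples and closed-form solutions are available,
which anchors the reference-solution tests. These defaults were chosen to
give a genuinely two-rate problem (measured macro/micro step ratios around
20) with the fast/slow exchanged-signal contrast of the electrical–
chemical test case, and are fixed.

What the generator does *not* emulate: nonlinear kinetics, state-dependent
stiffness, and whatever controller-specific interactions produced the
first-order error-versus-cost decline reported for fast-first coupling
with a fast exchanged signal in earlier studies of this method. On this
linear benchmark the implemented engine delivers clean second-order
declines in *both* configurations (slopes near 2 for slow-first/slow and
near 2.8 for fast-first/fast, the latter at visibly higher cost per
accuracy). A Gauss-Seidel coupling whose exchanged variables are
approximated by quadratics is second-order consistent on smooth problems,
so we regard the order *reduction* as an implementation-specific
phenomenon that printed information does not suffice to reproduce; the
efficiency penalty of consuming a fast signal, by contrast, reproduces
clearly (the slow component's controller is dragged to small steps). The
corresponding acceptance expectation is left unmet rather than engineered.

Evaluation methodology: accuracy is the percent relative error at
$T = 2$ s against a monolithic reference (both components as one system,
`deSolve::lsoda` at tolerance $10^{-12}$); cost is the number of
right-hand-side evaluations; order is the least-squares slope of
log-error versus log-cost over relTOL $\in \{10^{-4},\dots,10^{-7}\}$.
Sweeps are deterministic end to end — a repeated sweep is `identical()`.

## The electrical–chemical test case

The electrical component is a multi-compartment regular-spiking neuron:
a soma carrying minimal Hodgkin–Huxley spiking currents (fast Na,
delayed-rectifier K, and a slow M-type K current for spike-frequency
adaptation, Traub-style kinetics with threshold parameter
$V_T = -56.2$ mV), a passive 15-segment dendrite, and a spine head with a
low-voltage-activated calcium conductance and a potassium conductance
whose availability is set by the biochemical partner. Compartments are
coupled by lumped axial conductances with relative areas (soma 1, dendrite
segments 0.5, spine 0.05), so the spine follows its dendrite tightly while
the soma is only moderately loaded — this keeps the model electrically
compact enough for spikes to reach the spine while preserving a graded
frequency–current curve. Spine calcium is a phenomenological single pool,
$\dot{[\mathrm{Ca}]} = -([\mathrm{Ca}]-[\mathrm{Ca}]_{rest})/\tau_{Ca} +
k_{Ca}\,|I_{Ca}|$ with $\tau_{Ca} = 0.2$ s.

The biochemical component is a reduced bistable MAPK cascade in the spine:
calcium activates MAPK phosphorylation through a steep (Hill 4) term,
phosphorylated MAPK (P-MAPK) feeds back positively on its own activation,
and a phosphatase opposes it; P-MAPK drives a phosphorylation cycle that
inactivates the spine potassium channels. Both conserved pairs (MAPK
phosphoforms; channel forms) have exactly zero net derivative by
construction. At resting calcium the cascade sits at a low P-MAPK fixed
point; sustained calcium above ~0.5 uM switches it to a high fixed point
over tens to hundreds of seconds, and the high state persists after
calcium returns to rest (bistable memory) — all asserted in tests.

Two coupling variants differ in the electrical-to-biochemical signal:
`TC-fast` communicates the calcium **flux** (molecules/s, spike-locked),
with the calcium pool solved on the biochemical side; `TC-slow`
communicates the calcium **concentration** solved on the electrical side.
The reverse signal is in both cases the active-channel availability
fraction $C_1 K_A$ with $C_1 = 1/K_{tot}$. The flux-to-concentration
conversion uses a spine-volume factor (0.0166 uM per molecule) chosen so
both variants share identical calcium dynamics.

**Parameter provenance.** The spiking-current kinetics and passive
constants are the published minimal regular-spiking values; everything
else — morphology lumping, spine conductances, the calcium pool, all MAPK
rate constants, and the stimulation protocol — are this package's own
documented defaults, chosen once to satisfy the stated behavioral
conditions and overridable through `electrical_params()`,
`biochemical_params()` and the YAML configuration. The pulse protocol
(3 ms pulses of 25 uA/cm^2 at 2 Hz for 2.5 s, then a sustained
4 uA/cm^2 for 2.5 s) was calibrated so the neuron fires single spikes at
2 Hz in the regular phase and tonically at ~100 Hz in the burst phase;
spikes are detected as upward 0 mV crossings of the soma potential and
rates are spike counts over phase durations.

A known representational limit: with a single-pool concentration fed by
the spike-locked current, the concentration's peak rate of change is
proportional to the flux peak, so the flux-versus-concentration smoothness
contrast is bounded by the spike upstroke time — about an order of
magnitude here, rather than the hundredfold contrast a microsecond-scale
channel-flux model would give. The engine-facing distinction (smooth
versus fast exchanged signal) is preserved.

## Problem sizes used in the checks

The test suite and the acceptance script run: the standalone electrical
component for the full 5 s protocol at relTOL $10^{-4}$ (~$10^5$ accepted
steps); synthetic-problem sweeps over relTOL $10^{-4}..10^{-7}$ at
$T = 2$ s; the multirate-versus-singlerate cost comparison at relTOL
$10^{-5}$; and biochemical clamp solves of 600 s. These sizes were chosen
so every statement the package makes about itself is recomputed from
scratch in minutes on one core.

## Known limitations

* One Gauss-Seidel pass per macro step; no waveform-relaxation iteration.
* All-to-all coupling is assumed; no sparse-coupling optimization.
* Fixed integration order (BDF2 with backward-Euler startup); no order
  control.
* No event detection: discontinuous forcing is handled by the `h_max` cap.
* Reaction–diffusion (spatial) chemistry is out of scope; calcium is a
  point pool.
* The first-order accuracy loss reported for fast-first coupling with a
  fast exchanged signal is not reproduced (see above); the package's
  engine is second-order in both strategy/signal pairings on the linear
  benchmark.
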