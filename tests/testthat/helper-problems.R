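# Shared fixtures: tiny deterministic problems built in code.

# scalar exponential decay, exact solution x0 * exp(-lambda t)
decay_rhs <- function(lambda = 1) function(t, x, u) -lambda * x

# stiff linear scalar with smooth forcing; exact solution available
forced_stiff <- function(lambda = 50) {
  list(
    rhs = function(t, x, u) -lambda * x + sin(t),
    exact = function(t, x0 = 1) {
      part <- function(s) (lambda * sin(s) - cos(s)) / (lambda^2 + 1)
      (x0 - part(0)) * exp(-lambda * t) + part(t)
    })
}

# fixed-step BDF2 integration of a scalar problem (startup from the exact
# solution) - used as an independent driver for order measurements
bdf2_fixed_steps <- function(rhs, exact, h, t_end) {
  hist <- mr_history(1L)
  hist <- append_state(hist, 0, exact(0))
  hist <- append_state(hist, h, exact(h))
  t <- h
  while (t < t_end - 1e-12) {
    st <- bdf2_step(hist, h, rhs, rtol = 1e-12, atol = 1e-14)
    hist <- append_state(hist, st$t, st$x)
    t <- st$t
  }
  list(t = t, x = hist$states[length(hist$times), ])
}

# default synthetic problems as used across engine/evaluation tests
synth_slow <- function(...) make_synthetic_problem(signal_speed = "slow", ...)
synth_fast <- function(...) make_synthetic_problem(signal_speed = "fast", ...)
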