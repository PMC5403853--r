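test_that("the accuracy metric is the reference-normalized percent error", {
  expect_equal(relative_error(2.0, 1.9), 5.0)
  expect_equal(relative_error(3.7, 3.7), 0)
  expect_equal(relative_error(1e-6, 1.1e-6), 10.0, tolerance = 1e-9)
  # deliberately asymmetric: only the reference sets the scale
  expect_false(isTRUE(all.equal(relative_error(1, 2), relative_error(2, 1))))
  expect_error(relative_error(0, 1), "zero reference")
})

test_that("reference solutions agree with closed forms and are
           self-consistent across tolerances", {
  prob <- make_synthetic_problem(coupling_strength = 0)
  grid <- seq(0, 1, by = 0.25)
  ref <- compute_reference(prob, grid, tol = 1e-12)
  expect_equal(ref$at(0), prob$monolithic$x0) # exact at the initial time
  for (t in c(0.5, 1))
    expect_lt(abs(ref$at(t)[1] - prob$closed_form(t)$slow) /
                abs(prob$closed_form(t)$slow), 1e-9)
  ref10 <- compute_reference(prob, grid, tol = 1e-10)
  expect_lt(max(abs(ref$states - ref10$states)) /
              max(abs(ref$states)), 1e-8)
})

test_that("convergence order recovers exact log-linear declines", {
  expect_equal(convergence_order(c(1e-2, 1e-4, 1e-6), c(1e2, 1e3, 1e4)), 2,
               tolerance = 1e-10)
  expect_equal(convergence_order(c(1e-2, 1e-3, 1e-4), c(1e2, 1e3, 1e4)), 1,
               tolerance = 1e-10)
  expect_error(convergence_order(1e-2, 1e2), "matched")
  expect_error(convergence_order(c(1e-2, 1e-3), c(10, 10)), "degenerate")
  expect_error(convergence_order(c(0, 1e-3), c(1, 10)), "positive")
})

test_that("tolerance sweeps are deterministic and report monotone errors
           and the documented counters", {
  prob <- synth_slow()
  cfg <- mr_config("slow-first", "asynchronous", "multirate",
                   t_end = 0.5, keep_trace = FALSE)
  ref <- compute_reference(prob, c(0, 0.25, 0.5))
  tab1 <- run_sweep(prob, c(1e-4, 1e-6), cfg, t_eval = 0.5, reference = ref)
  tab2 <- run_sweep(prob, c(1e-4, 1e-6), cfg, t_eval = 0.5, reference = ref)
  expect_identical(tab1, tab2) # no hidden randomness anywhere in the stack
  expect_true(all(tab1$status == "ok"))
  expect_lt(tab1$err_x_slow[2], tab1$err_x_slow[1]) # tighter tol, less error
  expect_true(all(tab1$macros < tab1$micros))
  expect_true(all(tab1$rhs_calls >= tab1$rhs_calls_no_jac))
})
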