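test_that("components are ordered slowest to fastest with stable ties", {
  mk <- function(id, h) {
    c <- new_component(id, function(t, x, u) 0, 0)
    c$h <- h
    c
  }
  comps <- list(mk("B", 1e-4), mk("A", 1e-1), mk("C", 1e-4))
  ord <- order_components(comps)
  expect_equal(vapply(ord, function(c) c$id, ""), c("A", "B", "C"))
  # equal steps preserve the original order
  comps <- list(mk("x", 1), mk("y", 1), mk("z", 1))
  expect_equal(vapply(order_components(comps), function(c) c$id, ""),
               c("x", "y", "z"))
})

test_that("a single-component engine run is bitwise identical to the
           standalone adaptive solver", {
  rhs <- function(t, x, u) c(-x[1] + 0.3 * sin(t), -5 * x[2])
  sol <- bdf2_solve(rhs, c(1, 1), 0, 1.5, reltol = 1e-6, abstol = 1e-9)
  comp <- new_component("only", rhs, c(1, 1), reltol = 1e-6, abstol = 1e-9)
  res <- mr_run(list(comp), mr_config(t_end = 1.5))
  expect_identical(res$trajectories$only$times, sol$times)
  expect_identical(res$trajectories$only$states, sol$states)
  expect_identical(res$counters$rhs_evals + res$counters$jac_evals,
                   sol$nrhs + sol$njac)
})

test_that("a decoupled pair reproduces each component's standalone solve", {
  prob <- make_synthetic_problem(coupling_strength = 0, signal_speed = "fast")
  comps <- problem_components(prob, reltol = 1e-5)
  res <- mr_run(comps, mr_config("slow-first", "asynchronous", "multirate",
                                 t_end = 0.5))
  expect_equal(res$status, "ok")
  for (sp in prob$components) {
    sol <- bdf2_solve(sp$rhs, sp$x0, 0, 0.5, reltol = 1e-5,
                      abstol = 1e-5 * 1e-3)
    tr <- res$trajectories[[sp$id]]
    # the engine only clips the outermost component to t_end; an inner
    # component overshoots it asynchronously, so compare the bitwise-equal
    # prefix before the standalone solver's clipped final step
    n <- length(sol$times) - 1L
    expect_identical(tr$times[seq_len(n)], sol$times[seq_len(n)])
    expect_identical(tr$states[seq_len(n), ], sol$states[seq_len(n), ])
  }
})

test_that("identical components in singlerate mode share one step sequence", {
  mk <- function(id) new_component(id, function(t, x, u) -x + sin(t), 1,
                                   reltol = 1e-5, abstol = 1e-8)
  res <- mr_run(list(mk("a"), mk("b")),
                mr_config("slow-first", "asynchronous", "singlerate",
                          t_end = 1))
  expect_equal(res$status, "ok")
  expect_identical(res$trajectories$a$times, res$trajectories$b$times)
  expect_identical(res$trajectories$a$states, res$trajectories$b$states)
})

test_that("a rejected slow step rolls every component back to its pre-step
           state", {
  mk_pair <- function() list(
    new_component("slow", function(t, x, u) -x, 1,
                  reltol = 1e-8, abstol = 1e-10),
    new_component("fast", function(t, x, u) -40 * x + 2, 0.5,
                  reltol = 1e-6, abstol = 1e-9))
  # reference: initialized but never stepped
  ref <- mk_pair()
  invisible(mr_run(ref, mr_config("fast-first", "asynchronous", "multirate",
                                  t_end = 0)))
  # forced rejection: huge initial slow step, zero rejection budget, so the
  # run aborts right after the first rejection (and its rollback)
  comps <- mk_pair()
  res <- mr_run(comps, mr_config("fast-first", "asynchronous", "multirate",
                                 t_end = 1, max_rejections = 0L),
                h0 = c(slow = 0.9, fast = 1e-4))
  expect_equal(res$status, "aborted")
  expect_gt(sum(res$counters$rejected), 0)
  for (i in 1:2) {
    expect_identical(comps[[i]]$t, ref[[i]]$t)
    expect_identical(comps[[i]]$x, ref[[i]]$x)
    expect_identical(comps[[i]]$hist$times, ref[[i]]$hist$times)
    expect_identical(comps[[i]]$hist$states, ref[[i]]$hist$states)
    expect_identical(comps[[i]]$xs_times, ref[[i]]$xs_times)
    expect_identical(comps[[i]]$xs_vals, ref[[i]]$xs_vals)
  }
})

test_that("zero-length integration returns the initial state with no steps", {
  comp <- new_component("a", function(t, x, u) -x, 2)
  res <- mr_run(list(comp), mr_config(t_end = 0))
  expect_equal(res$trajectories$a$times, 0)
  expect_equal(res$trajectories$a$states[1, ], 2)
  expect_equal(res$macros, 0L)
  expect_equal(sum(res$counters$accepted), 0L)
})

test_that("exchanged variables are approximated by the quadratic through the
           source's samples", {
  src <- new_component("src", function(t, x, u) 0, 0, g = identity)
  for (t in c(0, 0.5, 1)) multirate:::exchange_append(src, t, t^2)
  # extrapolation of a quadratic signal is exact
  ex <- exchange_at(src, 1.7, "not-yet-solved")
  expect_equal(ex$value, 1.7^2, tolerance = 1e-12)
  expect_equal(ex$kind, "extrapolation")
  # query at a stored sample returns the stored value
  ex <- exchange_at(src, 0.5, "already-solved")
  expect_equal(ex$value, 0.25)
  expect_equal(ex$kind, "interpolation")
  expect_error(exchange_at(new_component("e", function(t, x, u) 0, 0), 1),
               "no samples")
})

test_that("macro-endpoint alignment interpolates asynchronous overshoot and
           reads synchronous samples exactly", {
  src <- new_component("f", function(t, x, u) 0, 0, g = identity)
  src$t <- 1.05
  for (t in c(0.6, 0.8, 1.05)) multirate:::exchange_append(src, t, t) # u(t) = t
  expect_equal(align_macro_end(src, 1.0, "asynchronous"), 1.0,
               tolerance = 1e-12)
  expect_error(align_macro_end(src, 1.2, "asynchronous"), "not reached")
  src2 <- new_component("g", function(t, x, u) 0, 0, g = identity)
  src2$t <- 1.0
  for (t in c(0.4, 0.8, 1.0)) multirate:::exchange_append(src2, t, 3 * t)
  expect_equal(align_macro_end(src2, 1.0, "synchronous"), 3.0)
})

test_that("every macro step contains at least one fast micro step", {
  prob <- synth_slow()
  comps <- problem_components(prob, reltol = 1e-4)
  res <- mr_run(comps, mr_config("slow-first", "asynchronous", "multirate",
                                 t_end = 0.5))
  expect_equal(res$status, "ok")
  fast_micros <- res$counters$accepted[res$counters$component == "fast"]
  expect_lte(res$macros, fast_micros)
})

test_that("accepted combined errors respect the coupled gating rule on a
           run trace", {
  for (strategy in c("slow-first", "fast-first")) {
    prob <- synth_slow()
    comps <- problem_components(prob, reltol = 1e-4)
    # pin the initial steps so the slow/fast roles match the labels for
    # the whole run (the gating rule is about the engine's ordering)
    res <- mr_run(comps, mr_config(strategy, "asynchronous", "multirate",
                                   t_end = 0.4),
                  h0 = c(slow = 1e-3, fast = 1e-5))
    expect_equal(res$status, "ok")
    expect_equal(res$switches, 0L)
    ids <- vapply(res$components, function(c) c$id, "")
    slow <- res$components[[match("slow", ids)]]
    fast <- res$components[[match("fast", ids)]]
    slog <- slow$log_mat[seq_len(slow$log_n), , drop = FALSE]
    flog <- fast$log_mat[seq_len(fast$log_n), , drop = FALSE]
    expect_true(all(slog[, 4] <= 1 + 1e-12))
    expect_true(all(flog[, 4] <= 1 + 1e-12))
    for (i in seq_len(nrow(slog))) {
      over <- flog[, 2] > slog[i, 1] & flog[, 1] < slog[i, 2]
      if (any(over))
        expect_gte(slog[i, 4], max(flog[over, 4]) - 1e-12)
    }
  }
})

test_that("synchronous communication lands the fast grid on every macro
           endpoint", {
  prob <- synth_slow()
  comps <- problem_components(prob, reltol = 1e-4)
  res <- mr_run(comps, mr_config("slow-first", "synchronous", "multirate",
                                 t_end = 0.3))
  expect_equal(res$status, "ok")
  slow_t <- res$trajectories$slow$times
  fast_t <- res$trajectories$fast$times
  # every slow time point is (to rounding) a fast time point
  for (t in slow_t)
    expect_lt(min(abs(fast_t - t)), 1e-9 * max(1, abs(t)))
})
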