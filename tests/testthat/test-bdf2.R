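test_that("bdf2_coefficients match the non-uniform formulas", {
  co <- bdf2_coefficients(0.5, 0.5) # gamma = 1: classic BDF2
  expect_equal(co$alpha1, 4 / 3)
  expect_equal(co$alpha2, -1 / 3)
  expect_equal(co$beta, 2 / 3)
  co <- bdf2_coefficients(2, 1) # gamma = 2
  expect_equal(co$alpha2, -4 / 5)
  expect_equal(co$alpha1, 9 / 5)
  expect_equal(co$beta, 3 / 5)
  # identity alpha1 + alpha2 = 1 for arbitrary ratios
  set.seed(7)
  for (g in c(10^runif(20, -2, 2))) {
    co <- bdf2_coefficients(g, 1)
    expect_equal(co$alpha1 + co$alpha2, 1)
    expect_gt(co$gamma, 0)
  }
  expect_error(bdf2_coefficients(0, 1), "h_next")
  expect_error(bdf2_coefficients(1, -1), "h_prev")
})

test_that("bdf2_step is exact on quadratic solutions for non-uniform grids", {
  h <- mr_history(1L)
  h <- append_state(h, 0, 0)
  h <- append_state(h, 0.7, 0.49)
  st <- bdf2_step(h, 0.5, function(t, x, u) 2 * t, rtol = 1e-12, atol = 1e-14)
  expect_equal(st$x, 1.44, tolerance = 1e-12) # x(t) = t^2 at t = 1.2
  # random quadratics on random grids
  set.seed(11)
  for (rep in 1:10) {
    co <- rnorm(3)
    f <- function(t) co[1] + co[2] * t + co[3] * t^2
    fp <- function(t, x, u) co[2] + 2 * co[3] * t
    ts <- sort(cumsum(runif(2, 0.05, 1)))
    hh <- mr_history(1L)
    hh <- append_state(hh, ts[1], f(ts[1]))
    hh <- append_state(hh, ts[2], f(ts[2]))
    hs <- runif(1, 0.05, 1)
    st <- bdf2_step(hh, hs, fp, rtol = 1e-12, atol = 1e-14)
    expect_equal(st$x, f(ts[2] + hs), tolerance = 1e-9)
  }
})

test_that("bdf2_step preserves constants and solves the linear implicit
           relation in closed form", {
  h <- mr_history(1L)
  h <- append_state(h, 0, 3)
  h <- append_state(h, 0.3, 3)
  st <- bdf2_step(h, 0.2, function(t, x, u) 0 * x, rtol = 1e-12, atol = 1e-14)
  expect_equal(st$x, 3, tolerance = 1e-13)
  # scalar dx/dt = -lambda x, uniform h: hand-solved implicit relation
  lambda <- 10; hs <- 0.1
  x0 <- 1; x1 <- exp(-lambda * hs)
  h <- mr_history(1L)
  h <- append_state(h, 0, x0)
  h <- append_state(h, hs, x1)
  st <- bdf2_step(h, hs, function(t, x, u) -lambda * x,
                  rtol = 1e-12, atol = 1e-14)
  expected <- (4 / 3 * x1 - 1 / 3 * x0) / (1 + 2 / 3 * lambda * hs)
  expect_equal(st$x, expected, tolerance = 1e-12)
})

test_that("bdf1 startup solves the backward-Euler relation", {
  st <- bdf1_startup_step(1, 0, 0.1, function(t, x, u) -x,
                          rtol = 1e-12, atol = 1e-14)
  expect_equal(st$x, 1 / 1.1, tolerance = 1e-12)
  st <- bdf1_startup_step(c(2, -1), 0, 0.1, function(t, x, u) c(0, 0),
                          rtol = 1e-10, atol = 1e-12)
  expect_equal(st$x, c(2, -1))
  st <- bdf1_startup_step(0.5, 0, 0.25, function(t, x, u) 3,
                          rtol = 1e-10, atol = 1e-12)
  expect_equal(st$x, 0.5 + 0.25 * 3, tolerance = 1e-12)
})

test_that("fixed-step global error declines at second order on a stiff
           forced problem", {
  fs <- forced_stiff(50)
  hs <- 1 / c(40, 80, 160, 320, 640)
  errs <- vapply(hs, function(h) {
    end <- bdf2_fixed_steps(fs$rhs, fs$exact, h, 1)
    abs(end$x - fs$exact(end$t))
  }, numeric(1))
  slope <- -coef(lm(log(errs) ~ log(1 / hs)))[[2]]
  expect_gt(slope, 1.8)
  expect_lt(slope, 2.2)
})

test_that("strong damping contracts the step for all step ratios", {
  lambda <- 1e4
  for (g in seq(0.2, 2, by = 0.2)) {
    h_prev <- 1
    h <- mr_history(1L)
    h <- append_state(h, 0, 1)
    h <- append_state(h, h_prev, 1)
    st <- bdf2_step(h, g * h_prev, function(t, x, u) -lambda * x,
                    rtol = 1e-10, atol = 1e-12)
    expect_lt(abs(st$x), 1)
  }
})

test_that("every right-hand-side evaluation is accounted for in the report", {
  count <- 0L
  rhs <- function(t, x, u) { count <<- count + 1L; -2 * x + sin(t) }
  h <- mr_history(1L)
  h <- append_state(h, 0, 1)
  h <- append_state(h, 0.05, 0.9)
  total <- 0L
  for (k in 1:5) {
    st <- bdf2_step(h, 0.05, rhs, rtol = 1e-8, atol = 1e-10)
    h <- append_state(h, st$t, st$x)
    total <- total + st$report$rhs_evals + st$report$jac_evals
  }
  expect_identical(count, total)
})
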