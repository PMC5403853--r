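test_that("the electrical model has a stationary resting state and sane
           current responses", {
  p <- electrical_params()
  x0 <- electrical_rest_state(p)
  # relax the approximate rest to the true fixed point, then check
  # stationarity relative to the resting scale of each variable
  out <- deSolve::lsoda(x0, c(0, 5),
                        function(t, y, parms)
                          list(electrical_rhs(t, y, NULL, p)),
                        rtol = 1e-10, atol = 1e-12)
  xr <- unname(out[nrow(out), -1])
  dx <- electrical_rhs(0, xr, NULL, p)
  scale <- pmax(abs(xr), 1)
  expect_lt(max(abs(dx) / scale), 1e-5)
  # a depolarizing current step makes the soma potential rise from rest
  dxi <- electrical_rhs(0, xr, NULL, p, i_inj = 10)
  expect_gt(dxi[1], 0)
  # more active potassium channels (larger availability) lower dV/dt of a
  # depolarized spine
  lay <- multirate:::elec_layout(p, "TC-slow")
  xd <- xr
  xd[lay$spine] <- -40
  d_lo <- electrical_rhs(0, xd, 0.4, p)
  d_hi <- electrical_rhs(0, xd, 0.8, p)
  expect_lt(d_hi[lay$spine], d_lo[lay$spine])
})

test_that("the pulse protocol is piecewise constant with the documented
           phases", {
  expect_equal(pulse_current_protocol(0.02), 0)      # before the first pulse
  expect_equal(pulse_current_protocol(0.051), 25)    # inside a pulse
  expect_equal(pulse_current_protocol(0.551), 25)    # second pulse
  expect_equal(pulse_current_protocol(0.3), 0)       # between pulses
  expect_equal(pulse_current_protocol(3), 4)         # burst phase
  expect_equal(pulse_current_protocol(5.5), 0)       # after the protocol
  expect_equal(pulse_current_protocol(c(0.02, 3)), c(0, 4)) # vectorized
})

test_that("conserved biochemical moieties have zero net derivative at
           arbitrary states", {
  p <- biochemical_params()
  set.seed(3)
  for (rep in 1:20) {
    x <- runif(4, 0, 0.5)
    ca <- runif(1, 0, 2)
    dx <- biochemical_rhs(0, x, ca, p)
    expect_equal(dx[1] + dx[2], 0) # total MAPK
    expect_equal(dx[3] + dx[4], 0) # total channel
  }
  # zero free species at conserved totals: derivatives stay finite
  dx <- biochemical_rhs(0, c(p$mapk_tot, 0, p$k_tot, 0), 0, p)
  expect_true(all(is.finite(dx)))
  expect_error(biochemical_rhs(0, c(-1, 0, 0, 0), 0.1, p), "negative")
})

test_that("clamped calcium drives the MAPK switch between two distinct
           stable states", {
  p <- biochemical_params()
  rest <- biochemical_rest_state(p)
  clamp <- function(ca, x0, T = 600)
    unname(deSolve::lsoda(x0, c(0, T),
                          function(t, y, parms)
                            list(biochemical_rhs(t, y, ca, p)),
                          rtol = 1e-10, atol = 1e-12)[2, -1])
  lo <- clamp(p$ca_rest, rest)
  hi <- clamp(1.0, rest)
  expect_lt(lo[2], 0.05)            # low P-MAPK fixed point
  expect_gt(hi[2], 0.3)             # high P-MAPK fixed point
  # bistable memory: the high state persists after calcium returns to rest
  back <- clamp(p$ca_rest, hi)
  expect_gt(back[2], 0.3)
  # conserved totals across the whole excursion
  expect_equal(hi[1] + hi[2], p$mapk_tot, tolerance = 1e-6)
  expect_equal(back[3] + back[4], p$k_tot, tolerance = 1e-6)
})

test_that("conserved totals drift below the relative tolerance over 5 s of
           adaptive integration", {
  p <- biochemical_params()
  reltol <- 1e-6
  # time-varying calcium drive emulating a spiking episode
  rhs <- function(t, x, u)
    biochemical_rhs(t, x, 0.05 + 0.5 * (1 + sin(2 * pi * 2 * t)), p)
  x0 <- biochemical_rest_state(p)
  sol <- bdf2_solve(rhs, x0, 0, 5, reltol = reltol,
                    abstol = reltol * 1e-3 * p$mapk_tot)
  totals_m <- sol$states[, 1] + sol$states[, 2]
  totals_k <- sol$states[, 3] + sol$states[, 4]
  expect_lt(max(abs(totals_m - totals_m[1])) / totals_m[1], reltol)
  expect_lt(max(abs(totals_k - totals_k[1])) / totals_k[1], reltol)
})

test_that("the communicated calcium concentration is far smoother than the
           calcium flux over a spiking episode", {
  p <- electrical_params()
  x0 <- electrical_rest_state(p)
  rhs <- function(t, y, parms)
    list(electrical_rhs(t, y, NULL, p, i_inj = 4))
  out <- deSolve::lsoda(x0, seq(0, 0.5, by = 2e-5), rhs,
                        rtol = 1e-8, atol = 1e-8)
  lay <- multirate:::elec_layout(p, "TC-slow")
  vsp <- out[, 1 + lay$spine]
  ca <- out[, 1 + lay$ca]
  mca <- 1 / (1 + exp(-(vsp - p$ca_half) / p$ca_slope))
  flux <- p$flux_scale * pmax(-(p$g_ca * mca^2 * (vsp - p$e_ca)), 0)
  rel_rate <- function(s) max(abs(diff(s) / diff(out[, 1]))) / diff(range(s))
  # qualitative contrast: the concentration pool integrates the spike-locked
  # flux, so its normalized rate of change is an order of magnitude smaller
  # (the flux's sharpness is bounded by the spike upstroke here, which caps
  # the achievable contrast; see the methods vignette)
  expect_gt(rel_rate(flux) / rel_rate(ca), 10)
})

test_that("gating variables stay in [0, 1] and calcium stays non-negative
           during sustained firing", {
  r <- simulate_electrical(t_end = 0.5, reltol = 3e-4,
                           protocol = list(regular_until = 0,
                                           burst_amp = 4, t_end = 0.5))
  p <- electrical_params()
  lay <- multirate:::elec_layout(p, "TC-slow")
  gidx <- c(lay$m, lay$h, lay$n, lay$p)
  g <- r$solution$states[, gidx]
  expect_true(all(g >= -1e-6 & g <= 1 + 1e-6))
  expect_true(all(r$solution$states[, lay$ca] >= 0))
  # sustained drive produces regular tonic firing
  expect_gt(r$stats$rates[["burst"]], 50)
})

test_that("synthetic problem fixtures expose the documented structure", {
  prob <- make_synthetic_problem(coupling_strength = 0)
  # decoupled closed form matches a direct solve of the monolithic system
  ref <- compute_reference(prob, c(0, 0.5, 1), tol = 1e-12)
  cf <- prob$closed_form(1)
  expect_equal(ref$at(1)[1], cf$slow, tolerance = 1e-9)
  expect_equal(ref$at(1)[2], cf$fast_y, tolerance = 1e-7)
  # fast/slow signal selection switches the communicated state
  pf <- make_synthetic_problem(signal_speed = "fast")
  ps <- make_synthetic_problem(signal_speed = "slow")
  x <- c(0.3, 0.7)
  expect_equal(pf$components[[2]]$g(x), 0.3)
  expect_equal(ps$components[[2]]$g(x), 0.7)
  expect_error(make_synthetic_problem(stiffness_ratio = 0.5))
})

test_that("both test-case variants expose consistent coupled problems", {
  for (variant in c("TC-slow", "TC-fast")) {
    prob <- make_testcase(variant)
    expect_s3_class(prob, "mr_problem")
    x_elec <- prob$components[[2]]$x0
    x_bioch <- prob$components[[1]]$x0
    # the biochemical output is the availability fraction in [0, 1]
    u <- prob$components[[1]]$g(x_bioch)
    expect_gt(u, 0)
    expect_lte(u, 1)
    # monolithic rhs agrees with the split component rhs at the initial
    # point when each side is fed the other's exchanged output
    mono <- prob$monolithic$rhs(0, prob$monolithic$x0)
    de <- prob$components[[2]]$rhs(0, x_elec,
                                   list(biochemical = u))
    ue <- prob$components[[2]]$g(x_elec)
    db <- prob$components[[1]]$rhs(0, x_bioch, list(electrical = ue))
    expect_equal(mono, c(de, db), tolerance = 1e-12)
  }
  # TC-slow communicates a concentration, TC-fast a (non-negative) flux
  ps <- make_testcase("TC-slow")
  expect_equal(ps$components[[2]]$g(ps$components[[2]]$x0),
               electrical_params()$ca_rest)
  pf <- make_testcase("TC-fast")
  expect_gte(pf$components[[2]]$g(pf$components[[2]]$x0), 0)
})
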