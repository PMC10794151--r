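test_that("trace subtraction is exact, labelled, and anti-symmetric", {
  a <- synthetic_sweep(rnorm(300))
  b <- synthetic_sweep(rnorm(300))
  expect_true(all(subtract_traces(a, a)$current == 0))
  ab <- subtract_traces(a, b, label = "TTX-S")
  ba <- subtract_traces(b, a)
  expect_equal(ab$current, -ba$current)
  expect_identical(ab$condition, "TTX-S")
  expect_error(subtract_traces(a, synthetic_sweep(rnorm(300), voltage = 10)),
               "different test voltages")
})

test_that("peak finding matches the closed-form argmax of a double exponential", {
  tau_r <- 0.5; tau_d <- 2; A <- 100
  dt <- 0.01
  t <- seq(0, 15, by = dt)
  trace <- -A * (1 - exp(-t / tau_r)) * exp(-t / tau_d)
  sw <- synthetic_sweep(trace, dt = dt, onset = 0, duration = 15)
  pk <- peak_amplitude(sw, search_window = c(0, 10))
  t_star <- tau_r * log(1 + tau_d / tau_r)   # analytic argmax
  expect_lt(abs(pk$t_peak - t_star), dt + 1e-12)
  expect_lt(pk$peak, 0)
})

test_that("flat and noise-only traces behave at the classifier boundary", {
  zero <- synthetic_sweep(rep(0, 500), dt = 0.02, onset = 1, duration = 9)
  pk <- peak_amplitude(zero)
  expect_identical(pk$peak, 0)
  expect_true(pk$no_peak)
  expect_equal(pk$t_peak, 1)

  set.seed(33)
  noise <- synthetic_sweep(rnorm(1000, sd = 2), dt = 0.01, onset = 1,
                           duration = 9)
  expect_lt(abs(peak_amplitude(noise)$peak), 30)
})

test_that("persistent current isolates the non-inactivating fraction", {
  # fast-inactivating current only: essentially nothing left at 10 ms
  p <- quick_params(g_ttxr = 0, g_leak = 0)
  p$tau_h_anchors$tau <- rep(1, 3)
  proto <- quick_protocol()
  sw <- baseline_correct(simulate_sweep(0, p, protocol = proto))
  expect_lt(abs(persistent_current(sw)),
            0.01 * abs(peak_amplitude(sw)$peak))

  # ungated persistent pool: measured level is g_p * (V - E_rev) exactly
  pp <- quick_params(g_nav17 = 0, g_ttxs_other = 0, g_ttxr = 0, g_leak = 0,
                     g_persistent = 1.5)
  swp <- simulate_sweep(0, pp, protocol = proto)
  expect_equal(persistent_current(swp), 1.5 * (0 - pp$e_rev_sim),
               tolerance = 0.02)

  expect_error(persistent_current(sw, at = 13), "exceeds the step duration")
})

test_that("percent inhibition reproduces the printed-amplitude arithmetic", {
  expect_equal(percent_inhibition(-141, -54), 100 * (141 - 54) / 141)
  expect_equal(percent_inhibition(-141, -54), 61.7, tolerance = 0.001)
  expect_equal(percent_inhibition(-80, -80), 0)
  expect_equal(percent_inhibition(-80, 0), 100)
  clipped <- percent_inhibition(-80, -90, clip = TRUE)
  expect_equal(as.numeric(clipped), 0)
  expect_lt(attr(clipped, "raw"), 0)
  expect_error(percent_inhibition(0, -10), "positive")
})

test_that("blocking a fraction f of all pools inhibits the peak by 100f", {
  p <- quick_params(g_ttxr = 0, g_leak = 0)   # all pools TTX-sensitive
  proto <- quick_protocol()
  ctl <- baseline_correct(simulate_sweep(0, p, protocol = proto))
  for (f in c(0.25, 0.618, 0.9)) {
    drg <- baseline_correct(simulate_sweep(0, p, drug = drug_state(f, 0),
                                           protocol = proto))
    inh <- percent_inhibition(peak_amplitude(ctl)$peak,
                              peak_amplitude(drg)$peak)
    expect_equal(inh, 100 * f, tolerance = 0.5 / 100)
  }
})

test_that("isolate_component summarises a preprocessed family at one voltage", {
  p <- quick_params(g_leak = 0.02)   # leak small enough not to bias peaks
  fam <- simulate_family(quick_protocol(test_voltages = c(-10, 0)), p,
                         conditions = standard_conditions(c("control", "TTX")))
  res <- isolate_component(preprocess_family(fam), "control", "TTX", 0)
  expect_s3_class(res, "isolation_result")
  expect_lte(abs(res$peak_sensitive), abs(res$peak_control) + 1e-6)
  expect_identical(res$sensitive_trace$condition, "TTX-S")
  frac <- (p$g_nav17 + p$g_ttxs_other) /
    (p$g_nav17 + p$g_ttxs_other + p$g_ttxr)
  expect_equal(res$percent_inhibition / 100, frac, tolerance = 0.1)
})
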