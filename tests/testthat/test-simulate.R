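test_that("degenerate membranes produce the expected flat traces", {
  p <- quick_params(g_nav17 = 0, g_ttxs_other = 0, g_ttxr = 0, g_leak = 0)
  sw <- simulate_sweep(0, p, protocol = quick_protocol())
  expect_true(all(sw$current == 0))

  # step to the holding potential: nothing changes, trace stays at the
  # holding current
  p2 <- quick_params()
  proto <- step_protocol(holding = -20, test_voltages = -20, step_onset = 2,
                         step_duration = 12, sweep_duration = 16)
  sw2 <- simulate_sweep(-20, p2, protocol = proto)
  expect_lt(diff(range(sw2$current)), 1e-9)
})

test_that("simulation is deterministic under a fixed master seed", {
  p <- quick_params()
  proto <- quick_protocol(test_voltages = c(-20, 0))
  f1 <- simulate_family(proto, p, seed = 11,
                        conditions = standard_conditions(c("control", "TTX")))
  f2 <- simulate_family(proto, p, seed = 11,
                        conditions = standard_conditions(c("control", "TTX")))
  expect_identical(lapply(f1$sweeps, `[[`, "current"),
                   lapply(f2$sweeps, `[[`, "current"))
  f3 <- simulate_family(proto, p, seed = 12,
                        conditions = list(control = drug_state()))
  expect_false(identical(f1$sweeps[[1]]$current, f3$sweeps[[1]]$current))
})

test_that("family emits repeats x voltages x conditions, plus P/4 sub-sweeps", {
  p <- quick_params()
  proto <- step_protocol(n_repeats_per_voltage = 8L, step_onset = 2,
                         step_duration = 10, sweep_duration = 14)
  fam <- simulate_family(proto, p)
  expect_length(fam$sweeps, 12 * 8)

  proto4 <- quick_protocol(test_voltages = c(-10, 0), p4_enabled = TRUE)
  fam4 <- simulate_family(proto4, p)
  expect_length(fam4$sweeps, 2 * 2 * 5)
  roles <- vapply(fam4$sweeps, `[[`, character(1), "role")
  expect_equal(sum(roles == "p4_sub"), 2 * 2 * 4)
})

test_that("pharmacological subtraction recovers the blocked pools exactly", {
  p <- quick_params()
  proto <- quick_protocol(test_voltages = c(-20, 0, 20))
  ctl <- lapply(proto$test_voltages, simulate_sweep, params = p,
                protocol = proto)
  ttx <- lapply(proto$test_voltages, simulate_sweep, params = p,
                drug = drug_state(1, 0), protocol = proto)
  pools <- p
  pools$g_ttxr <- 0; pools$g_leak <- 0
  ref <- lapply(proto$test_voltages, simulate_sweep, params = pools,
                protocol = proto)
  for (i in seq_along(ctl)) {
    diff_trace <- ctl[[i]]$current - ttx[[i]]$current
    expect_lt(max(abs(diff_trace - ref[[i]]$current)), 1e-8)
  }
})

test_that("gate variables remain within [0, 1] across the voltage grid", {
  p <- quick_params()
  proto <- quick_protocol()
  for (v in seq(-60, 50, by = 10)) {
    sw <- simulate_sweep(v, p, protocol = proto)
    gr <- sw$meta$gate_range
    expect_gte(gr[1], 0)
    expect_lte(gr[2], 1)
  }
})

test_that("noise-free peaks are grid-convergent: halving the step changes them by <0.1%", {
  p1 <- default_gating_params(g_leak = 0)
  p2 <- p1; p2$sample_rate <- 2e5
  proto <- step_protocol()
  for (v in c(-20, 0)) {
    a <- abs(peak_amplitude(baseline_correct(
      simulate_sweep(v, p1, protocol = proto)))$peak)
    b <- abs(peak_amplitude(baseline_correct(
      simulate_sweep(v, p2, protocol = proto)))$peak)
    expect_lt(abs(a - b) / a, 1e-3)
  }
})

test_that("invalid simulation requests are rejected", {
  p <- quick_params()
  expect_error(simulate_sweep(300, p), "coverage")
  bad <- quick_params()
  bad$v_half_m <- NaN
  expect_error(simulate_sweep(0, bad), "finite")
  expect_error(gating_params(v_half_m = -20, k_m = -1,
                             tau_m_anchors = data.frame(v = 0, tau = 1),
                             tau_h_anchors = data.frame(v = 0, tau = 1)),
               "positive")
  expect_error(step_protocol(test_voltages = c(0, -10)), "increasing")
  expect_error(drug_state(1.5, 0), "0, 1")
})
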