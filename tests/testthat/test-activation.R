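test_that("I-V construction validates its inputs and handles silent cells", {
  p <- quick_params(g_nav17 = 0, g_ttxs_other = 0, g_ttxr = 0, g_leak = 0)
  fam <- simulate_family(quick_protocol(test_voltages = c(-20, 0, 20)), p)
  iv <- build_iv(preprocess_family(fam))
  expect_equal(nrow(iv), 3)
  expect_true(all(iv$peak == 0))

  pre <- preprocess_family(fam)
  pre$sweeps <- pre$sweeps[-2]   # drop the 0 mV sweep
  expect_error(build_iv(pre), "0 mV")
  expect_error(iv_curve(data.frame(v = c(0, 0), peak = c(-1, -2))), "unique")
})

test_that("reversal extrapolation recovers linear and simulated reversals", {
  iv <- iv_curve(data.frame(v = c(30, 40, 50), peak = c(-30, -20, -10)))
  expect_equal(as.numeric(estimate_reversal(iv)), 60)

  p <- default_gating_params(g_leak = 0)
  fam <- simulate_family(step_protocol(), p,
                         conditions = standard_conditions(c("control", "TTX")))
  sens <- ttxs_traces(preprocess_family(fam))
  iv_sim <- iv_curve(do.call(rbind, lapply(sens, function(s)
    data.frame(v = s$test_voltage, peak = peak_amplitude(s)$peak))))
  expect_lt(abs(as.numeric(estimate_reversal(iv_sim)) - p$e_rev_sim), 3)

  expect_error(estimate_reversal(iv, n_tail_points = 5), "fewer")
})

test_that("Nernst potential matches the closed form and its symmetries", {
  expect_equal(nernst_potential(145, 10, 294), 67.8, tolerance = 0.001)
  expect_equal(nernst_potential(12, 12), 0)
  expect_equal(nernst_potential(10, 145, 294),
               -nernst_potential(145, 10, 294))
  expect_error(nernst_potential(-1, 10), "positive")
})

test_that("chord conductance reproduces hand arithmetic and excludes the reversal band", {
  iv <- iv_curve(data.frame(v = c(-20, -10, 0), peak = c(-30, -60, -87)))
  gc <- conductance_curve(iv, e_rev = -60.6)
  expect_equal(gc$g[gc$v == 0], 87 / 60.6, tolerance = 1e-12)

  ohmic <- iv_curve(data.frame(v = seq(-40, 40, 10),
                               peak = 2 * (seq(-40, 40, 10) - 65)))
  expect_true(all(abs(conductance_curve(ohmic, 65)$gnorm - 1) < 1e-12))

  tight <- iv_curve(data.frame(v = c(63, 64), peak = c(-2, -1)))
  expect_error(conductance_curve(tight, 65), "excluded band")
})

test_that("Boltzmann fitting is self-consistent on exact samples", {
  v <- seq(-60, 50, by = 10)
  gn <- data.frame(v = v, gnorm = 1 / (1 + exp((-14.2 - v) / 6.1)))
  fit <- fit_boltzmann(gn)
  expect_equal(unname(coef(fit)["v_half"]), -14.2, tolerance = 1e-6)
  expect_equal(unname(coef(fit)["k"]), 6.1, tolerance = 1e-6)
  # midpoint identity and the value the curve predicts at 0 mV
  expect_equal(unname(predict(fit, coef(fit)["v_half"])),
               unname(coef(fit)["amplitude"]) / 2)
  expect_equal(unname(predict(fit, 0)), 0.911, tolerance = 1e-3)
  expect_error(fit_boltzmann(gn[1:3, ]), "four")
  expect_error(fit_boltzmann(data.frame(v = v[1:6],
                                        gnorm = rep(0.01, 6))),
               "half-maximum")
})

test_that("Boltzmann fit is translation-covariant in voltage", {
  set.seed(5)
  v <- seq(-60, 50, by = 10)
  gn0 <- data.frame(v = v,
                    gnorm = 1 / (1 + exp((-12 - v) / 7)) +
                      rnorm(length(v), sd = 0.01))
  base <- coef(fit_boltzmann(gn0))
  for (delta in runif(3, -25, 25)) {
    shifted <- transform(gn0, v = v + delta)
    cf <- coef(fit_boltzmann(shifted))
    expect_equal(unname(cf["v_half"]), unname(base["v_half"]) + delta,
                 tolerance = 1e-4)
    expect_equal(unname(cf["k"]), unname(base["k"]), tolerance = 1e-4)
  }
})

test_that("activation threshold picks the most hyperpolarised detected voltage", {
  iv <- iv_curve(data.frame(v = c(-50, -40, -30, -20),
                            peak = c(-0.4, -6, -40, -120)))
  expect_equal(activation_threshold(iv), -40)
  expect_equal(activation_threshold(iv, criterion_pA = 30), -30)
  expect_equal(activation_threshold(iv, criterion_pA = 0), -50)
  silent <- iv_curve(data.frame(v = c(-20, 0), peak = c(0, 0)))
  expect_true(is.na(activation_threshold(silent)))
})
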