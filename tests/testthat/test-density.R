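test_that("density arithmetic matches hand calculation", {
  expect_equal(current_density(-82, 34), 82 / 34)
  expect_equal(current_density(0, 30), 0)
  expect_error(current_density(-82, 0), "positive")

  expect_equal(conductance_density(2.4, 0, -60.6), 2400 / 60.6)
  expect_equal(conductance_density(0, 0, -60.6), 0)
  expect_error(conductance_density(2.4, -60.6, -60.6), "equals")

  d <- channel_density(39.60396, gamma = 6.4, p_open = 0.4)
  expect_equal(d$channels_per_um2, 0.1547, tolerance = 1e-3)
  expect_equal(d$channels_per_um2_rounded, 0.15)
  d6 <- channel_density(39.60396, gamma = 6.4, p_open = 0.6)
  expect_equal(d6$channels_per_um2_rounded, 0.10)
  # identity scaling: gamma equal to the per-pF conductance, full opening
  ident <- channel_density(6.4, gamma = 6.4, p_open = 1,
                           specific_capacitance = 1)
  expect_equal(ident$channels_per_um2, 1)

  expect_equal(as.numeric(channels_per_cell(0.10)), 350)
  expect_equal(as.numeric(channels_per_cell(0.15)), 525)
  expect_equal(as.numeric(channels_per_cell(0)), 0)
})

test_that("the dimensional chain closes against a one-line oracle on random inputs", {
  set.seed(9)
  for (i in 1:20) {
    cd <- runif(1, 0.5, 10); e_rev <- runif(1, -80, -40)
    gamma <- runif(1, 2, 20); po <- runif(1, 0.1, 1)
    sc <- runif(1, 0.005, 0.02); area <- runif(1, 1000, 6000)
    chain <- channel_density_chain(cd, 0, e_rev, gamma, po, sc, area)
    oracle_um2 <- 1000 * cd / abs(e_rev) / (gamma * po) * sc
    expect_equal(chain$channels_per_um2, oracle_um2, tolerance = 1e-12)
    expect_equal(chain$channels_per_cell,
                 as.integer(round(round(oracle_um2, 2) * area)))
  }
})

test_that("channel density is inversely proportional to gamma and p_open", {
  base <- channel_density(40, gamma = 5, p_open = 0.5)
  expect_equal(channel_density(40, gamma = 10, p_open = 0.5)$channels_per_pF,
               base$channels_per_pF / 2)
  expect_equal(channel_density(40, gamma = 5, p_open = 0.25)$channels_per_pF,
               base$channels_per_pF * 2)
})

test_that("responder classification follows the strict 30 pA / fast-tau rule", {
  expect_true(classify_responder(82, 1.0))
  expect_false(classify_responder(30, 1.0))     # boundary is strict
  expect_false(classify_responder(100, NA))     # no fittable fast component
  expect_false(classify_responder(100, 8))      # slow inactivation
  expect_true(classify_responder(-45, 2))       # magnitude convention
})

test_that("cohort summaries report responder fractions and responder-only moments", {
  cells <- c(
    lapply(1:13, function(i)
      list(peak = 70 + i, responder = TRUE, current_density = 2 + i / 10,
           tau_at_0mV = 1, percent_inhibition = c(TTX = 60 + i / 10))),
    lapply(1:64, function(i)
      list(peak = 5, responder = FALSE, current_density = 0.2,
           tau_at_0mV = NA_real_, percent_inhibition = c(TTX = NA_real_))))
  s <- summarize_cohort(cells)
  expect_equal(s$n_cells, 77)
  expect_equal(s$n_responders, 13)
  expect_equal(s$responder_fraction, 17)
  expect_equal(unname(s$peak_amplitude["mean"]), mean(70 + 1:13))
  expect_equal(unname(s$peak_amplitude["sem"]),
               sd(70 + 1:13) / sqrt(13))
  expect_equal(unname(s$percent_inhibition$TTX["n"]), 13)

  single <- summarize_cohort(list(list(peak = 50, responder = TRUE)))
  expect_true(is.na(single$peak_amplitude["sem"]))
  expect_error(summarize_cohort(list()), "empty")
})
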