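test_that("F/F0 normalisation is exact on constructed traces", {
  const <- fluorescence_trace(seq(0, 58, 2), rep(137, 30), 10)
  expect_true(all(normalize_f_f0(const)$intensity == 1))

  tr <- generate_fluorescence(baseline_frames = 20, amplitude = 150, f0 = 100)
  norm <- normalize_f_f0(tr)
  expect_equal(max(norm$intensity), 1 + 150 / 100)
  expect_equal(mean(norm$intensity[1:19]), 1)
  expect_equal(attr(norm, "f0"), 100)

  dark <- fluorescence_trace(seq(0, 18, 2), c(rep(0, 5), rep(10, 5)), 6)
  expect_error(normalize_f_f0(dark), "positive")
})

test_that("normalisation and AUC are invariant to intensity rescaling", {
  tr <- generate_fluorescence(noise_sd = 5, seed = 4)
  scaled <- fluorescence_trace(tr$time, 7.3 * tr$intensity,
                               tr$stimulus_onset_index)
  a <- normalize_f_f0(tr); b <- normalize_f_f0(scaled)
  expect_equal(a$intensity, b$intensity)
  expect_equal(auc(a, 120), auc(b, 120))
})

test_that("AUC handles flat traces, rectangles, and closed-form decays", {
  flat <- normalize_f_f0(fluorescence_trace(seq(0, 98, 2), rep(50, 50), 10))
  expect_equal(auc(flat, 60), 0)

  # rectangular pulse: F/F0 = 2 over exactly 10 s
  y <- c(rep(100, 10), rep(200, 6), rep(100, 34))
  rect <- normalize_f_f0(fluorescence_trace(seq(0, 98, 2), y, 11))
  expect_equal(auc(rect, 10), 10)

  # exponential transient a*exp(-s/tau): closed form a*tau*(1 - e^-5)
  tau <- 20; a <- 1.5
  tm <- seq(0, 150, 2)
  onset <- 11
  s <- tm - tm[onset]
  y2 <- 100 * (1 + ifelse(s < 0, 0, a * exp(-s / tau)))
  dec <- normalize_f_f0(fluorescence_trace(tm, y2, onset))
  expect_equal(auc(dec, 5 * tau), a * tau * (1 - exp(-5)), tolerance = 0.01)
})

test_that("AUC is additive over adjacent windows", {
  tr <- normalize_f_f0(generate_fluorescence(noise_sd = 4, seed = 12))
  onset_t <- tr$time[tr$stimulus_onset_index]
  expect_equal(auc(tr, 40) + auc(tr, 60, from = onset_t + 40),
               auc(tr, 100), tolerance = 1e-10)
  expect_error(auc(tr, 1e5), "beyond the trace")
})

test_that("fluorescence traces round-trip through TSV and batch summaries run", {
  dir <- tempfile("catraces-")
  dir.create(dir)
  for (i in 1:3)
    write_fluorescence(generate_fluorescence(amplitude = 50 * i, noise_sd = 2,
                                             seed = i),
                       file.path(dir, sprintf("trace%d.tsv", i)))
  back <- read_fluorescence(file.path(dir, "trace2.tsv"))
  orig <- generate_fluorescence(amplitude = 100, noise_sd = 2, seed = 2)
  expect_equal(back$intensity, orig$intensity)
  expect_identical(back$stimulus_onset_index, orig$stimulus_onset_index)

  s <- summarize_fluorescence_dir(dir, duration = 150)
  expect_equal(nrow(s), 3)
  expect_true(all(diff(s$peak_f_f0) > 0))
})
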