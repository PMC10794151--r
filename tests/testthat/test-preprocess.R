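test_that("averaging identical sweeps is the identity and metadata counts runs", {
  sw <- synthetic_sweep(sin(seq(0, 4, length.out = 200)))
  avg <- average_sweeps(rep(list(sw), 8))
  expect_equal(avg$current, sw$current)
  expect_identical(avg$meta$n_averaged, 8L)
  expect_true(is.na(avg$repeat_index))
})

test_that("averaging n noisy sweeps shrinks the noise by about sqrt(n)", {
  set.seed(101)
  n <- 10L; len <- 1e4
  sweeps <- lapply(seq_len(n), function(i)
    synthetic_sweep(rnorm(len, sd = 2)))
  avg <- average_sweeps(sweeps)
  expect_equal(sd(avg$current), 2 / sqrt(n), tolerance = 0.1)
})

test_that("averaging is linear and rejects mismatched sweeps", {
  x <- synthetic_sweep(rnorm(100))
  y <- synthetic_sweep(rnorm(100))
  a <- 3.7
  ax <- synthetic_sweep(a * x$current)
  ay <- synthetic_sweep(a * y$current)
  expect_equal(average_sweeps(list(ax, ay))$current,
               a * average_sweeps(list(x, y))$current)
  expect_error(average_sweeps(list(x, synthetic_sweep(rnorm(100), voltage = 10))),
               "different test voltages")
  expect_error(average_sweeps(list(x, synthetic_sweep(rnorm(50)))),
               "different lengths")
})

test_that("P/4 removes a purely ohmic response exactly, for any leak", {
  proto <- quick_protocol(test_voltages = 0, p4_enabled = TRUE)
  set.seed(7)
  for (g in runif(4, 0.5, 5)) {
    p <- quick_params(g_nav17 = 0, g_ttxs_other = 0, g_ttxr = 0, g_leak = g)
    fam <- simulate_family(proto, p)
    main <- family_sweeps(fam, "control", 0, "main")[[1]]
    subs <- Filter(function(s) s$repeat_index == main$repeat_index,
                   family_sweeps(fam, "control", 0, "p4_sub"))
    corrected <- baseline_correct(p4_subtract(main, subs))
    expect_lt(max(abs(corrected$current)), 0.01)
  }
})

test_that("P/4 cancels linear capacitive edge transients too", {
  proto <- quick_protocol(test_voltages = 0, p4_enabled = TRUE)
  p <- quick_params(g_nav17 = 0, g_ttxs_other = 0, g_ttxr = 0, g_leak = 2)
  fam <- simulate_family(proto, p, cap_edge = TRUE)
  main <- family_sweeps(fam, "control", 0, "main")[[1]]
  subs <- Filter(function(s) s$repeat_index == main$repeat_index,
                 family_sweeps(fam, "control", 0, "p4_sub"))
  corrected <- baseline_correct(p4_subtract(main, subs))
  expect_lt(max(abs(corrected$current)), 0.01)
})

test_that("P/4-corrected channel recordings match a leak-free resimulation", {
  proto <- quick_protocol(test_voltages = 0, p4_enabled = TRUE)
  p <- quick_params(g_leak = 2)
  fam <- simulate_family(proto, p)
  main <- family_sweeps(fam, "control", 0, "main")[[1]]
  subs <- Filter(function(s) s$repeat_index == main$repeat_index,
                 family_sweeps(fam, "control", 0, "p4_sub"))
  corrected <- baseline_correct(p4_subtract(main, subs))
  noleak <- quick_params(g_leak = 0)
  ref <- baseline_correct(simulate_sweep(0, noleak,
                                         protocol = quick_protocol()))
  expect_lt(max(abs(corrected$current - ref$current)), 0.05)
})

test_that("P/4 insists on exactly four matching sub-sweeps", {
  proto <- quick_protocol(test_voltages = 0, p4_enabled = TRUE)
  p <- quick_params()
  fam <- simulate_family(proto, p)
  main <- family_sweeps(fam, "control", 0, "main")[[1]]
  subs <- Filter(function(s) s$repeat_index == main$repeat_index,
                 family_sweeps(fam, "control", 0, "p4_sub"))
  expect_error(p4_subtract(main, subs[1:3]), "four")
  shifted <- subs
  shifted[[1]]$meta$step_onset <- shifted[[1]]$meta$step_onset + 1
  expect_error(p4_subtract(main, shifted), "timing")
})

test_that("baseline correction zeroes constant traces and validates its window", {
  sw <- synthetic_sweep(rep(-5, 400), dt = 0.05, onset = 10)
  corrected <- baseline_correct(sw)
  expect_true(all(corrected$current == 0))
  expect_equal(corrected$meta$baseline_offset, -5)

  zero <- synthetic_sweep(c(rep(0, 200), rep(-3, 200)), dt = 0.05, onset = 10)
  expect_equal(baseline_correct(zero)$current, zero$current)
  expect_error(baseline_correct(sw, window = c(8, 12)), "overlaps the step")
  expect_error(baseline_correct(sw, window = c(9.9, 10)), "10 samples")
})
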