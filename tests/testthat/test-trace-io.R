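fixture_family <- function(seed = 3, p4 = FALSE, capacitance = TRUE) {
  p <- quick_params()
  if (!capacitance) p$c_m <- 30   # placeholder; stripped below
  fam <- simulate_family(quick_protocol(test_voltages = c(-20, 0),
                                        p4_enabled = p4),
                         p, seed = seed,
                         conditions = standard_conditions(c("control", "TTX")))
  if (!capacitance) fam$membrane_capacitance <- NA_real_
  fam
}

test_that("write/read round-trips every numeric value to the double", {
  fam <- fixture_family(p4 = TRUE)
  dir <- tempfile("fam-")
  write_family(fam, dir)
  back <- read_family(dir)
  expect_equal(length(back$sweeps), length(fam$sweeps))
  for (i in seq_along(fam$sweeps)) {
    expect_identical(back$sweeps[[i]]$current, fam$sweeps[[i]]$current)
    expect_identical(back$sweeps[[i]]$time, fam$sweeps[[i]]$time)
    expect_identical(back$sweeps[[i]]$condition, fam$sweeps[[i]]$condition)
    expect_identical(back$sweeps[[i]]$role, fam$sweeps[[i]]$role)
  }
  expect_equal(back$membrane_capacitance, fam$membrane_capacitance)
  expect_equal(back$protocol$test_voltages, fam$protocol$test_voltages)
})

test_that("P/4 sub-sweeps are tagged in the container and survive reading", {
  fam <- fixture_family(p4 = TRUE)
  dir <- tempfile("fam-")
  write_family(fam, dir)
  header <- readLines(file.path(dir, "condition_control.csv"), n = 1)
  expect_match(header, "p4_sub_s1")
  back <- read_family(dir)
  roles <- vapply(back$sweeps, `[[`, character(1), "role")
  expect_equal(sum(roles == "p4_sub"), 2 * 2 * 2 * 4)
})

test_that("a missing capacitance is stored as null and blocks density math", {
  fam <- fixture_family(capacitance = FALSE)
  dir <- tempfile("fam-")
  write_family(fam, dir)
  sidecar <- jsonlite::read_json(file.path(dir, "family.json"))
  expect_null(sidecar$membrane_capacitance)
  back <- read_family(dir)
  expect_true(is.na(back$membrane_capacitance))
  expect_error(current_density(-50, back$membrane_capacitance), "positive")
})

test_that("schema violations are reported with the offending element", {
  fam <- fixture_family()
  dir <- tempfile("fam-")
  write_family(fam, dir)
  csv <- file.path(dir, "condition_control.csv")

  # sidecar voltage absent from the CSV
  d <- read.csv(csv, check.names = FALSE)
  d0 <- d[, !grepl("^v0_", names(d)), drop = FALSE]
  write.csv(d0, csv, row.names = FALSE, quote = FALSE)
  expect_error(read_family(dir), "0 mV")

  # duplicated column header
  write_family(fam, dir)
  d <- read.csv(csv, check.names = FALSE)
  dup <- cbind(d, d[, 2, drop = FALSE])
  names(dup)[ncol(dup)] <- names(d)[2]
  write.csv(dup, csv, row.names = FALSE, quote = FALSE)
  expect_error(read_family(dir), "duplicated column header")

  # non-uniform timebase
  write_family(fam, dir)
  d <- read.csv(csv, check.names = FALSE)
  d$time_ms[5] <- d$time_ms[5] + 0.004
  write.csv(d, csv, row.names = FALSE, quote = FALSE)
  expect_error(read_family(dir), "timebase")

  # missing sidecar
  unlink(file.path(dir, "family.json"))
  expect_error(read_family(dir), "sidecar")
})
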