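#' Average repeated sweeps
#'
#' Pointwise arithmetic mean of repeated sweeps from the same test voltage,
#' condition, role and timebase, used to raise the signal-to-noise ratio
#' before measurement (e.g. eight runs per current-voltage trial, or 15-30
#' consecutive sweeps for averaged drug-comparison traces).
#'
#' @param sweeps List of [nav_sweep()] objects with identical voltage, role,
#'   length and timebase.
#' @return A [nav_sweep()] with `repeat_index = NA`; `meta$n_averaged`
#'   records how many sweeps entered the mean.
#' @export
average_sweeps <- function(sweeps) {
  if (length(sweeps) < 1L) stop("need at least one sweep", call. = FALSE)
  ref <- sweeps[[1L]]
  for (s in sweeps) {
    if (!isTRUE(all.equal(s$test_voltage, ref$test_voltage)))
      stop("cannot average sweeps from different test voltages", call. = FALSE)
    if (s$role != ref$role)
      stop("cannot average sweeps with different roles", call. = FALSE)
    if (length(s$current) != length(ref$current))
      stop("cannot average sweeps of different lengths", call. = FALSE)
    if (abs(sweep_dt(s) - sweep_dt(ref)) > 1e-9)
      stop("cannot average sweeps with different timebases", call. = FALSE)
  }
  avg <- Reduce(`+`, lapply(sweeps, `[[`, "current")) / length(sweeps)
  meta <- ref$meta
  meta$n_averaged <- length(sweeps)
  nav_sweep(ref$time, avg, ref$test_voltage, condition = ref$condition,
            role = ref$role, repeat_index = NA_integer_, meta = meta)
}

#' P/4 leak and capacitance subtraction
#'
#' Reconstructs the linear (leak + capacitive) response to the main step
#' from four sub-sweeps, each elicited by a pulse of one quarter of the main
#' step amplitude, and subtracts it. Each sub-sweep is referenced to its own
#' pre-step baseline before summation, so sub-sweep holding current does not
#' contaminate the result. On a purely linear cell the corrected trace is
#' flat (equal to the main sweep's holding current) to numerical tolerance.
#'
#' @param main The main [nav_sweep()].
#' @param subsweeps List of exactly four P/4 sub-sweeps with the same
#'   timebase and step timing as `main`.
#' @return Corrected [nav_sweep()]; `meta$p4_corrected = TRUE`.
#' @export
p4_subtract <- function(main, subsweeps) {
  if (length(subsweeps) != 4L)
    stop("P/4 subtraction requires exactly four sub-sweeps", call. = FALSE)
  on <- sweep_step_onset(main)
  for (s in subsweeps) {
    if (s$role != "p4_sub")
      stop("sub-sweeps must have role 'p4_sub'", call. = FALSE)
    if (length(s$current) != length(main$current) ||
        abs(sweep_dt(s) - sweep_dt(main)) > 1e-9 ||
        abs(sweep_step_onset(s) - on) > 1e-9)
      stop("sub-sweep timing does not match the main sweep", call. = FALSE)
  }
  pre <- main$time < on
  if (!any(pre)) stop("main sweep has no pre-step samples", call. = FALSE)
  template <- 0
  for (s in subsweeps) template <- template + (s$current - mean(s$current[pre]))
  meta <- main$meta
  meta$p4_corrected <- TRUE
  nav_sweep(main$time, main$current - template, main$test_voltage,
            condition = main$condition, role = "main",
            repeat_index = main$repeat_index, meta = meta)
}

#' Baseline (holding-current) correction
#'
#' Subtracts the mean current over a pre-step window so that subsequent
#' peak and amplitude measurements are referenced to the step, not to the
#' holding current. The default window is the final 5 ms before step onset.
#'
#' @param sweep A [nav_sweep()].
#' @param window Length-2 numeric, ms interval over which to average; must
#'   lie entirely before the step onset and contain at least 10 samples.
#' @return Corrected sweep; the subtracted offset is stored in
#'   `meta$baseline_offset`.
#' @export
baseline_correct <- function(sweep, window = NULL) {
  on <- sweep_step_onset(sweep)
  if (is.null(window)) window <- c(max(0, on - 5), on)
  if (length(window) != 2L || window[1] >= window[2])
    stop("window must be an increasing length-2 interval", call. = FALSE)
  if (window[2] > on + 1e-9)
    stop("baseline window overlaps the step", call. = FALSE)
  idx <- sweep$time >= window[1] & sweep$time < window[2]
  if (sum(idx) < 10L)
    stop("baseline window must contain at least 10 samples", call. = FALSE)
  offset <- mean(sweep$current[idx])
  meta <- sweep$meta
  meta$baseline_offset <- offset
  nav_sweep(sweep$time, sweep$current - offset, sweep$test_voltage,
            condition = sweep$condition, role = sweep$role,
            repeat_index = sweep$repeat_index, meta = meta)
}

#' Preprocess a sweep family into one measurement-ready trace per
#' condition and voltage
#'
#' Applies, in order: P/4 subtraction per repeat (when sub-sweeps are
#' present), averaging across repeats, and baseline correction. The result
#' is a family holding exactly one `main` sweep per condition x voltage.
#'
#' @param family A [sweep_family()].
#' @param baseline_window Optional window passed to [baseline_correct()].
#' @return A preprocessed [sweep_family()].
#' @export
preprocess_family <- function(family, baseline_window = NULL) {
  out <- list()
  conds <- unique(vapply(family$sweeps, function(s) s$condition, character(1)))
  for (cond in conds) {
    for (v in family$protocol$test_voltages) {
      mains <- family_sweeps(family, condition = cond, test_voltage = v,
                             role = "main")
      if (!length(mains)) next
      subs <- family_sweeps(family, condition = cond, test_voltage = v,
                            role = "p4_sub")
      if (length(subs)) {
        mains <- lapply(mains, function(m) {
          mine <- Filter(function(s) identical(s$repeat_index, m$repeat_index),
                         subs)
          if (length(mine) == 4L) p4_subtract(m, mine) else m
        })
      }
      avg <- average_sweeps(mains)
      out[[length(out) + 1L]] <- baseline_correct(avg, baseline_window)
    }
  }
  sweep_family(out, family$protocol, cell_id = family$cell_id,
               membrane_capacitance = family$membrane_capacitance,
               provenance = c(family$provenance, list(preprocessed = TRUE)))
}
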