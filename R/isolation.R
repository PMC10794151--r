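#' Point-by-point subtraction of drug from control traces
#'
#' Isolates the drug-sensitive current component: the trace recorded in the
#' presence of a blocker is subtracted, sample by sample, from the control
#' trace at the same test voltage (e.g. control - TTX gives the
#' TTX-sensitive current; control - ProTx II gives the ProTx II-sensitive,
#' i.e. Nav1.7, current). Both traces should be baseline-corrected first.
#'
#' @param control,drug [nav_sweep()] objects at the same voltage and
#'   timebase.
#' @param label Condition label for the difference trace.
#' @return A [nav_sweep()] holding the sensitive component.
#' @export
subtract_traces <- function(control, drug, label = "sensitive") {
  if (!isTRUE(all.equal(control$test_voltage, drug$test_voltage)))
    stop("control and drug sweeps have different test voltages", call. = FALSE)
  if (length(control$current) != length(drug$current) ||
      abs(sweep_dt(control) - sweep_dt(drug)) > 1e-9)
    stop("control and drug sweeps have different timebases", call. = FALSE)
  nav_sweep(control$time, control$current - drug$current,
            control$test_voltage, condition = label, role = "main",
            repeat_index = NA_integer_, meta = control$meta)
}

#' Peak current amplitude within a search window
#'
#' Finds the extremum of largest magnitude within the search window
#' (default: step onset to 10 ms after onset, which covers all observed
#' times to peak while excluding offset transients). Inward currents are
#' negative, so a typical sodium-current peak is the window minimum.
#'
#' @param sweep A baseline-corrected [nav_sweep()].
#' @param search_window Length-2 ms interval; defaults to
#'   `c(onset, onset + 10)` clipped to the step.
#' @return List with `peak` (signed pA), `t_peak` (ms), and `no_peak`
#'   (`TRUE` when the trace is identically zero in the window, in which case
#'   `t_peak` is the window start).
#' @export
peak_amplitude <- function(sweep, search_window = NULL) {
  on <- sweep_step_onset(sweep)
  dur <- sweep$meta$step_duration
  if (is.null(search_window))
    search_window <- c(on, on + min(10, if (is.null(dur)) 10 else dur))
  if (search_window[1] < on - 1e-9 ||
      (!is.null(dur) && search_window[2] > on + dur + 1e-9))
    stop("search window must lie within the test step", call. = FALSE)
  idx <- which(sweep$time >= search_window[1] - 1e-9 &
               sweep$time <= search_window[2] + 1e-9)
  if (!length(idx)) stop("empty search window", call. = FALSE)
  seg <- sweep$current[idx]
  if (all(seg == 0)) {
    return(list(peak = 0, t_peak = search_window[1], no_peak = TRUE))
  }
  k <- idx[which.max(abs(seg))]
  list(peak = sweep$current[k], t_peak = sweep$time[k], no_peak = FALSE)
}

#' Persistent (slow-inactivating) current
#'
#' Mean current over a +/-0.25 ms window centred `at` ms after step onset
#' (default 10 ms), measured on the control trace. Fast-inactivating
#' components have decayed by then, so this isolates the
#' slow/non-inactivating fraction.
#'
#' @param control A [nav_sweep()].
#' @param at Time after step onset (ms); must not exceed the step duration.
#' @param halfwidth Averaging half-window (ms).
#' @return Persistent current in pA (signed).
#' @export
persistent_current <- function(control, at = 10, halfwidth = 0.25) {
  on <- sweep_step_onset(control)
  dur <- control$meta$step_duration
  if (!is.null(dur) && at > dur)
    stop("persistent-current time point exceeds the step duration", call. = FALSE)
  idx <- control$time >= on + at - halfwidth & control$time <= on + at + halfwidth
  if (!any(idx)) stop("no samples in the persistent-current window", call. = FALSE)
  mean(control$current[idx])
}

#' Percent inhibition of the peak current by a blocker
#'
#' `100 * (|peak_control| - |peak_drug|) / |peak_control|`, the convention
#' used for reporting block by TTX or ProTx II at the control trace's peak
#' voltage. The raw value can be negative when the drug trace is larger
#' (noise); callers wanting the clipped \[0, 100\] convention can use
#' `clip = TRUE`, in which case the raw value is attached as an attribute.
#'
#' @param peak_control,peak_drug Signed peak amplitudes (pA);
#'   `|peak_control|` must be positive.
#' @param clip Clip the reported value into \[0, 100\].
#' @return Percent inhibition.
#' @export
percent_inhibition <- function(peak_control, peak_drug, clip = FALSE) {
  if (abs(peak_control) <= 0)
    stop("control peak magnitude must be positive", call. = FALSE)
  raw <- 100 * (abs(peak_control) - abs(peak_drug)) / abs(peak_control)
  if (!clip) return(raw)
  out <- min(100, max(0, raw))
  attr(out, "raw") <- raw
  out
}

#' Isolate a drug-sensitive component and summarise it at one voltage
#'
#' Convenience wrapper around [subtract_traces()], [peak_amplitude()] and
#' [persistent_current()] for a preprocessed family: returns the sensitive
#' trace at `test_voltage` together with control/drug/sensitive peaks,
#' persistent current and percent inhibition.
#'
#' @param family A preprocessed [sweep_family()] (one sweep per
#'   condition x voltage).
#' @param control,drug Condition labels.
#' @param test_voltage Voltage at which to summarise (mV).
#' @param label Label for the sensitive component.
#' @return List of class `isolation_result`.
#' @export
isolate_component <- function(family, control = "control", drug = "TTX",
                              test_voltage = 0, label = paste0(drug, "-S")) {
  ctl <- family_sweeps(family, condition = control, test_voltage = test_voltage,
                       role = "main")
  drg <- family_sweeps(family, condition = drug, test_voltage = test_voltage,
                       role = "main")
  if (length(ctl) != 1L || length(drg) != 1L)
    stop("family must hold exactly one preprocessed sweep per condition at ",
         test_voltage, " mV", call. = FALSE)
  sens <- subtract_traces(ctl[[1]], drg[[1]], label = label)
  pc <- peak_amplitude(ctl[[1]]); pd <- peak_amplitude(drg[[1]])
  ps <- peak_amplitude(sens)
  structure(list(
    sensitive_trace = sens,
    peak_control = pc$peak, peak_drug = pd$peak, peak_sensitive = ps$peak,
    t_peak_sensitive = ps$t_peak,
    persistent_control = persistent_current(ctl[[1]]),
    percent_inhibition = percent_inhibition(pc$peak, pd$peak),
    test_voltage = test_voltage
  ), class = "isolation_result")
}

#' @export
print.isolation_result <- function(x, ...) {
  cat(sprintf("<isolation_result> %s at %g mV\n", x$sensitive_trace$condition,
              x$test_voltage))
  cat(sprintf("  peaks (pA): control %.1f, drug %.1f, sensitive %.1f\n",
              x$peak_control, x$peak_drug, x$peak_sensitive))
  cat(sprintf("  persistent (10 ms, control): %.1f pA; inhibition %.1f%%\n",
              x$persistent_control, x$percent_inhibition))
  invisible(x)
}
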