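#' A single voltage-clamp sweep
#'
#' The universal currency of the pipeline: a uniformly sampled current trace
#' with its test voltage and bookkeeping metadata. Time is in ms, current in
#' pA (inward negative), voltage in mV.
#'
#' @param time Uniformly spaced time vector (ms).
#' @param current Current vector (pA), same length as `time`.
#' @param test_voltage Test (step) voltage of the sweep (mV).
#' @param condition Condition label, e.g. `"control"`, `"TTX"`, `"ProTxII"`.
#' @param role `"main"` for test sweeps, `"p4_sub"` for P/4 sub-sweeps.
#' @param repeat_index Integer repeat number, or `NA` after averaging.
#' @param meta Named list of additional metadata (step timing, offsets, ...).
#' @return An object of class `nav_sweep`.
#' @export
nav_sweep <- function(time, current, test_voltage,
                      condition = "control", role = c("main", "p4_sub"),
                      repeat_index = NA_integer_, meta = list()) {
  role <- match.arg(role)
  if (length(time) != length(current))
    stop("time and current must have equal length", call. = FALSE)
  if (length(time) < 2L)
    stop("a sweep needs at least two samples", call. = FALSE)
  if (!all(is.finite(time)) || !all(is.finite(current)))
    stop("sweep values must be finite", call. = FALSE)
  dt <- diff(time)
  if (any(abs(dt - dt[1]) > 1e-6 * abs(dt[1])))
    stop("sweep sampling interval is not uniform", call. = FALSE)
  structure(list(time = as.numeric(time), current = as.numeric(current),
                 test_voltage = test_voltage, condition = condition,
                 role = role, repeat_index = repeat_index, meta = meta),
            class = "nav_sweep")
}

#' @export
print.nav_sweep <- function(x, ...) {
  cat(sprintf("<nav_sweep> %s, %g mV, role %s, %d samples @ %.0f kHz, repeat %s\n",
              x$condition, x$test_voltage, x$role, length(x$time),
              1 / diff(x$time[1:2]), as.character(x$repeat_index)))
  invisible(x)
}

sweep_dt <- function(sweep) diff(sweep$time[1:2])

sweep_step_onset <- function(sweep) {
  on <- sweep$meta$step_onset
  if (is.null(on)) stop("sweep has no recorded step onset", call. = FALSE)
  on
}

#' A family of sweeps sharing one protocol and one cell
#'
#' @param sweeps List of [nav_sweep()] objects; every `test_voltage` must be
#'   one of `protocol$test_voltages` (P/4 sub-sweeps are tagged with the main
#'   step's test voltage).
#' @param protocol The [step_protocol()] the sweeps were acquired under.
#' @param cell_id Character cell identifier.
#' @param membrane_capacitance Membrane capacitance in pF, or `NA` when not
#'   recorded (density operations then refuse to run).
#' @param provenance List describing origin; for simulated families contains
#'   `type = "simulated"` and a hash of the true parameters.
#' @return An object of class `sweep_family`.
#' @export
sweep_family <- function(sweeps, protocol, cell_id = "cell",
                         membrane_capacitance = NA_real_,
                         provenance = list(type = "recorded")) {
  if (!inherits(protocol, "step_protocol")) stop("protocol must be a step_protocol")
  vs <- vapply(sweeps, function(s) s$test_voltage, numeric(1))
  if (!all(vs %in% protocol$test_voltages))
    stop("sweep test voltages must belong to the protocol", call. = FALSE)
  if (!is.na(membrane_capacitance) && membrane_capacitance <= 0)
    stop("membrane_capacitance must be positive when present", call. = FALSE)
  structure(list(sweeps = sweeps, protocol = protocol, cell_id = cell_id,
                 membrane_capacitance = membrane_capacitance,
                 provenance = provenance),
            class = "sweep_family")
}

#' @export
print.sweep_family <- function(x, ...) {
  conds <- unique(vapply(x$sweeps, function(s) s$condition, character(1)))
  cat(sprintf("<sweep_family> cell %s: %d sweeps, conditions {%s}, C_m %s pF, %s\n",
              x$cell_id, length(x$sweeps), paste(conds, collapse = ", "),
              ifelse(is.na(x$membrane_capacitance), "NA",
                     format(x$membrane_capacitance)),
              x$provenance$type))
  print(x$protocol)
  invisible(x)
}

#' Select sweeps from a family
#'
#' @param family A [sweep_family()].
#' @param condition,test_voltage,role Optional filters; `NULL` keeps all.
#' @return List of matching `nav_sweep` objects.
#' @export
family_sweeps <- function(family, condition = NULL, test_voltage = NULL,
                          role = NULL) {
  keep <- vapply(family$sweeps, function(s) {
    (is.null(condition) || s$condition %in% condition) &&
      (is.null(test_voltage) || isTRUE(all.equal(s$test_voltage, test_voltage))) &&
      (is.null(role) || s$role %in% role)
  }, logical(1))
  family$sweeps[keep]
}
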