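# Sweep-family container format: one wide CSV per condition (column 1 =
# time_ms; one column per voltage x repeat x role, headers encoding all
# three) plus a JSON sidecar holding the protocol, condition list, cell
# capacitance and provenance. Units are fixed: ms, pA, mV. Numeric content
# round-trips at full double precision (17 significant digits).

column_name <- function(sweep) {
  base <- sprintf("v%g_r%s_%s", sweep$test_voltage,
                  ifelse(is.na(sweep$repeat_index), "NA", sweep$repeat_index),
                  sweep$role)
  if (sweep$role == "p4_sub") base <- paste0(base, "_s", sweep$meta$sub_index)
  base
}

parse_column_name <- function(name) {
  m <- regmatches(name, regexec("^v(-?[0-9.]+)_r([0-9]+|NA)_(main|p4_sub)(_s([1-4]))?$",
                                name))[[1]]
  if (!length(m)) stop(sprintf("malformed sweep column header '%s'", name),
                       call. = FALSE)
  list(test_voltage = as.numeric(m[2]),
       repeat_index = if (m[3] == "NA") NA_integer_ else as.integer(m[3]),
       role = m[4],
       sub_index = if (nzchar(m[6])) as.integer(m[6]) else NULL)
}

#' Write a sweep family to disk
#'
#' Writes one wide CSV per condition (`condition_<name>.csv`; first column
#' `time_ms`, one column per voltage x repeat x role) and a
#' `family.json` sidecar with the protocol, condition list, capacitance
#' and provenance, into a directory. All numbers are written with 17
#' significant digits so that [read_family()] round-trips losslessly.
#'
#' @param family A [sweep_family()].
#' @param path Directory to write into (created if absent).
#' @return `path`, invisibly.
#' @export
write_family <- function(family, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create directory ", path, call. = FALSE)
  conds <- unique(vapply(family$sweeps, function(s) s$condition, character(1)))
  fmt <- function(x) sprintf("%.17g", x)
  for (cond in conds) {
    sweeps <- family_sweeps(family, condition = cond)
    cols <- c(list(time_ms = fmt(sweeps[[1]]$time)),
              stats::setNames(lapply(sweeps, function(s) fmt(s$current)),
                              vapply(sweeps, column_name, character(1))))
    if (anyDuplicated(names(cols)))
      stop("duplicate sweep identity within condition ", cond, call. = FALSE)
    utils::write.csv(as.data.frame(cols, check.names = FALSE),
                     file.path(path, paste0("condition_", cond, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  sidecar <- list(
    format = "navclamp-sweep-family", version = 1L,
    units = list(time = "ms", current = "pA", voltage = "mV",
                 capacitance = "pF"),
    cell_id = family$cell_id,
    membrane_capacitance = if (is.na(family$membrane_capacitance)) NULL
                           else family$membrane_capacitance,
    conditions = as.list(conds),
    protocol = unclass(family$protocol),
    provenance = family$provenance)
  jsonlite::write_json(sidecar, file.path(path, "family.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read a sweep family from disk
#'
#' Reads the container written by [write_family()], validating the schema:
#' the sidecar must be present, every per-condition CSV must exist, column
#' headers must parse, columns must be complete (no ragged data), the
#' timebase must be uniform to a relative tolerance of 1e-6, and every
#' protocol test voltage must appear in each condition's CSV.
#'
#' @param path Directory containing `family.json` and the condition CSVs.
#' @return A [sweep_family()].
#' @export
read_family <- function(path) {
  sc_path <- file.path(path, "family.json")
  if (!file.exists(sc_path)) stop("missing sidecar family.json", call. = FALSE)
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  if (!identical(sc$format, "navclamp-sweep-family"))
    stop("not a navclamp sweep-family container", call. = FALSE)
  pr <- sc$protocol
  protocol <- step_protocol(holding = pr$holding,
                            test_voltages = as.numeric(pr$test_voltages),
                            step_onset = pr$step_onset,
                            step_duration = pr$step_duration,
                            sweep_duration = pr$sweep_duration,
                            p4_enabled = isTRUE(pr$p4_enabled),
                            p4_subholding = pr$p4_subholding,
                            n_repeats_per_voltage = pr$n_repeats_per_voltage)
  sweeps <- list()
  for (cond in sc$conditions) {
    csv <- file.path(path, paste0("condition_", cond, ".csv"))
    if (!file.exists(csv)) stop("missing condition file ", csv, call. = FALSE)
    header <- strsplit(readLines(csv, n = 1L), ",", fixed = TRUE)[[1]]
    if (anyDuplicated(header))
      stop(sprintf("duplicated column header '%s' in %s",
                   header[duplicated(header)][1], basename(csv)), call. = FALSE)
    d <- utils::read.csv(csv, check.names = FALSE)
    if (names(d)[1] != "time_ms")
      stop("first column must be time_ms in ", basename(csv), call. = FALSE)
    tm <- d[[1]]
    dt <- diff(tm)
    if (any(!is.finite(tm)) || any(abs(dt - dt[1]) > 1e-6 * abs(dt[1])))
      stop("non-uniform or non-finite timebase in ", basename(csv),
           call. = FALSE)
    seen_v <- numeric(0)
    for (nm in names(d)[-1]) {
      info <- parse_column_name(nm)
      cur <- d[[nm]]
      if (any(!is.finite(cur)))
        stop(sprintf("column '%s' in %s has missing or non-finite samples",
                     nm, basename(csv)), call. = FALSE)
      meta <- list(step_onset = protocol$step_onset,
                   step_duration = protocol$step_duration,
                   holding = if (info$role == "p4_sub") protocol$p4_subholding
                             else protocol$holding)
      if (!is.null(info$sub_index)) meta$sub_index <- info$sub_index
      sweeps[[length(sweeps) + 1L]] <-
        nav_sweep(tm, cur, info$test_voltage, condition = cond,
                  role = info$role, repeat_index = info$repeat_index,
                  meta = meta)
      if (info$role == "main") seen_v <- c(seen_v, info$test_voltage)
    }
    missing_v <- setdiff(protocol$test_voltages, seen_v)
    if (length(missing_v))
      stop(sprintf("condition '%s' lacks sweeps at %s mV", cond,
                   paste(missing_v, collapse = ", ")), call. = FALSE)
  }
  cm <- sc$membrane_capacitance
  sweep_family(sweeps, protocol, cell_id = sc$cell_id,
               membrane_capacitance = if (is.null(cm)) NA_real_ else cm,
               provenance = as.list(sc$provenance))
}
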