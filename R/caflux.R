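#' Calcium-indicator fluorescence trace
#'
#' A sampled fluorescence time series with a recorded stimulus-onset
#' frame. Times are in seconds and strictly increasing; at least two
#' pre-onset frames are required so a baseline can be formed.
#'
#' @param time Time vector (s), strictly increasing.
#' @param intensity Fluorescence intensities (arbitrary units).
#' @param stimulus_onset_index Index (1-based) of the first stimulated
#'   frame.
#' @return Object of class `fluorescence_trace`.
#' @export
fluorescence_trace <- function(time, intensity, stimulus_onset_index) {
  if (length(time) != length(intensity))
    stop("time and intensity must have equal length", call. = FALSE)
  if (is.unsorted(time, strictly = TRUE))
    stop("time must be strictly increasing", call. = FALSE)
  if (stimulus_onset_index < 3L || stimulus_onset_index > length(time))
    stop("stimulus onset must lie within the trace and leave at least two baseline frames",
         call. = FALSE)
  structure(list(time = as.numeric(time), intensity = as.numeric(intensity),
                 stimulus_onset_index = as.integer(stimulus_onset_index)),
            class = "fluorescence_trace")
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf("<fluorescence_trace> %d frames, %.3g s spacing, stimulus at frame %d (t = %g s)%s\n",
              length(x$time), diff(x$time[1:2]), x$stimulus_onset_index,
              x$time[x$stimulus_onset_index],
              if (isTRUE(attr(x, "normalized"))) " [F/F0]" else ""))
  invisible(x)
}

#' Normalise a fluorescence trace to F/F0
#'
#' Divides the trace by its baseline F0, the mean intensity over all
#' pre-onset frames, so the pre-onset mean of the normalised trace is 1
#' exactly. Scale-invariant: multiplying the raw intensities by any
#' positive constant leaves the result unchanged.
#'
#' @param trace A [fluorescence_trace()].
#' @return A `fluorescence_trace` with normalised intensities, attribute
#'   `normalized = TRUE` and the baseline stored in attribute `f0`.
#' @export
normalize_f_f0 <- function(trace) {
  pre <- seq_len(trace$stimulus_onset_index - 1L)
  f0 <- mean(trace$intensity[pre])
  if (!is.finite(f0) || f0 <= 0)
    stop("baseline mean must be positive", call. = FALSE)
  out <- fluorescence_trace(trace$time, trace$intensity / f0,
                            trace$stimulus_onset_index)
  attr(out, "normalized") <- TRUE
  attr(out, "f0") <- f0
  out
}

#' Area under the curve of a normalised transient
#'
#' Trapezoidal integral of `F/F0 - 1` over a window starting at the
#' stimulus onset (baseline-referenced, so a flat trace integrates to
#' zero). Additive over adjacent windows and invariant to rescaling the
#' raw intensities.
#'
#' @param trace A normalised trace from [normalize_f_f0()].
#' @param duration Window length (s) from `from`; the window must lie
#'   within the trace.
#' @param from Window start (s); defaults to the stimulus-onset time.
#' @param baseline Reference level subtracted before integration (the
#'   F/F0 - 1 convention; set 0 to integrate F/F0 itself).
#' @return AUC in (F/F0) x seconds.
#' @export
auc <- function(trace, duration, from = NULL, baseline = 1) {
  if (!isTRUE(attr(trace, "normalized")))
    stop("auc expects a normalised (F/F0) trace", call. = FALSE)
  if (is.null(from)) from <- trace$time[trace$stimulus_onset_index]
  to <- from + duration
  eps <- 1e-9
  if (from < trace$time[1] - eps || to > trace$time[length(trace$time)] + eps)
    stop("integration window extends beyond the trace", call. = FALSE)
  idx <- which(trace$time >= from - eps & trace$time <= to + eps)
  if (length(idx) < 2L)
    stop("integration window spans fewer than two frames", call. = FALSE)
  pracma::trapz(trace$time[idx], trace$intensity[idx] - baseline)
}

#' Read / write fluorescence traces as TSV
#'
#' Two tab-separated columns (`time_s`, `F`) plus a JSON sidecar
#' (`<path>.json`) holding the stimulus-onset index.
#'
#' @param trace A [fluorescence_trace()].
#' @param path TSV file path.
#' @return `read_fluorescence()` returns a `fluorescence_trace`;
#'   `write_fluorescence()` returns `path` invisibly.
#' @export
write_fluorescence <- function(trace, path) {
  utils::write.table(
    data.frame(time_s = sprintf("%.17g", trace$time),
               F = sprintf("%.17g", trace$intensity)),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(stimulus_onset_index = trace$stimulus_onset_index,
                            units = list(time = "s", F = "a.u.")),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fluorescence
#' @export
read_fluorescence <- function(path) {
  d <- utils::read.delim(path)
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  fluorescence_trace(d$time_s, d$F, sc$stimulus_onset_index)
}

#' Summarise a batch of fluorescence traces
#'
#' Normalises every TSV trace in a directory and reports peak F/F0 and
#' AUC per trace.
#'
#' @param dir Directory of trace TSVs written by [write_fluorescence()].
#' @param duration AUC window length (s).
#' @return Data frame with one row per trace (`file`, `f0`, `peak_f_f0`,
#'   `auc`).
#' @export
summarize_fluorescence_dir <- function(dir, duration) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  do.call(rbind, lapply(files, function(f) {
    tr <- normalize_f_f0(read_fluorescence(f))
    data.frame(file = basename(f), f0 = attr(tr, "f0"),
               peak_f_f0 = max(tr$intensity),
               auc = auc(tr, duration))
  }))
}
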