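#' Single-exponential fit to the inactivating (falling) phase
#'
#' Fits `I(t) = A * exp(-(t - t_peak)/tau) + C` from the measured peak time
#' to the end of the test step. The initial `tau` comes from the 1/e
#' crossing of the peak-referenced decay; `A` and `C` start at the peak
#' excursion and the late-trace mean.
#'
#' @param sweep A baseline-corrected [nav_sweep()] carrying step timing in
#'   its metadata (the simulator and [preprocess_family()] both record it).
#' @param search_window Optional peak-search window passed to
#'   [peak_amplitude()].
#' @return An object of class `tau_fit` with components `tau` (ms),
#'   `amplitude` and `offset` (pA), `fit_window`, `residual_rms`, `voltage`.
#' @export
fit_inactivation_tau <- function(sweep, search_window = NULL) {
  on <- sweep_step_onset(sweep)
  dur <- sweep$meta$step_duration
  if (is.null(dur)) stop("sweep metadata lacks step_duration", call. = FALSE)
  pk <- peak_amplitude(sweep, search_window)
  if (pk$no_peak) stop("no identifiable peak to fit from", call. = FALSE)
  idx <- which(sweep$time >= pk$t_peak & sweep$time <= on + dur + 1e-9)
  if (length(idx) < 20L)
    stop("fewer than 20 samples in the falling phase", call. = FALSE)
  tt <- sweep$time[idx] - pk$t_peak
  yy <- sweep$current[idx]
  C0 <- mean(yy[tt >= max(tt) * 0.9])
  A0 <- yy[1] - C0
  if (abs(A0) < .Machine$double.eps)
    stop("no decaying excursion above the late baseline", call. = FALSE)
  dec <- (yy - C0) / A0
  cross <- which(dec <= exp(-1))[1]
  tau0 <- if (is.na(cross) || cross == 1L) max(tt) / 3 else tt[cross]
  fit <- minpack.lm::nlsLM(
    yy ~ A * exp(-tt / tau) + C,
    start = list(A = A0, tau = max(tau0, 1e-3), C = C0),
    lower = c(A = -Inf, tau = 1e-4, C = -Inf),
    upper = c(A = Inf, tau = 1e4, C = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  if (cf[["tau"]] <= 2e-4 || cf[["tau"]] >= 5e3)
    warning("inactivation tau pinned near its bound", call. = FALSE)
  structure(list(tau = unname(cf[["tau"]]), amplitude = unname(cf[["A"]]),
                 offset = unname(cf[["C"]]),
                 fit_window = c(pk$t_peak, on + dur),
                 residual_rms = sqrt(mean(stats::resid(fit)^2)),
                 voltage = sweep$test_voltage, t_peak = pk$t_peak, fit = fit),
            class = "tau_fit")
}

#' @export
print.tau_fit <- function(x, ...) {
  cat(sprintf("Inactivation fit at %g mV: tau = %.3f ms (A = %.1f pA, C = %.2f pA, rms %.3g) over [%.2f, %.2f] ms\n",
              x$voltage, x$tau, x$amplitude, x$offset, x$residual_rms,
              x$fit_window[1], x$fit_window[2]))
  invisible(x)
}

#' @export
coef.tau_fit <- function(object, ...) {
  c(tau = object$tau, amplitude = object$amplitude, offset = object$offset)
}

#' @export
predict.tau_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) seq(object$fit_window[1], object$fit_window[2],
                                 length.out = 200)
       else if (is.data.frame(newdata)) newdata$time else newdata
  object$amplitude * exp(-(t - object$fit_window[1]) / object$tau) + object$offset
}

#' Time from step onset to peak current
#'
#' Interval from the voltage-step onset to the current extremum, with
#' parabolic three-point sub-sample refinement around the discrete
#' extremum (the refinement moves the value by well under one sample at
#' 100 kHz).
#'
#' @param sweep A baseline-corrected [nav_sweep()].
#' @param search_window Optional window passed to [peak_amplitude()].
#' @return Time to peak in ms.
#' @export
time_to_peak <- function(sweep, search_window = NULL) {
  on <- sweep_step_onset(sweep)
  pk <- peak_amplitude(sweep, search_window)
  if (pk$no_peak) stop("no identifiable peak", call. = FALSE)
  i <- which.min(abs(sweep$time - pk$t_peak))
  dt <- sweep_dt(sweep)
  if (i > 1L && i < length(sweep$current)) {
    y1 <- abs(sweep$current[i - 1L]); y2 <- abs(sweep$current[i])
    y3 <- abs(sweep$current[i + 1L])
    denom <- y1 - 2 * y2 + y3
    if (abs(denom) > .Machine$double.eps) {
      delta <- 0.5 * (y1 - y3) / denom
      if (abs(delta) <= 1) return(sweep$time[i] + delta * dt - on)
    }
  }
  pk$t_peak - on
}

#' Voltage dependence of inactivation kinetics
#'
#' Per-voltage single-exponential inactivation constants and times to peak
#' for a set of isolated (or control) sweeps. Voltages whose falling phase
#' cannot be fitted are omitted with a warning. A monotonicity check
#' (tau decreasing with depolarisation) is reported, not enforced.
#'
#' @param sweeps List of baseline-corrected [nav_sweep()] objects, one per
#'   voltage (e.g. the sensitive traces from [isolate_component()]), or a
#'   preprocessed [sweep_family()] together with `condition`.
#' @param condition Condition label when `sweeps` is a family.
#' @param min_peak_pA Sweeps whose peak magnitude falls below this are
#'   skipped (nothing to fit).
#' @return Data frame with columns `v`, `tau`, `time_to_peak`; attribute
#'   `tau_monotone_decreasing`.
#' @export
tau_voltage_curve <- function(sweeps, condition = "control", min_peak_pA = 1) {
  if (inherits(sweeps, "sweep_family")) {
    fam <- sweeps
    sweeps <- lapply(fam$protocol$test_voltages, function(v) {
      s <- family_sweeps(fam, condition = condition, test_voltage = v,
                         role = "main")
      if (length(s) == 1L) s[[1]] else NULL
    })
    sweeps <- Filter(Negate(is.null), sweeps)
  }
  if (length(sweeps) < 3L)
    stop("need at least three voltages with fittable falling phases",
         call. = FALSE)
  rows <- lapply(sweeps, function(s) {
    res <- tryCatch({
      pk <- peak_amplitude(s)
      if (abs(pk$peak) < min_peak_pA) stop("below fit floor")
      tf <- fit_inactivation_tau(s)
      data.frame(v = s$test_voltage, tau = tf$tau,
                 time_to_peak = time_to_peak(s))
    }, error = function(e) NULL)
    if (is.null(res))
      warning(sprintf("voltage %g mV omitted: falling phase not fittable",
                      s$test_voltage), call. = FALSE)
    res
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out) || nrow(out) < 3L)
    stop("fewer than three voltages yielded tau fits", call. = FALSE)
  out <- out[order(out$v), ]
  rownames(out) <- NULL
  attr(out, "tau_monotone_decreasing") <- !is.unsorted(rev(out$tau))
  out
}
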