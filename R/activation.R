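#' Peak current-voltage curve
#'
#' One (voltage, signed peak current) point per test voltage of a
#' preprocessed family, using [peak_amplitude()].
#'
#' @param family A preprocessed [sweep_family()] (one sweep per
#'   condition x voltage).
#' @param condition Condition label to extract.
#' @param search_window Optional window passed to [peak_amplitude()].
#' @return An object of class `iv_curve`: a data frame with columns `v`
#'   (mV) and `peak` (pA, signed), plus attributes `condition` and
#'   `n_cells_averaged`.
#' @export
build_iv <- function(family, condition = "control", search_window = NULL) {
  pts <- lapply(family$protocol$test_voltages, function(v) {
    sw <- family_sweeps(family, condition = condition, test_voltage = v,
                        role = "main")
    if (length(sw) != 1L)
      stop(sprintf("family has no unique preprocessed sweep at %g mV for '%s'",
                   v, condition), call. = FALSE)
    pk <- peak_amplitude(sw[[1]], search_window)
    data.frame(v = v, peak = pk$peak)
  })
  iv_curve(do.call(rbind, pts), condition = condition)
}

#' @rdname build_iv
#' @param points Data frame with columns `v` and `peak`; voltages must be
#'   unique (they are sorted on construction).
#' @param n_cells_averaged Number of cells averaged into the curve.
#' @export
iv_curve <- function(points, condition = "control", n_cells_averaged = 1L) {
  stopifnot(all(c("v", "peak") %in% names(points)))
  if (anyDuplicated(points$v)) stop("I-V voltages must be unique", call. = FALSE)
  points <- points[order(points$v), c("v", "peak")]
  rownames(points) <- NULL
  structure(points, class = c("iv_curve", "data.frame"),
            condition = condition, n_cells_averaged = n_cells_averaged)
}

#' @export
print.iv_curve <- function(x, ...) {
  cat(sprintf("<iv_curve> condition %s, %d voltages, peak %.1f pA at %g mV\n",
              attr(x, "condition"), nrow(x),
              x$peak[which.max(abs(x$peak))], x$v[which.max(abs(x$peak))]))
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
plot.iv_curve <- function(x, ...) {
  graphics::plot(x$v, x$peak, type = "b", pch = 16,
                 xlab = "Test voltage (mV)", ylab = "Peak current (pA)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Reversal potential by linear extrapolation of the depolarised I-V limb
#'
#' Fits a straight line through the `n_tail_points` most depolarised I-V
#' points and extrapolates to zero current. One defensible convention among
#' several; the slope and extrapolation distance are attached as attributes
#' so the extrapolation can be audited.
#'
#' @param iv An `iv_curve`.
#' @param n_tail_points Number of most-depolarised points to use (>= 2).
#' @return Estimated reversal potential (mV).
#' @export
estimate_reversal <- function(iv, n_tail_points = 3L) {
  if (n_tail_points < 2L) stop("need at least two tail points", call. = FALSE)
  if (nrow(iv) < n_tail_points)
    stop("fewer I-V points than n_tail_points", call. = FALSE)
  tail_pts <- utils::tail(iv[order(iv$v), ], n_tail_points)
  fit <- stats::lm(peak ~ v, data = tail_pts)
  b <- stats::coef(fit)
  if (abs(b[["v"]]) < .Machine$double.eps)
    stop("tail I-V slope is zero; cannot extrapolate", call. = FALSE)
  e_rev <- -b[["(Intercept)"]] / b[["v"]]
  structure(e_rev, slope = unname(b[["v"]]),
            extrapolation_mV = e_rev - max(tail_pts$v))
}

#' Nernst equilibrium potential
#'
#' `(R*T/F) * ln(c_out/c_in)` in mV, for a monovalent cation. With the
#' recording solutions used here (145 mM external / 10 mM internal Na+) the
#' sodium equilibrium potential at room temperature is about +68 mV.
#'
#' @param c_out,c_in Concentrations (mM), both positive.
#' @param temperature Absolute temperature (K).
#' @return Potential in mV.
#' @export
nernst_potential <- function(c_out, c_in, temperature = 294) {
  if (c_out <= 0 || c_in <= 0) stop("concentrations must be positive", call. = FALSE)
  R <- 8.314462618; FARADAY <- 96485.33212
  1000 * R * temperature / FARADAY * log(c_out / c_in)
}

#' Normalised chord-conductance curve
#'
#' Transforms a peak I-V curve into normalised conductance:
#' `G(V) = |peak(V)| / |V - e_rev|`, normalised by the maximum over the
#' included points. Voltages within `min_driving_force` of the reversal
#' potential are excluded, since the chord conductance diverges there.
#'
#' @param iv An `iv_curve`.
#' @param e_rev Reversal potential to use (mV) - the simulator's truth, an
#'   [estimate_reversal()] result, or a printed analysis-mode constant.
#' @param min_driving_force Minimum |V - e_rev| (mV) for inclusion.
#' @return Data frame with columns `v`, `g` (nS) and `gnorm`; attribute
#'   `e_rev_used`.
#' @export
conductance_curve <- function(iv, e_rev, min_driving_force = 5) {
  keep <- abs(iv$v - e_rev) >= min_driving_force
  if (!any(keep))
    stop("all I-V points lie within the excluded band around e_rev", call. = FALSE)
  g <- abs(iv$peak[keep]) / abs(iv$v[keep] - e_rev)
  out <- data.frame(v = iv$v[keep], g = g, gnorm = g / max(g))
  attr(out, "e_rev_used") <- e_rev
  out
}

#' Fit a Boltzmann activation curve to normalised conductance
#'
#' Least-squares fit of `G/Gmax(V) = A / (1 + exp((v_half - V)/k))` with the
#' amplitude `A` constrained to \[0.8, 1.2\] (the data are already
#' normalised; the bounded amplitude absorbs the choice of normalisation
#' point without letting the plateau drift). Initial values come from the
#' half-maximum crossing and the 10-90% rise width.
#'
#' @param gnorm Data frame with columns `v` and `gnorm` (from
#'   [conductance_curve()]), at least 4 points spanning the inflection.
#' @param weights Optional per-point weights for the least-squares fit.
#' @return An object of class `boltzmann_fit` with components
#'   `coefficients` (`v_half`, `k`, `amplitude`), `residual_rms`,
#'   `covariance`, `data`, `e_rev_used`, and `pinned` (flag set when a
#'   parameter sits on its bound).
#' @export
fit_boltzmann <- function(gnorm, weights = NULL) {
  stopifnot(all(c("v", "gnorm") %in% names(gnorm)))
  d <- gnorm[order(gnorm$v), ]
  if (nrow(d) < 4L) stop("need at least four points to fit", call. = FALSE)
  if (max(d$gnorm) < 0.5 || min(d$gnorm) > 0.5)
    stop("points must span both sides of the half-maximum", call. = FALSE)
  # initial guesses: half-maximum crossing and 10-90% rise width
  v_half0 <- stats::approx(d$gnorm, d$v, xout = 0.5, ties = "ordered")$y
  v10 <- tryCatch(stats::approx(d$gnorm, d$v, xout = 0.1, ties = "ordered")$y,
                  error = function(e) NA)
  v90 <- tryCatch(stats::approx(d$gnorm, d$v, xout = 0.9, ties = "ordered")$y,
                  error = function(e) NA)
  k0 <- if (is.finite(v10) && is.finite(v90) && v90 > v10)
    (v90 - v10) / (2 * log(9)) else diff(range(d$v)) / 8
  if (is.null(weights)) weights <- rep(1, nrow(d))
  fit <- minpack.lm::nlsLM(
    gnorm ~ A / (1 + exp((v_half - v) / k)),
    data = d, weights = weights,
    start = list(v_half = v_half0, k = max(k0, 0.5), A = 1),
    lower = c(v_half = -Inf, k = 1e-3, A = 0.8),
    upper = c(v_half = Inf, k = Inf, A = 1.2),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  pinned <- cf[["A"]] <= 0.8 + 1e-8 || cf[["A"]] >= 1.2 - 1e-8 ||
    cf[["k"]] <= 1e-3 + 1e-8
  if (pinned)
    warning("Boltzmann fit parameter pinned at its bound", call. = FALSE)
  res <- stats::resid(fit)
  structure(list(
    coefficients = c(v_half = unname(cf[["v_half"]]), k = unname(cf[["k"]]),
                     amplitude = unname(cf[["A"]])),
    residual_rms = sqrt(mean(res^2)),
    covariance = tryCatch(stats::vcov(fit), error = function(e) NULL),
    data = d, e_rev_used = attr(gnorm, "e_rev_used", exact = TRUE),
    pinned = pinned, fit = fit
  ), class = "boltzmann_fit")
}

#' @export
coef.boltzmann_fit <- function(object, ...) object$coefficients

#' @export
print.boltzmann_fit <- function(x, ...) {
  cf <- x$coefficients
  cat("Boltzmann activation fit: G/Gmax = A / (1 + exp((V1/2 - V)/k))\n")
  cat(sprintf("  V1/2 = %.2f mV, k = %.2f mV, A = %.3f\n",
              cf["v_half"], cf["k"], cf["amplitude"]))
  cat(sprintf("  residual rms = %.4g over %d points%s\n", x$residual_rms,
              nrow(x$data), if (x$pinned) " [parameter at bound]" else ""))
  invisible(x)
}

#' @export
summary.boltzmann_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$covariance)) {
    se <- sqrt(diag(object$covariance))
    cat(sprintf("  approx. s.e.: V1/2 %.3f, k %.3f, A %.3f\n",
                se[1], se[2], se[3]))
  }
  invisible(object)
}

#' @export
predict.boltzmann_fit <- function(object, newdata = NULL, ...) {
  v <- if (is.null(newdata)) object$data$v
       else if (is.data.frame(newdata)) newdata$v else newdata
  cf <- object$coefficients
  cf["amplitude"] / (1 + exp((cf["v_half"] - v) / cf["k"]))
}

#' @export
residuals.boltzmann_fit <- function(object, ...) {
  object$data$gnorm - predict(object)
}

#' @export
plot.boltzmann_fit <- function(x, ...) {
  graphics::plot(x$data$v, x$data$gnorm, pch = 16,
                 xlab = "Test voltage (mV)", ylab = "G/Gmax", ...)
  vv <- seq(min(x$data$v), max(x$data$v), length.out = 200)
  graphics::lines(vv, predict(x, vv))
  graphics::abline(h = 0.5, v = x$coefficients["v_half"], lty = 3)
  invisible(x)
}

#' Activation threshold voltage
#'
#' The most hyperpolarised test voltage whose peak magnitude meets the
#' detection criterion (default 5 pA, about 2.5x the default recording
#' noise).
#'
#' @param iv An `iv_curve`.
#' @param criterion_pA Detection criterion (pA).
#' @return Threshold voltage (mV), or `NA` if no point qualifies.
#' @export
activation_threshold <- function(iv, criterion_pA = 5) {
  hit <- abs(iv$peak) >= criterion_pA & abs(iv$peak) > 0
  if (!any(hit)) return(NA_real_)
  min(iv$v[hit])
}
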