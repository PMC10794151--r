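#' Current density
#'
#' Peak current magnitude normalised by membrane capacitance, in pA/pF.
#'
#' @param peak Peak current (pA; sign is ignored).
#' @param c_m Membrane capacitance (pF), positive.
#' @return Current density (pA/pF).
#' @export
current_density <- function(peak, c_m) {
  if (!is.finite(c_m) || c_m <= 0)
    stop("membrane capacitance must be positive", call. = FALSE)
  abs(peak) / c_m
}

#' Chord-conductance density
#'
#' Converts a current density into a conductance density at a given test
#' voltage and reversal potential:
#' `1000 * cd / |v_test - e_rev|` (pA/pF per mV, scaled to pS/pF).
#'
#' @param cd Current density (pA/pF).
#' @param v_test Test voltage (mV).
#' @param e_rev Reversal potential (mV); must differ from `v_test`.
#' @return Conductance density (pS/pF).
#' @export
conductance_density <- function(cd, v_test, e_rev) {
  if (v_test == e_rev)
    stop("test voltage equals the reversal potential", call. = FALSE)
  1000 * cd / abs(v_test - e_rev)
}

#' Channel density from single-channel constants
#'
#' Converts a macroscopic conductance density into channel counts using a
#' cited single-channel conductance and open probability:
#' `channels_per_pF = gd / (gamma * p_open)`, and
#' `channels_per_um2 = channels_per_pF * specific_capacitance`. The
#' specific capacitance default is the textbook 1 uF/cm^2 = 0.01 pF/um^2.
#'
#' @param gd Conductance density (pS/pF).
#' @param gamma Single-channel conductance (pS), positive.
#' @param p_open Open probability at the test voltage, in (0, 1].
#' @param specific_capacitance pF per um^2.
#' @return List with `channels_per_pF`, `channels_per_um2` (unrounded) and
#'   `channels_per_um2_rounded` (2 decimals, the convention used when
#'   quoting per-cell counts).
#' @export
channel_density <- function(gd, gamma = 6.4, p_open,
                            specific_capacitance = 0.01) {
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  if (p_open <= 0 || p_open > 1) stop("p_open must lie in (0, 1]", call. = FALSE)
  per_pf <- gd / (gamma * p_open)
  per_um2 <- per_pf * specific_capacitance
  list(channels_per_pF = per_pf, channels_per_um2 = per_um2,
       channels_per_um2_rounded = round(per_um2, 2))
}

#' Channels per cell
#'
#' Multiplies an areal channel density by a nominal cell surface area. The
#' default area of 3500 um^2 is a reconstruction chosen so that densities
#' of 0.10 and 0.15 channels/um^2 correspond to 350 and 525 channels per
#' cell; it is not a measurement.
#'
#' @param density_um2 Channel density (1/um^2); by convention the 2-decimal
#'   rounded value when reproducing printed derivations.
#' @param cell_area Cell surface area (um^2).
#' @return Channel count, rounded to the nearest integer; the unrounded
#'   product is attached as attribute `unrounded`.
#' @export
channels_per_cell <- function(density_um2, cell_area = 3500) {
  if (density_um2 < 0) stop("density must be non-negative", call. = FALSE)
  structure(round(density_um2 * cell_area),
            unrounded = density_um2 * cell_area)
}

#' Full printed-arithmetic channel-density chain
#'
#' Runs the complete derivation from a current density to channels per
#' cell in one call: conductance density, channels per pF/um^2 (2-decimal
#' rounding), and channels per cell. Used to reproduce printed derivations
#' from their stated inputs.
#'
#' @inheritParams conductance_density
#' @inheritParams channel_density
#' @inheritParams channels_per_cell
#' @return List with every intermediate (`conductance_density`,
#'   `channels_per_pF`, `channels_per_um2`, `channels_per_um2_rounded`,
#'   `channels_per_cell`).
#' @export
channel_density_chain <- function(cd, v_test = 0, e_rev = -60.6, gamma = 6.4,
                                  p_open, specific_capacitance = 0.01,
                                  cell_area = 3500) {
  gd <- conductance_density(cd, v_test, e_rev)
  dens <- channel_density(gd, gamma, p_open, specific_capacitance)
  npc <- channels_per_cell(dens$channels_per_um2_rounded, cell_area)
  c(list(conductance_density = gd), dens,
    list(channels_per_cell = as.integer(npc),
         channels_per_cell_unrounded = attr(npc, "unrounded")))
}

#' Responder classification
#'
#' A cell is a responder when it shows an inward current with peak
#' magnitude strictly above the threshold (30 pA) *and* a fast-inactivating
#' component: a fitted millisecond-scale inactivation constant at 0 mV at
#' or below the fast cutoff. A missing tau (no fittable falling phase)
#' means non-responder.
#'
#' @param peak Peak current magnitude at 0 mV (pA).
#' @param tau_at_0mV Fitted inactivation tau at 0 mV (ms), or `NA`.
#' @param peak_threshold Strict threshold on the peak magnitude (pA).
#' @param tau_fast_cutoff Maximum tau still counted as fast (ms).
#' @return Logical.
#' @export
classify_responder <- function(peak, tau_at_0mV, peak_threshold = 30,
                               tau_fast_cutoff = 5) {
  isTRUE(abs(peak) > peak_threshold) &&
    isTRUE(is.finite(tau_at_0mV)) && isTRUE(tau_at_0mV <= tau_fast_cutoff)
}

#' Summarise a cohort of analysed cells
#'
#' Descriptive summary of per-cell results: responder counts and
#' percentage (rounded to the nearest integer), and responder-only
#' mean +/- s.e.m. of peak amplitude, current density, inactivation tau at
#' 0 mV and percent inhibition per drug. No hypothesis tests.
#'
#' @param cell_results List of per-cell result lists; each needs at least
#'   `peak` (pA magnitude) and `responder` (logical), and optionally
#'   `current_density`, `tau_at_0mV` and `percent_inhibition` (a named
#'   vector, one entry per drug).
#' @return An object of class `cohort_summary`.
#' @export
summarize_cohort <- function(cell_results) {
  if (length(cell_results) < 1L) stop("empty cohort", call. = FALSE)
  n <- length(cell_results)
  resp <- vapply(cell_results, function(x) isTRUE(x$responder), logical(1))
  grab <- function(field, which = resp) {
    vals <- vapply(cell_results[which], function(x) {
      v <- x[[field]]
      if (is.null(v) || !is.finite(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
    vals[is.finite(vals)]
  }
  mean_sem <- function(v) {
    if (!length(v)) return(c(mean = NA_real_, sem = NA_real_, n = 0))
    c(mean = mean(v),
      sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
      n = length(v))
  }
  drugs <- unique(unlist(lapply(cell_results, function(x)
    names(x$percent_inhibition))))
  inhib <- lapply(drugs, function(d) {
    vals <- vapply(cell_results[resp], function(x) {
      v <- x$percent_inhibition[[d]]
      if (is.null(v) || !is.finite(v)) NA_real_ else v
    }, numeric(1))
    mean_sem(vals[is.finite(vals)])
  })
  names(inhib) <- drugs
  structure(list(
    n_cells = n, n_responders = sum(resp),
    responder_fraction = round(100 * sum(resp) / n),
    peak_amplitude = mean_sem(grab("peak")),
    current_density = mean_sem(grab("current_density")),
    tau_at_0mV = mean_sem(grab("tau_at_0mV")),
    percent_inhibition = inhib
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  fmt <- function(ms) {
    if (ms[["n"]] == 0) return("n/a")
    sem <- if (is.finite(ms[["sem"]])) sprintf(" +/- %.2f", ms[["sem"]]) else ""
    sprintf("%.2f%s (n = %d)", ms[["mean"]], sem, as.integer(ms[["n"]]))
  }
  cat(sprintf("Cohort: %d cells, %d responders (%d%%)\n", x$n_cells,
              x$n_responders, x$responder_fraction))
  cat("  responder peak amplitude (pA):  ", fmt(x$peak_amplitude), "\n")
  cat("  responder current density (pA/pF):", fmt(x$current_density), "\n")
  cat("  responder tau at 0 mV (ms):     ", fmt(x$tau_at_0mV), "\n")
  for (d in names(x$percent_inhibition))
    cat(sprintf("  %% inhibition by %s:            %s\n", d,
                fmt(x$percent_inhibition[[d]])))
  invisible(x)
}

#' Cohort summary as a per-patient style table
#'
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @return Data frame with one row (cells recorded, responders, mean peak,
#'   mean density), mirroring a per-patient summary table layout.
#' @export
as.data.frame.cohort_summary <- function(x, ...) {
  data.frame(n_cells = x$n_cells, n_responders = x$n_responders,
             responder_pct = x$responder_fraction,
             mean_peak_pA = x$peak_amplitude[["mean"]],
             mean_density_pA_pF = x$current_density[["mean"]])
}
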