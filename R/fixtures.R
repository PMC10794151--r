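#' Generate the packaged PSM-table fixture
#'
#' Builds a synthetic peptide-spectrum-match (spectral count) abundance
#' table emulating a fractionated conditioned-medium secretome screen with
#' two size-exclusion fractions (10-30 and 30-100 kDa) and three
#' conditions (vehicle, PF-04856264, ProTx II). The table plants exactly
#' six rows that pass the three-criterion candidate filter - including an
#' HSP70 row (30-100 kDa fraction) and a midkine row (10-30 kDa fraction);
#' the four other passers are synthetic placeholders - plus decoys that
#' each fail exactly one criterion (molecular weight outside both windows;
#' enrichment under only one treatment; fold change of exactly 2, which
#' the strict "more than twofold" rule excludes; not secreted) and
#' abundant non-enriched background proteins.
#'
#' @param seed Seed for the background-count jitter.
#' @return A data frame of class `psm_table` with columns `protein_id`,
#'   `gene`, `mw_kda`, `secreted`, `fraction`, `psm_vehicle`, `psm_pf`,
#'   `psm_protx`.
#' @export
generate_psm_fixture <- function(seed = 42L) {
  row <- function(id, gene, mw, secreted, fraction, v, pf, protx)
    data.frame(protein_id = id, gene = gene, mw_kda = mw,
               secreted = secreted, fraction = fraction,
               psm_vehicle = v, psm_pf = pf, psm_protx = protx)
  planted <- rbind(
    # the six intended passers
    row("P0DMV8", "HSPA1A", 70.1, TRUE, "30-100", 0L, 9L, 7L),
    row("P21741", "MDK", 15.6, TRUE, "10-30", 0L, 6L, 5L),
    row("SYN0001", "CAND1", 45.2, TRUE, "30-100", 2L, 7L, 7L),
    row("SYN0002", "CAND2", 82.4, TRUE, "30-100", 0L, 4L, 3L),
    row("SYN0003", "CAND3", 12.8, TRUE, "10-30", 3L, 10L, 8L),
    row("SYN0004", "CAND4", 24.5, TRUE, "10-30", 1L, 5L, 3L),
    # decoys, each failing exactly one criterion
    row("SYN0101", "DECMW", 8.9, TRUE, "10-30", 0L, 8L, 6L),     # MW outside windows
    row("SYN0102", "DECPF", 55.0, TRUE, "30-100", 2L, 9L, 2L),   # enriched under PF only
    row("SYN0103", "DECFOLD", 28.0, TRUE, "10-30", 3L, 6L, 6L),  # fold exactly 2.0 under PF
    row("SYN0104", "DECSEC", 40.0, FALSE, "30-100", 1L, 10L, 10L) # not secreted
  )
  set.seed(seed)
  n_bg <- 14L
  bg_counts <- stats::rpois(n_bg, 18) + 5L
  background <- do.call(rbind, lapply(seq_len(n_bg), function(i) {
    frac <- if (i %% 2 == 0) "30-100" else "10-30"
    mw <- if (frac == "30-100") stats::runif(1, 31, 99) else stats::runif(1, 11, 29)
    v <- bg_counts[i]
    row(sprintf("SYN%04d", 200 + i), sprintf("BG%02d", i), round(mw, 1),
        TRUE, frac, v,
        v + stats::rpois(1, 2) - 1L,  # ~1x, never > 2x for these counts
        v + stats::rpois(1, 2) - 1L)
  }))
  out <- rbind(planted, background)
  rownames(out) <- NULL
  class(out) <- c("psm_table", "data.frame")
  out
}

#' Generate a synthetic calcium-indicator fluorescence trace
#'
#' Emulates a plate-reader or confocal F/F0 experiment: frames at a fixed
#' interval (default 2 s), a flat baseline of `baseline_frames` frames at
#' intensity `f0`, then an agonist-evoked transient that jumps by
#' `amplitude` at the stimulus-onset frame and relaxes toward a sustained
#' plateau: `f0 + amplitude * ((1 - sustained_fraction) * exp(-s/decay_tau)
#' + sustained_fraction)`. The onset frame carries the peak exactly, so
#' with noise off the normalised peak is `1 + amplitude/f0` by
#' construction.
#'
#' @param baseline_frames Number of pre-stimulus frames (>= 2).
#' @param amplitude Transient amplitude in raw intensity units.
#' @param f0 Baseline intensity (arbitrary units).
#' @param decay_tau Decay time constant (s).
#' @param sustained_fraction Plateau level as a fraction of the amplitude.
#' @param n_after Number of post-onset frames.
#' @param frame_interval Frame spacing (s).
#' @param noise_sd Additive Gaussian noise s.d. (intensity units); applied
#'   only when `seed` is given.
#' @param seed Noise seed, or `NULL` for a noise-free trace.
#' @return A [fluorescence_trace()].
#' @export
generate_fluorescence <- function(baseline_frames = 30L, amplitude = 150,
                                  f0 = 100, decay_tau = 60,
                                  sustained_fraction = 0.25, n_after = 120L,
                                  frame_interval = 2, noise_sd = 0,
                                  seed = NULL) {
  if (baseline_frames < 2L) stop("need at least two baseline frames", call. = FALSE)
  n <- baseline_frames + n_after
  tm <- (seq_len(n) - 1L) * frame_interval
  onset <- baseline_frames + 1L
  s <- tm - tm[onset]
  shape <- ifelse(s < 0, 0,
                  (1 - sustained_fraction) * exp(-s / decay_tau) +
                    sustained_fraction)
  intensity <- f0 + amplitude * shape
  if (!is.null(seed) && noise_sd > 0) {
    set.seed(seed)
    intensity <- intensity + stats::rnorm(n, sd = noise_sd)
  }
  fluorescence_trace(tm, intensity, onset)
}
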