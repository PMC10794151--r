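#' Gating-model parameters for the voltage-clamp simulator
#'
#' Bundles every constant the step-protocol simulator needs: steady-state
#' activation/inactivation midpoints and slopes, voltage-dependent time
#' constant tables, pool conductances, reversal potentials, cell capacitance
#' and acquisition constants. Units follow patch-clamp convention throughout:
#' mV, ms, nS, pA, pF.
#'
#' The model is a Hodgkin-Huxley-style scheme with an activation gate raised
#' to the power `act_exponent` (default 3) and a single inactivation gate
#' whose relaxation rate is gated by activation (`dh/dt =
#' (h_inf - h) * m^p / tau_h`), so inactivation proceeds from activated
#' states. Three sodium conductance pools share the same gating and differ
#' only in pharmacology: `g_nav17` (blocked by both TTX and ProTx II),
#' `g_ttxs_other` (blocked by TTX only) and `g_ttxr` (TTX-resistant). An
#' optional ungated persistent conductance `g_persistent` and an ohmic leak
#' complete the membrane model.
#'
#' @param v_half_m,k_m Midpoint (mV) and slope (mV, > 0) of the steady-state
#'   activation curve `m_inf(V) = 1/(1 + exp((v_half_m - V)/k_m))`.
#' @param v_half_h,k_h Midpoint and slope (> 0) of steady-state inactivation
#'   `h_inf(V) = 1/(1 + exp((V - v_half_h)/k_h))`.
#' @param tau_m_anchors,tau_h_anchors Data frames (or 2-column matrices) with
#'   columns `v` (mV) and `tau` (ms, > 0). Time constants between anchors are
#'   interpolated linearly in `log(tau)` versus voltage and clamped at the
#'   outermost anchors.
#' @param g_nav17,g_ttxs_other,g_ttxr,g_leak,g_persistent Conductances in nS
#'   (all >= 0). `g_persistent` is an ungated, non-inactivating conductance
#'   with reversal `e_rev_sim`.
#' @param e_rev_sim Simulated sodium reversal potential (mV).
#' @param e_leak Leak reversal potential (mV).
#' @param c_m Membrane capacitance (pF).
#' @param noise_sd Additive white Gaussian noise s.d. (pA); applied only when
#'   a seed is supplied to the simulator.
#' @param sample_rate Sampling rate in Hz.
#' @param filter_cutoff Low-pass corner frequency in Hz (metadata; an optional
#'   Gaussian smoothing kernel in [simulate_sweep()] emulates it on request).
#' @param act_exponent Integer exponent on the activation gate.
#'
#' @return An object of class `gating_params` (a validated list).
#' @seealso [default_gating_params()], [simulate_sweep()], [calibrate_gating()]
#' @export
gating_params <- function(v_half_m, k_m,
                          tau_m_anchors, tau_h_anchors,
                          v_half_h = -70, k_h = 7,
                          g_nav17 = 0, g_ttxs_other = 0, g_ttxr = 0,
                          g_leak = 0, g_persistent = 0,
                          e_rev_sim = 65, e_leak = -70, c_m = 34,
                          noise_sd = 2, sample_rate = 1e5,
                          filter_cutoff = 2000, act_exponent = 3L) {
  as_anchor <- function(x, what) {
    x <- as.data.frame(x)
    if (ncol(x) < 2L) stop(what, " must have columns v and tau", call. = FALSE)
    names(x)[1:2] <- c("v", "tau")
    x <- x[order(x$v), 1:2, drop = FALSE]
    if (anyDuplicated(x$v)) stop(what, ": duplicated anchor voltages", call. = FALSE)
    x
  }
  p <- structure(list(
    v_half_m = v_half_m, k_m = k_m, v_half_h = v_half_h, k_h = k_h,
    tau_m_anchors = as_anchor(tau_m_anchors, "tau_m_anchors"),
    tau_h_anchors = as_anchor(tau_h_anchors, "tau_h_anchors"),
    g_nav17 = g_nav17, g_ttxs_other = g_ttxs_other, g_ttxr = g_ttxr,
    g_leak = g_leak, g_persistent = g_persistent,
    e_rev_sim = e_rev_sim, e_leak = e_leak, c_m = c_m,
    noise_sd = noise_sd, sample_rate = sample_rate,
    filter_cutoff = filter_cutoff, act_exponent = as.integer(act_exponent)
  ), class = "gating_params")
  validate_gating_params(p)
}

validate_gating_params <- function(p) {
  num <- unlist(p[c("v_half_m", "k_m", "v_half_h", "k_h", "g_nav17",
                    "g_ttxs_other", "g_ttxr", "g_leak", "g_persistent",
                    "e_rev_sim", "e_leak", "c_m", "noise_sd", "sample_rate",
                    "filter_cutoff")])
  if (!all(is.finite(num)))
    stop("gating_params: all numeric fields must be finite", call. = FALSE)
  if (p$k_m <= 0 || p$k_h <= 0)
    stop("gating_params: slopes k_m and k_h must be positive", call. = FALSE)
  if (any(p$tau_m_anchors$tau <= 0) || any(p$tau_h_anchors$tau <= 0))
    stop("gating_params: tau anchors must be positive", call. = FALSE)
  gs <- c(p$g_nav17, p$g_ttxs_other, p$g_ttxr, p$g_leak, p$g_persistent)
  if (any(gs < 0))
    stop("gating_params: conductances must be non-negative", call. = FALSE)
  if (p$c_m <= 0) stop("gating_params: c_m must be positive", call. = FALSE)
  if (p$noise_sd < 0) stop("gating_params: noise_sd must be >= 0", call. = FALSE)
  if (p$sample_rate <= 2 * p$filter_cutoff)
    stop("gating_params: sample_rate must exceed 2 * filter_cutoff", call. = FALSE)
  if (p$act_exponent < 1L)
    stop("gating_params: act_exponent must be >= 1", call. = FALSE)
  p
}

#' @export
print.gating_params <- function(x, ...) {
  cat("Gating model parameters\n")
  cat(sprintf("  activation : m^%d, v_half_m = %.2f mV, k_m = %.2f mV\n",
              x$act_exponent, x$v_half_m, x$k_m))
  cat(sprintf("  inactivation: v_half_h = %.1f mV, k_h = %.1f mV (coupled to m^%d)\n",
              x$v_half_h, x$k_h, x$act_exponent))
  cat(sprintf("  pools (nS) : Nav1.7 %.3f | other TTX-S %.3f | TTX-R %.3f | persistent %.3f | leak %.3f\n",
              x$g_nav17, x$g_ttxs_other, x$g_ttxr, x$g_persistent, x$g_leak))
  cat(sprintf("  reversals  : E_Na(sim) %+.1f mV, E_leak %+.1f mV; C_m %.1f pF\n",
              x$e_rev_sim, x$e_leak, x$c_m))
  cat(sprintf("  acquisition: %.0f kHz, %.1f kHz low-pass, noise sd %.1f pA\n",
              x$sample_rate / 1e3, x$filter_cutoff / 1e3, x$noise_sd))
  cat("  tau_m anchors (V, ms):",
      paste(sprintf("(%g, %.3g)", x$tau_m_anchors$v, x$tau_m_anchors$tau), collapse = " "), "\n")
  cat("  tau_h anchors (V, ms):",
      paste(sprintf("(%g, %.3g)", x$tau_h_anchors$v, x$tau_h_anchors$tau), collapse = " "), "\n")
  invisible(x)
}

#' Voltage-step protocol description
#'
#' Describes a rectangular step protocol: a holding potential, a family of
#' test voltages, step timing within the sweep, the number of repeats
#' averaged per voltage, and (optionally) a P/4 leak-subtraction scheme in
#' which each main step is accompanied by four sub-sweeps of one quarter of
#' the step amplitude delivered from `p4_subholding`.
#'
#' Defaults emulate the recording conditions the analysis targets: steps from
#' a -90 mV holding potential to -60 ... +50 mV in 10 mV increments, with
#' eight runs averaged per current-voltage trial.
#'
#' @param holding Holding potential (mV).
#' @param test_voltages Strictly increasing vector of test voltages (mV).
#' @param step_onset,step_duration,sweep_duration Step timing (ms); the step
#'   must fit inside the sweep.
#' @param p4_enabled Logical; generate P/4 sub-sweeps.
#' @param p4_subholding Sub-sweep holding potential (mV).
#' @param n_repeats_per_voltage Number of repeats per test voltage (>= 1).
#' @return An object of class `step_protocol`.
#' @export
step_protocol <- function(holding = -90,
                          test_voltages = seq(-60, 50, by = 10),
                          step_onset = 5, step_duration = 20,
                          sweep_duration = 30,
                          p4_enabled = FALSE, p4_subholding = -90,
                          n_repeats_per_voltage = 8L) {
  if (length(test_voltages) < 1L || is.unsorted(test_voltages, strictly = TRUE))
    stop("test_voltages must be strictly increasing", call. = FALSE)
  if (!(step_onset >= 0 && step_onset < step_onset + step_duration &&
        step_onset + step_duration <= sweep_duration))
    stop("step timing must satisfy 0 <= onset < onset + duration <= sweep duration",
         call. = FALSE)
  if (n_repeats_per_voltage < 1L)
    stop("n_repeats_per_voltage must be >= 1", call. = FALSE)
  structure(list(holding = holding, test_voltages = test_voltages,
                 step_onset = step_onset, step_duration = step_duration,
                 sweep_duration = sweep_duration, p4_enabled = p4_enabled,
                 p4_subholding = p4_subholding,
                 n_repeats_per_voltage = as.integer(n_repeats_per_voltage)),
            class = "step_protocol")
}

#' @export
print.step_protocol <- function(x, ...) {
  cat(sprintf("Step protocol: hold %g mV, steps %g..%g mV (%d voltages), onset %g ms, duration %g ms, sweep %g ms, %d repeats%s\n",
              x$holding, min(x$test_voltages), max(x$test_voltages),
              length(x$test_voltages), x$step_onset, x$step_duration,
              x$sweep_duration, x$n_repeats_per_voltage,
              if (x$p4_enabled) sprintf(", P/4 from %g mV", x$p4_subholding) else ""))
  invisible(x)
}

#' Pharmacological condition as pool block fractions
#'
#' A static description of a bath condition. `ttx_block_fraction` scales down
#' the TTX-sensitive pools (`g_nav17` and `g_ttxs_other`);
#' `protx_block_fraction` scales down `g_nav17` only, mirroring the
#' selectivity of 1 uM tetrodotoxin and 20 nM protoxin II respectively.
#'
#' @param ttx_block_fraction,protx_block_fraction Fractions in \[0, 1\].
#' @return An object of class `drug_state`.
#' @export
drug_state <- function(ttx_block_fraction = 0, protx_block_fraction = 0) {
  if (ttx_block_fraction < 0 || ttx_block_fraction > 1 ||
      protx_block_fraction < 0 || protx_block_fraction > 1)
    stop("block fractions must lie in [0, 1]", call. = FALSE)
  structure(list(ttx_block_fraction = ttx_block_fraction,
                 protx_block_fraction = protx_block_fraction),
            class = "drug_state")
}
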