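# shared fixtures, built in code

# cheap gating model for unit tests: coarse sampling, short sweeps
quick_params <- function(...) {
  args <- list(
    v_half_m = -20, k_m = 8,
    tau_m_anchors = data.frame(v = c(-20, 0, 50), tau = c(0.6, 0.9, 0.4)),
    tau_h_anchors = data.frame(v = c(-20, 0, 50), tau = c(0.5, 0.4, 0.15)),
    g_nav17 = 10, g_ttxs_other = 5, g_ttxr = 8, g_leak = 0.5,
    sample_rate = 2e4)
  args[names(list(...))] <- list(...)
  do.call(gating_params, args)
}

quick_protocol <- function(...) {
  step_protocol(step_onset = 2, step_duration = 12, sweep_duration = 16,
                n_repeats_per_voltage = 2L, ...)
}

# control - full-TTX subtracted traces for every protocol voltage
ttxs_traces <- function(pre) {
  lapply(pre$protocol$test_voltages, function(v)
    subtract_traces(family_sweeps(pre, "control", v, "main")[[1]],
                    family_sweeps(pre, "TTX", v, "main")[[1]], "TTX-S"))
}

# full activation chain: simulate (or take) a control+TTX family, isolate,
# build the I-V, transform to G/Gmax and fit the Boltzmann
activation_fit <- function(family, e_rev) {
  pre <- preprocess_family(family)
  sens <- ttxs_traces(pre)
  iv <- iv_curve(do.call(rbind, lapply(sens, function(s)
    data.frame(v = s$test_voltage, peak = peak_amplitude(s)$peak))),
    condition = "TTX-S")
  list(iv = iv, fit = fit_boltzmann(conductance_curve(iv, e_rev)),
       sensitive = sens)
}

# synthetic flat-baseline sweep with step metadata, for constructed traces
synthetic_sweep <- function(current, dt = 0.05, onset = 0,
                            duration = NULL, voltage = 0) {
  n <- length(current)
  if (is.null(duration)) duration <- (n - 1) * dt - onset
  nav_sweep((seq_len(n) - 1) * dt, current, voltage,
            meta = list(step_onset = onset, step_duration = duration))
}
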