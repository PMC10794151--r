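#' Analyse one cell's sweep family
#'
#' Runs the full measurement chain on a single cell: preprocessing (P/4
#' correction where sub-sweeps exist, repeat averaging, baseline
#' correction), drug-sensitive component isolation by subtraction when a
#' drug condition is present, peak and kinetic measurements at a reference
#' voltage (default 0 mV), activation analysis (peak I-V, chord
#' conductance, Boltzmann fit, activation threshold) when the family spans
#' at least four voltages, current density when the capacitance is known,
#' and responder classification.
#'
#' @param family A [sweep_family()].
#' @param control Condition label of the control recording.
#' @param drugs Character vector of drug condition labels to use for
#'   subtraction; defaults to every non-control condition present.
#' @param e_rev Reversal potential (mV) for the conductance transform;
#'   `NULL` estimates it from the sensitive I-V curve
#'   ([estimate_reversal()]).
#' @param measure_voltage Voltage at which peaks, tau and time-to-peak are
#'   measured (mV).
#' @return An object of class `cell_result`.
#' @export
analyze_cell <- function(family, control = "control", drugs = NULL,
                         e_rev = NULL, measure_voltage = 0) {
  pre <- preprocess_family(family)
  conds <- unique(vapply(pre$sweeps, function(s) s$condition, character(1)))
  if (!control %in% conds)
    stop("control condition '", control, "' not present", call. = FALSE)
  if (is.null(drugs)) drugs <- setdiff(conds, control)

  ctl0 <- family_sweeps(pre, control, measure_voltage, "main")
  if (length(ctl0) != 1L)
    stop("no control sweep at the measurement voltage", call. = FALSE)
  ctl0 <- ctl0[[1]]
  pk <- peak_amplitude(ctl0)

  iso <- lapply(drugs, function(d)
    tryCatch(isolate_component(pre, control, d, measure_voltage,
                               label = paste0(d, "-S")),
             error = function(e) NULL))
  names(iso) <- drugs
  iso <- Filter(Negate(is.null), iso)

  # kinetics at the measurement voltage: prefer the first isolated
  # component (cleanest trace), fall back to control
  kin_trace <- if (length(iso)) iso[[1]]$sensitive_trace else ctl0
  tau0 <- tryCatch(fit_inactivation_tau(kin_trace)$tau,
                   error = function(e) NA_real_)
  ttp0 <- tryCatch(time_to_peak(kin_trace), error = function(e) NA_real_)

  activation <- NULL
  if (length(family$protocol$test_voltages) >= 4L) {
    act_sweeps <- if (length(iso)) {
      lapply(family$protocol$test_voltages, function(v)
        subtract_traces(family_sweeps(pre, control, v, "main")[[1]],
                        family_sweeps(pre, names(iso)[1], v, "main")[[1]],
                        label = paste0(names(iso)[1], "-S")))
    } else {
      lapply(family$protocol$test_voltages, function(v)
        family_sweeps(pre, control, v, "main")[[1]])
    }
    iv <- iv_curve(do.call(rbind, lapply(act_sweeps, function(s)
      data.frame(v = s$test_voltage, peak = peak_amplitude(s)$peak))),
      condition = if (length(iso)) paste0(names(iso)[1], "-S") else control)
    e_used <- if (is.null(e_rev)) as.numeric(estimate_reversal(iv)) else e_rev
    bf <- tryCatch(fit_boltzmann(conductance_curve(iv, e_used)),
                   error = function(e) NULL)
    activation <- list(iv = iv, e_rev_used = e_used, boltzmann = bf,
                       threshold = activation_threshold(iv),
                       tau_curve = tryCatch(tau_voltage_curve(act_sweeps),
                                            error = function(e) NULL))
  }

  cd <- if (!is.na(family$membrane_capacitance))
    current_density(pk$peak, family$membrane_capacitance) else NA_real_

  structure(list(
    cell_id = family$cell_id,
    peak = abs(pk$peak), peak_signed = pk$peak,
    t_peak = pk$t_peak, tau_at_0mV = tau0, time_to_peak = ttp0,
    persistent = tryCatch(persistent_current(ctl0), error = function(e) NA_real_),
    percent_inhibition = vapply(iso, `[[`, numeric(1), "percent_inhibition"),
    current_density = cd,
    membrane_capacitance = family$membrane_capacitance,
    responder = classify_responder(pk$peak, tau0),
    activation = activation,
    measure_voltage = measure_voltage
  ), class = "cell_result")
}

#' @export
print.cell_result <- function(x, ...) {
  cat(sprintf("<cell_result> %s @ %g mV: peak %.1f pA (density %s pA/pF), tau %.3g ms, ttp %.3g ms, %s\n",
              x$cell_id, x$measure_voltage, x$peak,
              ifelse(is.na(x$current_density), "NA",
                     sprintf("%.2f", x$current_density)),
              x$tau_at_0mV, x$time_to_peak,
              if (isTRUE(x$responder)) "responder" else "non-responder"))
  for (d in names(x$percent_inhibition))
    cat(sprintf("  inhibition by %s: %.1f%%\n", d, x$percent_inhibition[[d]]))
  if (!is.null(x$activation) && !is.null(x$activation$boltzmann)) {
    cf <- coef(x$activation$boltzmann)
    cat(sprintf("  activation: V1/2 %.2f mV, k %.2f mV (E_rev %.1f mV), threshold %g mV\n",
                cf["v_half"], cf["k"], x$activation$e_rev_used,
                x$activation$threshold))
  }
  invisible(x)
}

#' Generate a simulated cohort of cells
#'
#' Builds `n_cells` sweep families from the calibrated default gating
#' model, rescaled per cell so that exactly `n_responders` cells carry a
#' fast-inactivating current with control peak magnitude strictly above
#' the 30 pA responder threshold, while the remaining cells stay safely
#' below it. Responder amplitudes are drawn from a log-normal centred
#' around 80 pA (clipped to `amplitude_range`); non-responder amplitudes
#' are uniform on `nonresponder_range`. Per-cell capacitance is uniform on
#' `c_m_range`. Each family is recorded at the measurement voltage (0 mV)
#' under control and TTX, with P/4 sub-sweeps and repeat averaging, with
#' recording noise.
#'
#' @param n_cells,n_responders Cohort composition (`n_responders <=
#'   n_cells`).
#' @param amplitude_range Responder control-peak range (pA); the lower
#'   bound must exceed the 30 pA classification boundary so that recording
#'   noise cannot flip labels.
#' @param nonresponder_range Non-responder control-peak range (pA); upper
#'   bound must stay below 30 pA.
#' @param c_m_range Capacitance range (pF).
#' @param seed Master seed for the cohort (amplitude draws and recording
#'   noise).
#' @param protocol Acquisition protocol; default records 0 mV steps with
#'   eight repeats and P/4 sub-sweeps.
#' @param conditions Conditions to record (default control and TTX).
#' @return List of [sweep_family()] objects; each family's provenance
#'   records the intended (`truth_responder`) label and scale factor.
#' @export
generate_cohort <- function(n_cells = 77L, n_responders = 13L,
                            amplitude_range = c(40, 250),
                            nonresponder_range = c(2, 20),
                            c_m_range = c(25, 45),
                            seed = 1L,
                            protocol = step_protocol(test_voltages = 0,
                                                     p4_enabled = TRUE),
                            conditions = standard_conditions(c("control", "TTX"))) {
  if (n_responders > n_cells)
    stop("n_responders must not exceed n_cells", call. = FALSE)
  if (amplitude_range[1] <= 30)
    stop("responder amplitude_range must start above the 30 pA boundary",
         call. = FALSE)
  if (nonresponder_range[2] >= 30)
    stop("nonresponder_range must stay below the 30 pA boundary", call. = FALSE)

  base <- default_gating_params()
  ref <- baseline_correct(simulate_sweep(0, base, protocol = step_protocol()))
  base_peak <- abs(peak_amplitude(ref)$peak)

  set.seed(derive_seed(seed, 0L))
  resp_amp <- pmin(pmax(stats::rlnorm(n_responders, log(80), 0.4),
                        amplitude_range[1]), amplitude_range[2])
  nonresp_amp <- stats::runif(n_cells - n_responders,
                              nonresponder_range[1], nonresponder_range[2])
  amps <- c(resp_amp, nonresp_amp)
  is_resp <- rep(c(TRUE, FALSE), c(n_responders, n_cells - n_responders))
  ord <- sample.int(n_cells)
  amps <- amps[ord]; is_resp <- is_resp[ord]
  cms <- stats::runif(n_cells, c_m_range[1], c_m_range[2])

  lapply(seq_len(n_cells), function(i) {
    p <- base
    fac <- amps[i] / base_peak
    p$g_nav17 <- p$g_nav17 * fac
    p$g_ttxs_other <- p$g_ttxs_other * fac
    p$g_ttxr <- p$g_ttxr * fac
    p$c_m <- cms[i]
    fam <- simulate_family(protocol, p, conditions = conditions,
                           seed = derive_seed(seed, i),
                           cell_id = sprintf("cell%03d", i))
    fam$provenance$truth_responder <- is_resp[i]
    fam$provenance$target_peak_pA <- amps[i]
    fam
  })
}

#' Analyse a cohort and summarise it
#'
#' Convenience wrapper: [analyze_cell()] on every family, then
#' [summarize_cohort()].
#'
#' @param cohort List of [sweep_family()] objects (see
#'   [generate_cohort()]).
#' @param ... Passed to [analyze_cell()].
#' @return List with `cells` (per-cell results) and `summary`
#'   (a `cohort_summary`).
#' @export
analyze_cohort <- function(cohort, ...) {
  cells <- lapply(cohort, analyze_cell, ...)
  list(cells = cells, summary = summarize_cohort(cells))
}
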