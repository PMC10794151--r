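#' Pipeline configuration
#'
#' Collects the analysis-side constants, mode flags and seeds the staged
#' pipeline runner uses, and echoes them into every run manifest so
#' derived numbers are auditable. Two reversal-potential conventions are
#' supported and must be chosen explicitly: `"simulation"` uses the
#' simulated/estimated reversal; `"paper"` carries the printed
#' analysis-side constants (`e_rev_paper`, `current_density_paper`) through
#' the density arithmetic verbatim, reproducing the published derivation
#' chain.
#'
#' @param mode `"simulation"` or `"paper"`; never inferred.
#' @param e_rev_paper Analysis-mode reversal potential (mV).
#' @param current_density_paper Analysis-mode current density (pA/pF).
#' @param gamma Single-channel conductance (pS).
#' @param p_open_range Open-probability range used for density reports.
#' @param specific_capacitance pF per um^2.
#' @param cell_area Nominal cell surface area (um^2).
#' @param seed Master seed for stochastic stages.
#' @param out_dir Output directory for artifacts.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulation", "paper"),
                            e_rev_paper = -60.6,
                            current_density_paper = 2.4,
                            gamma = 6.4, p_open_range = c(0.4, 0.6),
                            specific_capacitance = 0.01, cell_area = 3500,
                            seed = 1L, out_dir = tempfile("navclamp-run-")) {
  mode <- match.arg(mode)
  if (gamma <= 0 || specific_capacitance <= 0 || cell_area <= 0)
    stop("constants must be positive", call. = FALSE)
  if (any(p_open_range <= 0) || any(p_open_range > 1))
    stop("p_open_range must lie in (0, 1]", call. = FALSE)
  structure(list(mode = mode, e_rev_paper = e_rev_paper,
                 current_density_paper = current_density_paper,
                 gamma = gamma, p_open_range = sort(p_open_range),
                 specific_capacitance = specific_capacitance,
                 cell_area = cell_area, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

write_manifest <- function(config, task, out_dir) {
  jsonlite::write_json(
    list(task = task, config = unclass(config),
         config_hash = fnv_hash(unclass(config)),
         package = "navclamp",
         version = as.character(utils::packageVersion("navclamp"))),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run one pipeline stage and write its artifacts
#'
#' Stage runner behind the package's end-to-end workflows. Each task
#' writes its JSON/TSV artifacts plus a manifest (config echo and hash,
#' seed, package version) into `config$out_dir`; identical config and
#' seed produce identical artifacts.
#'
#' Tasks: `"simulate"` (write a noisy default family), `"fixtures"`
#' (write the PSM and fluorescence fixtures), `"analyze-cell"` (noise-free
#' default family through the full per-cell analysis), `"cohort"`
#' (generate and summarise the default 77-cell cohort), `"density"`
#' (printed-arithmetic channel-density report), `"secretome"` (candidate
#' filter over a PSM table), `"caflux"` (normalise and integrate
#' fluorescence traces).
#'
#' @param task Stage name (see Details).
#' @param config A [pipeline_config()].
#' @param input Optional task-specific input path (PSM TSV for
#'   `"secretome"`; directory of trace TSVs for `"caflux"`).
#' @return The stage's main result, invisibly for writing stages.
#' @export
run_pipeline <- function(task, config = pipeline_config("simulation"),
                         input = NULL) {
  tasks <- c("simulate", "fixtures", "analyze-cell", "cohort", "density",
             "secretome", "caflux")
  if (!is.character(task) || length(task) != 1L || !task %in% tasks)
    stop("unknown task; use one of: ", paste(tasks, collapse = ", "),
         call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_manifest(config, task, config$out_dir)
  params <- default_gating_params()

  if (task == "simulate") {
    fam <- simulate_family(step_protocol(), params,
                           conditions = standard_conditions(c("control", "TTX")),
                           seed = config$seed)
    return(invisible(write_family(fam, file.path(config$out_dir, "family"))))
  }

  if (task == "fixtures") {
    write_psm_table(generate_psm_fixture(config$seed),
                    file.path(config$out_dir, "psm_fixture.tsv"))
    write_fluorescence(generate_fluorescence(noise_sd = 3, seed = config$seed),
                       file.path(config$out_dir, "fluorescence_fixture.tsv"))
    fam <- simulate_family(step_protocol(), params,
                           conditions = standard_conditions(c("control", "TTX")),
                           seed = config$seed)
    write_family(fam, file.path(config$out_dir, "family"))
    return(invisible(config$out_dir))
  }

  if (task == "analyze-cell") {
    fam <- simulate_family(step_protocol(), params,
                           conditions = standard_conditions(c("control", "TTX")),
                           seed = NULL)
    e_rev <- if (config$mode == "paper") config$e_rev_paper else params$e_rev_sim
    res <- analyze_cell(fam, e_rev = e_rev)
    rec <- list(
      cell_id = res$cell_id, peak_pA = res$peak,
      tau_ms = res$tau_at_0mV, time_to_peak_ms = res$time_to_peak,
      persistent_pA = res$persistent,
      percent_inhibition = as.list(res$percent_inhibition),
      current_density_pA_pF = res$current_density,
      v_half_mV = unname(coef(res$activation$boltzmann)["v_half"]),
      k_mV = unname(coef(res$activation$boltzmann)["k"]),
      e_rev_used_mV = res$activation$e_rev_used,
      threshold_mV = res$activation$threshold,
      tau_curve = res$activation$tau_curve,
      responder = res$responder)
    jsonlite::write_json(rec, file.path(config$out_dir, "cell.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(res))
  }

  if (task == "cohort") {
    coh <- analyze_cohort(generate_cohort(seed = config$seed))
    s <- coh$summary
    jsonlite::write_json(
      list(n_cells = s$n_cells, n_responders = s$n_responders,
           responder_pct = s$responder_fraction,
           peak_amplitude = as.list(s$peak_amplitude),
           current_density = as.list(s$current_density),
           tau_at_0mV = as.list(s$tau_at_0mV),
           percent_inhibition = lapply(s$percent_inhibition, as.list)),
      file.path(config$out_dir, "cohort.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(as.data.frame(s),
                       file.path(config$out_dir, "cohort.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(s))
  }

  if (task == "density") {
    chains <- lapply(config$p_open_range, function(po)
      channel_density_chain(config$current_density_paper,
                            v_test = 0, e_rev = config$e_rev_paper,
                            gamma = config$gamma, p_open = po,
                            specific_capacitance = config$specific_capacitance,
                            cell_area = config$cell_area))
    names(chains) <- sprintf("p_open_%g", config$p_open_range)
    jsonlite::write_json(chains, file.path(config$out_dir, "density.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(chains))
  }

  if (task == "secretome") {
    tbl <- if (is.null(input)) generate_psm_fixture(config$seed)
           else read_psm_table(input)
    cand <- apply_candidate_filter(tbl)
    write_psm_table(cand, file.path(config$out_dir, "candidates.tsv"))
    jsonlite::write_json(cand, file.path(config$out_dir, "candidates.json"),
                         digits = NA, pretty = TRUE)
    return(invisible(cand))
  }

  # caflux
  if (is.null(input)) {
    tr <- generate_fluorescence()
    norm <- normalize_f_f0(tr)
    out <- data.frame(file = "generated", f0 = attr(norm, "f0"),
                      peak_f_f0 = max(norm$intensity),
                      auc = auc(norm, duration = 200))
  } else {
    out <- summarize_fluorescence_dir(input, duration = 200)
  }
  utils::write.table(out, file.path(config$out_dir, "caflux.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out)
}
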