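#' @name gating-curves
#' @title Steady-state gating curves and time-constant interpolation
#' @description Steady-state activation follows
#'   `m_inf(V) = 1/(1 + exp((v_half_m - V)/k_m))` and steady-state
#'   inactivation `h_inf(V) = 1/(1 + exp((V - v_half_h)/k_h))`. Time
#'   constants are interpolated between anchors linearly in `log(tau)`
#'   against voltage and clamped at the outermost anchors, so they are
#'   positive and defined everywhere by construction.
#' @param params A [gating_params()] object.
#' @param v Voltage(s) in mV.
#' @return Numeric vector of gate values or time constants (ms).
NULL

#' @rdname gating-curves
#' @export
m_inf <- function(params, v) 1 / (1 + exp((params$v_half_m - v) / params$k_m))

#' @rdname gating-curves
#' @export
h_inf <- function(params, v) 1 / (1 + exp((v - params$v_half_h) / params$k_h))

tau_interp <- function(anchors, v) {
  if (nrow(anchors) == 1L) return(rep(anchors$tau, length(v)))
  exp(stats::approx(anchors$v, log(anchors$tau), xout = v, rule = 2)$y)
}

#' @rdname gating-curves
#' @export
tau_m <- function(params, v) tau_interp(params$tau_m_anchors, v)

#' @rdname gating-curves
#' @export
tau_h <- function(params, v) tau_interp(params$tau_h_anchors, v)

tau_coverage_ok <- function(params, v) {
  lo <- min(params$tau_m_anchors$v, params$tau_h_anchors$v) - 40
  hi <- max(params$tau_m_anchors$v, params$tau_h_anchors$v) + 40
  v >= lo & v <= hi
}

# integral of m(s)^p over [0, s] for m(s) = A + B*exp(-s/tau), via binomial
# expansion; exact for piecewise-constant voltage.
gate_power_integral <- function(A, B, tau, p, s) {
  E <- exp(-s / tau)
  out <- A^p * s
  for (k in seq_len(p)) {
    out <- out + choose(p, k) * A^(p - k) * B^k * (tau / k) * (1 - E^k)
  }
  out
}

# derive a 32-bit-safe per-sweep seed from a master seed and sweep index
derive_seed <- function(master, index) {
  (as.numeric(master) %% 2147483629 * 48271 + 1000003 * index) %% 2147483629
}

fnv_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 2166136261
  for (b in bytes) h <- ((h + b) * 16777619) %% 4294967296
  sprintf("%08x", as.integer(h %% 2147483647))
}

gaussian_lowpass <- function(current, dt_ms, cutoff_hz) {
  # Gaussian kernel whose -3 dB point sits at the cutoff frequency:
  # |H(f)| = exp(-2 pi^2 sigma^2 f^2) = 1/sqrt(2) at f = cutoff.
  sigma_s <- sqrt(log(2) / 2) / (2 * pi * cutoff_hz)
  sigma_samp <- sigma_s * 1000 / dt_ms
  half <- max(1L, ceiling(4 * sigma_samp))
  kern <- stats::dnorm(seq(-half, half), sd = sigma_samp)
  kern <- kern / sum(kern)
  n <- length(current)
  padded <- c(rep(current[1], half), current, rep(current[n], half))
  stats::filter(padded, kern, sides = 2)[(half + 1):(half + n)]
}

# core trace integrator shared by main sweeps and P/4 sub-sweeps.
# voltage path: `holding` outside [onset, onset+duration), `vstep` inside.
sim_trace <- function(holding, vstep, params, drug, step_onset, step_duration,
                      sweep_duration, seed = NULL, cap_edge = FALSE,
                      lowpass = FALSE) {
  dt <- 1000 / params$sample_rate                       # ms per sample
  n <- round(sweep_duration / dt)
  t <- (seq_len(n) - 1L) * dt
  p <- params$act_exponent

  g_na <- params$g_nav17 * (1 - drug$ttx_block_fraction) *
            (1 - drug$protx_block_fraction) +
          params$g_ttxs_other * (1 - drug$ttx_block_fraction) +
          params$g_ttxr

  segs <- data.frame(v = c(holding, vstep, holding),
                     from = c(0, step_onset, step_onset + step_duration),
                     to = c(step_onset, step_onset + step_duration,
                            sweep_duration))
  segs <- segs[segs$to > segs$from, , drop = FALSE]

  m <- numeric(n); h <- numeric(n); vtrace <- numeric(n)
  m0 <- m_inf(params, holding)
  h0 <- h_inf(params, holding)
  for (i in seq_len(nrow(segs))) {
    v <- segs$v[i]
    idx <- which(t >= segs$from[i] - dt / 2 & t < segs$to[i] - dt / 2)
    minf <- m_inf(params, v); hinf <- h_inf(params, v)
    tm <- tau_m(params, v); th <- tau_h(params, v)
    s_end <- segs$to[i] - segs$from[i]
    if (length(idx)) {
      s <- t[idx] - segs$from[i]
      mi <- minf + (m0 - minf) * exp(-s / tm)
      Q <- gate_power_integral(minf, m0 - minf, tm, p, s)
      hi <- hinf + (h0 - hinf) * exp(-Q / th)
      m[idx] <- mi; h[idx] <- hi; vtrace[idx] <- v
    }
    Qe <- gate_power_integral(minf, m0 - minf, tm, p, s_end)
    h0 <- hinf + (h0 - hinf) * exp(-Qe / th)
    m0 <- minf + (m0 - minf) * exp(-s_end / tm)
  }

  current <- g_na * m^p * h * (vtrace - params$e_rev_sim) +
             params$g_persistent * (vtrace - params$e_rev_sim) +
             params$g_leak * (vtrace - params$e_leak)

  if (cap_edge) {
    # linear capacitive charging transient at each voltage transition,
    # total charge C_m * dV spread over tau_c; cancels under P/4.
    tau_c <- 0.1
    edges <- data.frame(at = c(step_onset, step_onset + step_duration),
                        dv = c(vstep - holding, holding - vstep))
    for (j in seq_len(nrow(edges))) {
      on <- t >= edges$at[j] - dt / 2
      current[on] <- current[on] + params$c_m * edges$dv[j] / tau_c *
        exp(-(t[on] - edges$at[j]) / tau_c)
    }
  }
  if (!is.null(seed) && params$noise_sd > 0) {
    withr_seed <- floor(seed) %% 2147483629
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(withr_seed)
    current <- current + stats::rnorm(n, sd = params$noise_sd)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  if (lowpass) current <- as.numeric(gaussian_lowpass(current, dt, params$filter_cutoff))

  list(time = t, current = current, gate_range = range(c(m, h)))
}

#' Simulate one voltage-clamp sweep
#'
#' Integrates the gating model over a single rectangular voltage step and
#' returns the sampled whole-cell current. The integrator uses the exact
#' exponential solution of each first-order gate per constant-voltage
#' segment (the activation-coupled inactivation gate has the closed form
#' `h(t) = h_inf + (h0 - h_inf) * exp(-Q(t)/tau_h)` with
#' `Q(t) = integral of m(s)^p`), so the sampled values carry no
#' discretisation error beyond the sampling itself. Gates start at steady
#' state for the holding potential. Inward current is negative.
#'
#' Without a `seed` the sweep is noise-free; with a seed, white Gaussian
#' noise of s.d. `params$noise_sd` is added reproducibly.
#'
#' @param test_voltage Step voltage (mV); must lie within the coverage of
#'   the time-constant tables.
#' @param params A [gating_params()] object.
#' @param drug A [drug_state()]; defaults to control (no block).
#' @param protocol A [step_protocol()] supplying holding potential and step
#'   timing; its `test_voltages` are not consulted here.
#' @param seed Integer noise seed, or `NULL` for a noise-free sweep.
#' @param condition,repeat_index Labels stored on the sweep.
#' @param cap_edge Add a linear capacitive edge transient at each voltage
#'   transition (for P/4 exercises; default off, emulating compensated
#'   recordings).
#' @param lowpass Apply a Gaussian low-pass kernel matched to
#'   `params$filter_cutoff` (default off).
#' @return A [nav_sweep()] with step timing in `meta` and the extreme gate
#'   values reached in `meta$gate_range`.
#' @export
simulate_sweep <- function(test_voltage, params, drug = drug_state(),
                           protocol = step_protocol(test_voltages = test_voltage),
                           seed = NULL, condition = "control",
                           repeat_index = NA_integer_,
                           cap_edge = FALSE, lowpass = FALSE) {
  stopifnot(inherits(params, "gating_params"), inherits(drug, "drug_state"))
  validate_gating_params(params)
  if (!tau_coverage_ok(params, test_voltage))
    stop(sprintf("test voltage %g mV lies outside the tau-table coverage",
                 test_voltage), call. = FALSE)
  tr <- sim_trace(protocol$holding, test_voltage, params, drug,
                  protocol$step_onset, protocol$step_duration,
                  protocol$sweep_duration, seed = seed,
                  cap_edge = cap_edge, lowpass = lowpass)
  nav_sweep(tr$time, tr$current, test_voltage, condition = condition,
            role = "main", repeat_index = repeat_index,
            meta = list(step_onset = protocol$step_onset,
                        step_duration = protocol$step_duration,
                        holding = protocol$holding,
                        gate_range = tr$gate_range))
}

#' Simulate a full sweep family over a protocol and conditions
#'
#' Emits `n_repeats_per_voltage` sweeps per test voltage per condition and,
#' when the protocol enables P/4, four quarter-amplitude sub-sweeps per main
#' sweep delivered from `p4_subholding` with the same step timing. Per-sweep
#' noise seeds are derived deterministically from the master seed and a
#' running sweep index, so the same master seed always reproduces the same
#' family bit for bit.
#'
#' @param protocol A [step_protocol()].
#' @param params A [gating_params()].
#' @param conditions Named list of [drug_state()] objects; names become the
#'   sweep condition labels.
#' @param seed Master seed (integer) or `NULL` for noise-free output.
#' @param cell_id Cell identifier stored on the family.
#' @param cap_edge,lowpass Passed to the trace integrator (see
#'   [simulate_sweep()]).
#' @return A [sweep_family()] whose provenance records the truth-parameter
#'   hash.
#' @export
simulate_family <- function(protocol, params,
                            conditions = list(control = drug_state()),
                            seed = NULL, cell_id = "sim",
                            cap_edge = FALSE, lowpass = FALSE) {
  stopifnot(inherits(protocol, "step_protocol"))
  if (is.null(names(conditions)) || any(names(conditions) == ""))
    stop("conditions must be a named list of drug_state objects", call. = FALSE)
  sweeps <- list()
  idx <- 0L
  for (cond in names(conditions)) {
    drug <- conditions[[cond]]
    for (v in protocol$test_voltages) {
      for (r in seq_len(protocol$n_repeats_per_voltage)) {
        idx <- idx + 1L
        sw_seed <- if (is.null(seed)) NULL else derive_seed(seed, idx)
        sweeps[[length(sweeps) + 1L]] <-
          simulate_sweep(v, params, drug, protocol, seed = sw_seed,
                         condition = cond, repeat_index = r,
                         cap_edge = cap_edge, lowpass = lowpass)
        if (protocol$p4_enabled) {
          dv4 <- (v - protocol$holding) / 4
          for (k in 1:4) {
            idx <- idx + 1L
            sub_seed <- if (is.null(seed)) NULL else derive_seed(seed, idx)
            tr <- sim_trace(protocol$p4_subholding,
                            protocol$p4_subholding + dv4, params, drug,
                            protocol$step_onset, protocol$step_duration,
                            protocol$sweep_duration, seed = sub_seed,
                            cap_edge = cap_edge, lowpass = lowpass)
            sweeps[[length(sweeps) + 1L]] <-
              nav_sweep(tr$time, tr$current, v, condition = cond,
                        role = "p4_sub", repeat_index = r,
                        meta = list(step_onset = protocol$step_onset,
                                    step_duration = protocol$step_duration,
                                    holding = protocol$p4_subholding,
                                    sub_index = k,
                                    pulse_voltage = protocol$p4_subholding + dv4,
                                    gate_range = tr$gate_range))
          }
        }
      }
    }
  }
  sweep_family(sweeps, protocol, cell_id = cell_id,
               membrane_capacitance = params$c_m,
               provenance = list(type = "simulated",
                                 params_hash = fnv_hash(unclass(params)),
                                 seed = if (is.null(seed)) NA else seed))
}
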