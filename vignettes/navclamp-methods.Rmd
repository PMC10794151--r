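---
title: "Methods: simulation, calibration and analysis of TTX-sensitive sodium currents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, calibration and analysis of TTX-sensitive sodium currents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navclamp)
```

## Scope

`navclamp` implements the inference chain used to establish a functional,
fast-inactivating sodium conductance in cells that are not classically
excitable — osteoarthritic chondrocytes being the motivating case — and the
two companion analyses that the same experimental programme leans on: a
deterministic spectral-count filter for secretome candidates, and F/F0
normalisation of calcium-indicator transients. Everything is driven by a
simulator with known gating truth, so each stage of the analysis is
testable offline, and recovery of known parameters can be demonstrated
rather than assumed.

## The gating model

Each simulated cell is a parallel combination of three sodium conductance
pools that share one set of gating variables and differ only in
pharmacology (Na~v~1.7: blocked by both TTX and ProTx II; other
TTX-sensitive channels: blocked by TTX only; TTX-resistant channels),
plus an ohmic leak and an optional ungated persistent conductance. The
current is

$$I(t) = G_\mathrm{eff}\, m(t)^3\, h(t)\,(V - E_\mathrm{Na}) +
  g_p (V - E_\mathrm{Na}) + g_\mathrm{leak}(V - E_\mathrm{leak}) + \xi(t),$$

with inward current negative and additive white Gaussian recording noise
$\xi$ (s.d. 2 pA by default, applied only when a seed is supplied).

Activation is first-order Hodgkin–Huxley with
$m_\infty(V) = [1 + e^{(V_{1/2,m}-V)/k_m}]^{-1}$ and a cubed gate.
Inactivation is first-order but **activation-coupled**:

$$\frac{dh}{dt} = \frac{(h_\infty(V) - h)\, m(t)^3}{\tau_h(V)},$$

i.e. channels inactivate from activated states. Two observations force
this choice over independent gates. First, with independent first-order
gates and a single (non-cubed) activation gate, the decay rate of
$m\,h$ after the peak never exceeds $1/\tau_h$, so the fitted
falling-phase time constant is always *larger* than the time to peak —
yet the measured chondrocyte values have time to peak (1.4 ms at 0 mV,
0.5 ms at +50 mV) *above* the fitted inactivation constant (1.0 and
0.3 ms). Second, even with $m^3$, independent inactivation combined with
those late peaks erodes the peak open probability so severely at
depolarised voltages that the chord-conductance curve *declines* above
0 mV and the current–voltage maximum migrates to −10 mV, contradicting
the measured saturating activation curve and 0 mV maximum. With coupled
inactivation — the standard phenomenology for sodium channels, whose
inactivation is derived from the open and pre-open states — all the
measured quantities are simultaneously attainable, the gates remain in
[0, 1], and pool additivity under pharmacological subtraction is exact.

Time constants are supplied as anchor tables over voltage and
interpolated linearly in $\log\tau$ (clamped at the outermost anchors),
which keeps them positive and smooth. Steady-state inactivation is not
characterised by the measurements this package targets; its defaults
($V_{1/2,h} = -70$ mV, $k_h = 7$ mV) are stated assumptions, not fitted
values.

### Integration

Voltage is piecewise constant under a step protocol, so both gates have
closed forms per segment; the coupled gate integrates to
$h(t) = h_\infty + (h_0 - h_\infty)\exp(-Q(t)/\tau_h)$ with
$Q(t) = \int m^3$, available in closed form by binomial expansion. The
simulator therefore evaluates the exact solution at the 100 kHz sample
times — there is no discretisation error to tune, and the grid-convergence
test (halving the sample interval changes peaks by < 0.1%) passes by
construction. The 2 kHz low-pass character of the recording chain is
available as an optional Gaussian kernel whose −3 dB point matches the
cutoff; it is off by default because the analysis tests target the
underlying currents. Capacitive edge transients are likewise off by
default (recordings are modelled post-compensation); an optional linear
edge transient exercises the P/4 machinery.

## Calibration: apparent targets, microscopic knobs

Everything the analysis reports is *apparent*: the Boltzmann midpoint and
slope of the normalised chord conductance differ from $V_{1/2,m}$ and
$k_m$ (gate cubing steepens and shifts the curve; inactivation erosion
flattens it), and the fitted falling-phase constant sits above the
microscopic $\tau_h$ whenever activation is still settling near the peak.
`calibrate_gating()` therefore treats the full measurement pipeline as the
oracle: a Nelder–Mead search per anchor voltage tunes
$(\tau_m, \tau_h)$ until the *fitted* $\tau$ and the measured time to
peak hit their targets, and a fixed-point update tunes
$(V_{1/2,m}, k_m)$ until the *fitted* Boltzmann hits its targets; the two
stages alternate until every residual is inside tolerance (0.1 mV /
0.05 ms by default; the shipped defaults were generated at 0.02 ms). Both
$\tau$ tables are calibrated — passing the inactivation targets straight
through as $\tau_h$ anchors would bias the fitted constants upward by
5–15% for the reasons above. If the starting parameters already satisfy
the targets the function returns them unchanged, which makes the shipped
defaults a verifiable fixed point.

The default cell's amplitude scale is pinned by the activation threshold:
conductances are scaled so the noise-free TTX-sensitive current is 6 pA
at −40 mV, which puts the 5 pA detection criterion (about 2.5× the
default noise s.d.) exactly at the −40 mV threshold. A consequence worth
stating plainly: the default cell's 0 mV peak (≈1.3 nA total) is
several-fold brighter than a typical responder chondrocyte, because a
cell whose activation is first detectable at −40 mV under a 5 pA
criterion must be bright. Cohort cells are rescaled per cell to realistic
amplitudes (below). The pool split 0.400 : 0.217 : 0.383
(Na~v~1.7 : other TTX-S : TTX-R) reflects the reported fractional
contributions of the ProTx II-sensitive (~40%) and TTX-sensitive (~62%)
components, so a full TTX block removes 61.7% of the sodium current.

## Analysis conventions and numerical choices

- **Preprocessing order.** P/4 correction per repeat, then averaging
  across repeats, then baseline correction (mean of the final 5 ms before
  step onset). Whether averaging preceded or followed leak subtraction in
  the original recordings is not stated; correcting per repeat first is
  this package's choice and is linear either way in the noise-free limit.
- **P/4 convention.** Four sub-pulses of a quarter of the step amplitude,
  delivered from the sub-holding potential in the same polarity as the
  main step; each sub-sweep is referenced to its own pre-step baseline and
  their sum is the linear template. On a purely ohmic cell the corrected
  trace is flat to numerical tolerance (a property test randomises the
  leak conductance).
- **Peak search.** Extremum of largest magnitude between step onset and
  onset + 10 ms — wide enough for every observed time to peak, short
  enough to exclude offset transients. Time to peak uses three-point
  parabolic refinement (sub-sample; moves values by ≪ 0.01 ms at
  100 kHz).
- **Falling-phase fit.** $A e^{-t/\tau} + C$ from the measured peak to
  the step end (not a fixed window: maximal data, no rising-phase
  contamination), Levenberg–Marquardt with the 1/e crossing as the
  initial $\tau$; invariant to amplitude scaling and vertical offsets.
- **Persistent current.** Mean over a ±0.25 ms window centred 10 ms after
  onset; whether the original measurement was instantaneous or averaged
  is unstated, and the window choice is documented here.
- **Chord conductance and reversal.** $G = |I|/|V - E_r|$ with points
  within 5 mV of $E_r$ excluded (the chord diverges there), normalised to
  the included maximum. Two reversal conventions are supported and must
  be chosen explicitly (a `pipeline_config()` mode, never inferred):
  *simulation* mode uses the simulator's physiological reversal
  (+65 mV, near the Nernst potential for 145/10 mM Na⁺, ≈ +68 mV at room
  temperature) or an estimate from the depolarised I–V limb; *paper* mode
  carries the printed analysis constants (reversal −60.6 mV, current
  density 2.4 pA/pF) through the density arithmetic verbatim. The printed
  reversal is physically anomalous for a sodium conductance — a channel
  reversing at −60.6 mV cannot carry inward current at 0 mV — but it is
  load-bearing for the published derivation chain, so it is reproduced
  exactly in paper mode and never used to drive the simulator.
  `estimate_reversal()` (line through the three most depolarised I–V
  points) is one defensible convention among several; how the original
  estimate was obtained is unstated, so the estimator is kept out of the
  arithmetic-reproduction paths.
- **Boltzmann fit.** Amplitude constrained to [0.8, 1.2] so normalisation
  choice cannot masquerade as gating; initial values from the half-maximum
  crossing and the 10–90% rise width; a parameter landing on a bound
  raises a flag rather than failing silently.
- **Density chain.** Specific capacitance fixed at the textbook
  1 µF/cm² = 0.01 pF/µm². The 3500 µm² cell area is a *reconstruction*:
  it is the unique area for which densities of 0.10 and 0.15 /µm²
  give exactly 350 and 525 channels per cell, and it is documented as
  such, not as a measurement. Per-µm² densities are rounded to two
  decimals before the per-cell multiplication, matching the printed
  derivation; unrounded values are reported alongside.
- **Secretome filter.** Strictly more than twofold (a fold change of
  exactly 2.0 fails); "unique" requires at least one treated spectral
  count; molecular-weight windows are closed at both ends. The filter is
  a deterministic screen — no normalisation, no multiple-testing — because
  that is what the screen it reproduces is.
- **Calcium AUC.** The integrand is $F/F_0 - 1$, so a flat trace has zero
  area; whether the original AUC was baseline-referenced is ambiguous, and
  the `baseline` argument makes the choice explicit and reversible.
  $F_0$ is the mean of *all* pre-stimulus frames.

## What the generators emulate, and what they do not

The sweep simulator emulates: −90 mV holding, −60…+50 mV steps in 10 mV
increments, 100 kHz sampling with 2 kHz low-pass character, paired
control/drug conditions, eight-run averaging, P/4 sub-sweeps, and
millisecond-scale fast-inactivating inward currents of tens to hundreds
of pA riding on leak and Gaussian noise. It does not model stochastic
single-channel gating, temperature, series-resistance artefacts, drug
wash-in kinetics, or run-down — so passing tests demonstrate that the
*analysis* is correct and well-conditioned under realistic signal and
noise scales, not that real recordings are free of those artefacts.

The cohort generator plants composition by construction: responder cells
draw control peaks from a log-normal centred near 80 pA (clipped to
[40, 250] pA) with fast inactivation; non-responders draw 2–20 pA. The
margins on either side of the 30 pA classification boundary are chosen so
that averaged recording noise (≈1.6 pA s.d. after P/4 and eight-sweep
averaging) cannot flip a label, which is what makes the responder
percentage an exact, seed-independent quantity. Capacitances are uniform
on 25–45 pF. The PSM fixture plants exactly six filter-passing rows
(including HSP70 in the 30–100 kDa fraction and midkine in 10–30 kDa;
the four other passers are invented placeholders, as the remaining hit
identities are not public) plus decoys each failing exactly one
criterion. The fluorescence generator uses 2 s frames, a flat baseline,
and an instant-rise/exponential-decay transient whose peak lands exactly
on the onset frame so normalised peaks have closed forms.

## Problem sizes and runtimes

The shipped test-suite and acceptance runs use the study-scale defaults
throughout: 12-voltage families with 8 repeats at 100 kHz (30 ms sweeps),
100 noisy replicates for the Boltzmann-recovery distribution, and the
full 77-cell cohort. The complete suite runs in about two minutes on one
core; the acceptance script in under a minute.

## Known limitations

- The coupled-inactivation model is a phenomenological fit to apparent
  kinetics, not a Markov model of Na~v~1.7; recovery from inactivation
  and steady-state inactivation protocols are out of scope.
- Calibration targets three anchor voltages; between anchors the
  log-linear interpolation is a smoothness assumption.
- `estimate_reversal()` extrapolates a three-point line; on strongly
  rectifying I–V tails it inherits that line's bias (±3 mV on the
  simulator).
- The secretome and calcium modules deliberately stop at descriptive
  outputs; no between-group statistics are computed anywhere in the
  package.
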