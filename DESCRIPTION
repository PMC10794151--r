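Package: navclamp
Title: Whole-Cell Voltage-Clamp Analysis of TTX-Sensitive Sodium Currents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of whole-cell voltage-clamp recordings of
    voltage-gated sodium currents in electrically non-excitable cells such as
    osteoarthritic chondrocytes. Provides a Hodgkin-Huxley-style step-protocol
    simulator with activation-coupled inactivation and known ground truth;
    sweep averaging, P/4 leak subtraction and baseline correction;
    pharmacological isolation of drug-sensitive current components by trace
    subtraction (tetrodotoxin, protoxin II); peak current-voltage curves,
    chord-conductance transformation and Boltzmann activation fitting;
    single-exponential inactivation time constants and time-to-peak;
    conversion of current density into channel densities from single-channel
    conductance and open probability; responder classification and cohort
    summaries; a spectral-count (PSM) candidate filter for secretome screens;
    and F/F0 normalisation with area-under-curve for calcium-indicator traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite,
    pracma
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
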