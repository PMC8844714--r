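Package: spindlesource
Title: Source-Space Sleep-Spindle Analysis for Focal Epilepsy Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify sleep-spindle deficits in cortical
    source-space EEG and relate them to cognition. Provides a synthetic
    source-recording and cohort generator (1/f background, Poisson sigma
    bursts, epileptic-spike transients, group-specific overdispersed
    spindle rates), icosahedral source-space geometry with patch
    averaging and an inferior Rolandic region-of-interest construction,
    aperiodic-slope artifact flagging and spike masking, Hann and
    Slepian multitaper spectral estimation (relative power, sigma power,
    sigma bump, coherence), a trainable three-feature probabilistic
    spindle detector with duration filtering, per-spindle and bilateral
    synchrony statistics, quasi-Poisson mixed-effects group models with
    false-discovery-rate regional screening, and inverse-hyperbolic-sine
    spindle-rate models of neuropsychological task performance.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    MASS,
    yaml
Suggests:
    nlme,
    nortest,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
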