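Package: dcarepro
Title: Reproducibility Analysis for Dynamic Cerebral Autoregulation Estimates
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify test-retest reproducibility of dynamic cerebral
    autoregulation (DCA) estimates derived from paired recordings of mean
    arterial blood pressure (MABP), cerebral blood flow velocity (CBFV) and
    end-tidal CO2. Provides Welch spectral estimation of MABP band power in
    the very-low- and low-frequency bands, reference DCA estimators (transfer
    function gain and phase, the Tiecks autoregulation index, and an Mx-like
    correlation index), one-way intraclass correlation analysis with
    percentile-based case removal on MABP spectral power, repeated-measures
    linear trend testing, Monte Carlo comparison of intraclass correlations,
    and Spearman-Brown extrapolation of reliability to longer recording
    durations. Includes synthetic-data generators for paired physiological
    recordings and paired-estimate tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
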