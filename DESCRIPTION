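Package: laminarid
Title: Laminar Identification for High-Density Linear Probe Recordings
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies cortical layer boundaries from dense linear-probe
    (Neuropixels-class) extracellular recordings. Implements stimulus-independent
    spike-derived depth metrics (unit density, spike spatial spread, duration,
    peak-trough ratio), stimulus-evoked action-potential-band spectral metrics
    (multitaper power spectra, baseline-relative instantaneous power change,
    gaussian-weighted local coherence), thin-disc inverse current source density
    with smoothing and down-sampling experiments, rule-based layer boundary
    detection with anatomical fallback rules and manual overrides, and
    cross-penetration layer-template normalization. Ships a synthetic laminar
    recording generator with known ground-truth layers so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
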