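Package: punctacol
Title: Automated Synapse Quantification by Noise-Corrected Puncta Colocalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated, threshold-robust quantification of synapses in
    multi-channel confocal images of neuronal cultures. Detects pre- and
    post-synaptic puncta as local intensity maxima, restricts object-based
    colocalization to a dendrite mask via a triple binary AND, and corrects
    the colocalization count for random-chance overlap using two independent
    null estimators (puncta-location randomization and the asymptote of a
    spatial cross-correlation profile). Includes a synthetic-scene simulator
    with exact ground truth for validating detector sensitivity as a function
    of signal-to-noise ratio, and utilities for multi-electrode-array (MEA)
    recordings: Butterworth band-pass filtering, threshold spike detection,
    leaky-integrator burst detection, and firing/burst-rate summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
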