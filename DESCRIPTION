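Package: BrainStates
Title: Multi-Level Integration and Segregation Analysis of Brain States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies large-scale brain organization across altered states of
    consciousness from parcellated BOLD time series. Implements multi-level
    functional connectivity (global, cortical-hierarchy and network averages of
    Pearson correlations), topological integration as weighted global efficiency
    with a logarithmic weight-to-distance transform normalized against a
    weight-distribution-preserving null model, and interaction complexity as the
    normalized entropy of the singular-value spectrum of windowed cross-product
    interaction matrices. Paired effect sizes (Cohen's d) with FDR correction are
    aggregated into composite state rankings, Kendall's tau agreement, and an
    uncentered principal component ordering of states. A block-covariance
    synthetic cohort generator emulates paired baseline/altered designs with
    psychedelic-like and sedation-like coupling shifts so the full pipeline is
    testable without neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
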