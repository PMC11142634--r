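Package: crossconn
Title: Cross-Modal EEG-fMRI Functional Connectome Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and group-level comparison of multimodal functional
    connectomes. Builds per-subject fMRI connectomes (nuisance regression,
    band-pass filtering, motion scrubbing, Pearson correlation) and band-wise
    EEG connectomes (segment-wise corrected imaginary coherency with analytic
    significance masking) from region-level time series, and quantifies the
    cross-modal spatial correlation between them. Inference machinery covers
    group-label permutation tests, split-half reliability, bootstrap-of-group-
    averages linear models, per-edge contribution decomposition, intrinsic-
    connectivity-subnetwork analyses, and network-based statistics. A
    deterministic synthetic-cohort generator with controlled ground-truth
    coupling supports validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    igraph,
    yaml
Config/testthat/edition: 3
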