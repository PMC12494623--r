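Package: seroreact
Title: Serum Autoantibody Bead-Array Profiling with Clinical Association
    and Interaction-Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for multiplexed suspension bead-array (xMAP)
    serum autoantibody profiles measured against a curated antigen panel in
    a glaucoma cohort.  Covers median-fluorescence-intensity pre-processing
    (empty-well background correction, robust spline normalization, Box-Cox
    variance stabilization), Spearman screening of antigen reactivity
    against numeric clinical parameters with Benjamini-Hochberg control,
    distance-based PERMANOVA and per-antigen permutation t-tests for
    categorical parameters, hierarchical stratification of patients into
    reactivity tiers with within-tier re-screening, antigen co-reactivity
    clustering with size-constrained cluster extraction, and
    shortest-path-recurrence ("bridge node") analysis on protein-protein
    interaction graphs.  A synthetic-data generator with planted, recorded
    ground truth makes every stage testable without access to the original
    serum dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    limma,
    stats,
    utils
Suggests:
    MASS,
    withr,
    mclust,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
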