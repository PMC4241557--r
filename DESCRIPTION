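Package: ephystraj
Title: Developmental Trajectory Analysis of Neuronal Electrical Phenotype
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the developmental electrical phenotype of
    substantia nigra pars compacta dopaminergic neurons from current-clamp
    recordings. Provides extraction of 16 electrophysiological parameters from
    voltage traces (interspike-interval statistics, action-potential waveform
    metrics, passive membrane properties, sag/rebound, frequency-current gain
    and spike-frequency adaptation), firing-pattern classification from the
    coefficient of variation of the interspike interval, pairwise-stage
    significance stacking (one-way ANOVA with Tukey HSD), Ward agglomerative
    hierarchical clustering with an automatic dendrogram cut, covariance-based
    principal component analysis with supplementary projection, per-stage
    trajectory and variability-ellipse statistics, and emulation of
    pharmacology and dynamic-clamp leak-conductance perturbations. A seeded
    synthetic cohort generator calibrated to published stage-wise descriptive
    statistics produces surrogate recordings with known ground truth for
    validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
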