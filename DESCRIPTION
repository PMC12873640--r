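Package: ensembledyn
Title: Neuronal Ensemble Dynamics and Inter-Regional Coactivation During Sleep
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detection and tracking of local neuronal ensembles (cell
    assemblies) from multi-region extracellular recordings, and analysis of
    their inter-regional coactivation during non-REM sleep. Ensembles are
    extracted per region and behavioral session by independent component
    analysis of 20 ms binned, z-scored unit firing, with the number of
    components set by the Marchenko-Pastur eigenvalue threshold. The package
    computes instantaneous activation strength, detects activation events,
    tracks ensembles across sessions by absolute cosine similarity against a
    shuffle null, tests cross-region coactivation by cross-correlogram peaks
    against a 2-s chunk-shuffle null, detects hippocampal sharp-wave ripples,
    amygdalar high-frequency oscillations, and cortical ripples from LFP, and
    quantifies oscillation-locked ensemble activation. A synthetic-data
    generator with planted ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
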