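Package: nirboost
Title: Robust NIR Calibration with Repeated UVE Selection and Boosted PLS Ensembles
Version: 0.1.0
Authors@R:
    person("NIR", "Calibration Team", email = "nirboost@example.org",
           role = c("aut", "cre"))
Description: A calibration toolkit for near-infrared (NIR) prediction of fruit
    total soluble solids (TSS, degrees Brix). Implements robust-PCA outlier
    screening with score/orthogonal distance diagnostics, z-score spectral
    pretreatment, Kennard-Stone calibration/prediction partitioning, PLS1
    regression with k-fold cross-validated latent-variable selection,
    repeated uninformative variable elimination (UVE) with noise-derived
    stability cutoffs, frequency-tier stratification of selected wavelengths,
    tier-specific PLS member models, and an AdaBoost-style weighted ensemble.
    Includes a synthetic NIR spectra generator with known analyte signal so
    the complete workflow is testable without proprietary instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
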