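Package: chemoprofiler
Title: Chemoresistance Phenotyping of Cancer Cell Lines from MALDI-TOF-MS
    Profiles and XTT Dose-Response Assays
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discriminates chemotherapy-resistant from sensitive cancer cell
    lines by whole-cell MALDI-TOF mass-spectrometry profiling. Implements the
    full spectral workflow (square-root variance stabilization,
    Savitzky-Golay smoothing, SNIP baseline estimation, MAD noise and
    signal-to-noise peak detection, peak binning, frequency filtering and
    technical-replicate averaging), binary discriminant analysis t-score peak
    ranking, hierarchical k-means clustering on the binary distance with PCA
    visualization, cluster-homogeneity scoring and confidence ellipses, plus
    XTT metabolic-activity analysis with four-parameter log-logistic
    dose-response fits, EC50/IC50 derivation and fold-change comparisons. A
    synthetic-data module generates linear-mode spectra with a three-tier
    replicate hierarchy and 4PL dose-response plates with planted ground
    truth so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    mzR,
    withr
Config/testthat/edition: 3
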