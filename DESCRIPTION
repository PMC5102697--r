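Package: wavedf
Title: Wavelet Despiking and Effective Degrees of Freedom for Functional
    Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the spatially variable effective degrees of freedom
    (df) of denoised fMRI-like multivariate time series using the maximal
    overlap discrete wavelet transform (MODWT), and uses those df for valid
    probabilistic inference on functional connectivity. Provides a MODWT
    engine with reflection and periodic boundaries, a wavelet despiking
    step that separates detail coefficients into signal and noise sets,
    per-scale per-voxel effective df maps, df-corrected Fisher r-to-Z seed
    correlation maps, P-value-thresholded brain graphs built by adding
    edges in order of increasing P, signal-fraction-driven dynamic windows
    for time-varying analysis, head-motion and artifact-burden diagnostics,
    Fourier phase-randomization null models for Type I error validation,
    and a synthetic data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
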