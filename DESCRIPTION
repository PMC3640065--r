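Package: dtiqa
Title: Automated Quality Assurance for Diffusion Tensor Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An automated quality-assurance pipeline for diffusion tensor
    imaging (DTI). Fits the diffusion tensor by log-linear least squares,
    computes slice-adapted chi-squared goodness-of-fit maps, estimates the
    standard deviation of fractional anisotropy (FA) by wild bootstrap and
    FA bias by simulation-extrapolation (SIMEX) under a stacked Rician
    noise model, derives bias-aware power curves for two-sample t-tests,
    summarises tensor metrics per segmented region, condenses each dataset
    into a 112-element QA feature vector for PCA-based cohort outlier
    exploration, and renders a four-page graphical QA report. A synthetic
    DTI phantom generator with known ground truth and injectable
    corruption supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
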