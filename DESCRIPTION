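Package: ssmpca
Title: Scaled Subprofile Model PCA for Metabolic Brain Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derivation, validation and prospective scoring of disease-related
    metabolic spatial covariance patterns from normalized FDG-PET volumes using
    the scaled subprofile model with principal component analysis (SSM/PCA).
    Includes Gaussian smoothing and intensity-threshold masking of NIfTI
    volumes, log transformation and double centering of subject profiles,
    subject-space PCA, AIC-guided logistic combination of components,
    within-group bootstrap validation of voxel weights, z-transformed pattern
    expression scores, voxel-weight and score correlations between patterns,
    cohort-level inference from raw data or printed summary statistics, and a
    synthetic-cohort generator with known ground-truth covariance structure for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    nortest,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
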