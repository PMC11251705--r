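Package: PETstd
Title: Landmark-Based Intensity Standardization for PET and SUV Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-acquisition standardization of PET activity-concentration
    and SUV volumes. A one-time calibration on normal scans selects an optimal
    upper percentile by minimizing the coefficient of variation of
    reference-organ uptake across subjects, fixes a standard intensity scale,
    and estimates an inverse scale factor; each image is then mapped by a
    two-segment piecewise-linear intensity transformation anchored at
    histogram landmarks. Includes SUV conversion, reference-organ
    normalization baselines (Gaussian, z-score, and a classic
    histogram-landmark method), test-retest and cross-scanner evaluation
    metrics, and a synthetic PET phantom generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, RNifti, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'landmarks.R'
    'calibration.R'
    'transform.R'
    'baselines.R'
    'evaluation.R'
    'phantom.R'
    'io.R'
    'cli.R'
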