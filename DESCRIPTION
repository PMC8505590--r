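Package: qea
Title: Quantitative Enhancement Analysis for Paired Contrast-Enhanced MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxelwise quantitative enhancement analysis (QEA) of paired
    unenhanced and contrast-enhanced T1-weighted brain MRI volumes. Builds
    quantitative enhancement maps (QEMs) that grade every voxel on a fuzzy
    membership scale from 0 (nonenhancing) to 1 (maximally enhancing) after
    bias-field correction, mutual-information rigid registration and
    genetic-algorithm intensity harmonisation, compares two gadolinium-based
    contrast agents per region of interest with an equivalence-zone test, and
    reproduces cohort-level agreement statistics (paired t-tests, Pearson and
    Spearman correlation, Bland-Altman limits of agreement) from per-patient
    enhancement summaries. Includes a synthetic phantom generator with known
    ground-truth enhancement membership for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
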