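Package: nwuct
Title: Net Water Uptake Densitometry and Perfusion Core Volumetrics for
    Ischemic Stroke CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies ischemic edema on admission non-contrast head CT as
    percent net water uptake (NWU) via contralateral mirror-ROI densitometry,
    derives predicted core, hypoperfusion, penumbra and final infarct volumes
    from CT-perfusion threshold maps, computes lesion growth, and classifies
    CT-perfusion core overestimation ("ghost infarct core"). Includes a
    synthetic head-CT phantom generator with known ground-truth water uptake
    and a cohort simulator with multiplicative relative-risk outcome structure,
    log-binomial relative-risk and linear lesion-growth regression models,
    univariable-to-multivariable model construction, stratified sensitivity
    analysis, and descriptive cohort tables, so the full analysis pipeline is
    reproducible end-to-end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
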