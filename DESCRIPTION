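Package: retinarate
Title: Longitudinal Analysis of Retinal Thinning Rates from Macular Thickness Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for studying retinal neurodegeneration from optical
    coherence tomography (OCT) thickness maps in longitudinal cohorts.
    Normalizes scattered per-eye macular thickness samples into fovea-centred,
    right-eye-oriented regular grids; reduces them to concentric-ring and
    quadrant sector features including the parafoveal ganglion cell-inner
    plexiform layer (pfGCIPL) thickness; stratifies subjects by a
    reference-population quartile cutoff; and estimates annualized thinning
    rates, group contrasts and clinical associations with linear mixed-effects
    models. A synthetic cohort and scan generator with known ground truth makes
    every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deldir,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
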