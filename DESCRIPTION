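Package: dinofactor
Title: Transcript-to-Carbon Calibration for Quantitative Plankton
    Metatranscriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calibrates absolute transcript concentrations against carbon
    biomass for open-ocean plankton functional groups. Converts spike-in
    normalized per-contig transcript counts into transcripts per liter,
    converts classified imaging-flow-cytometer cell observations into
    carbon biomass per liter via allometric scaling, co-locates the two
    along a latitudinal transect, and fits per-group power laws
    T = a * C^b with AIC model comparison, ANCOVA taxonomy tests with
    Tukey post-hoc grouping, and estimation of the dinoflagellate
    transcript-per-carbon scaling factor ("Dino-factor") with propagated
    standard errors. Includes a synthetic-cruise generator for testing
    the full pipeline against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    stats,
    tools,
    utils,
    yaml,
    withr,
    generics,
    emmeans,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    jsonlite,
    optparse
VignetteBuilder: knitr
Config/testthat/edition: 3
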