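Package: zfscreen
Title: Concentration-Response Analysis of Zebrafish Embryo Developmental Toxicity Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A uniform data-analysis pipeline for plate-based zebrafish embryo
    developmental toxicity screening. Converts well-level 96-well plate records
    (mortality at 24 and 120 hours post-fertilization, altered-phenotype flags
    in survivors) into concentration-response endpoints, selects a
    dataset-adaptive benchmark response (BMR) by pooled-variance stabilization,
    interpolates benchmark concentrations (BMC) on noise-corrected monotone
    curves, scores the specificity of altered phenotypes against mortality with
    a data-driven noise cutoff, and harmonizes lab-specific phenotype
    recordings across laboratories through a zebrafish phenotype ontology
    mapping with granular and general developmental-defect groupings. Includes
    quality-control gates for vehicle controls, weekly-pooled positive
    controls, and blinded duplicates, a relational schema export, and a seeded
    synthetic plate generator emulating multi-laboratory study designs so the
    whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    yaml,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
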