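Package: gpcraxes
Title: Cancer-Rewired GPCR Receptor-Ligand-Enzyme Signaling Axes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds an interaction network of G-protein-coupled receptors
    (GPCRs) with their endogenous ligands and ligand-biosynthetic enzymes,
    scores co-differential regulation of receptor-ligand and receptor-enzyme
    axis pairs across cancer subtypes, assesses transcript-metabolite pathway
    concordance via a pathway abundance score, screens axes for combined
    two-gene survival association with Kaplan-Meier, log-rank and Cox
    proportional-hazards models, and calls growth-inhibitory GPCR drugs from
    pooled viability screens using a bimodality-coefficient filter. Ships a
    synthetic-data generator that emulates every pipeline input with planted
    effects so each stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    fgsea,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
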