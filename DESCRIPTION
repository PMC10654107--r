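Package: schitomine
Title: Hallmark-Gene-Guided Discovery and Characterization of N4-like Viruses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reference-guided mining pipeline for the N4-like viral lineage
    (Schitoviridae). Derives orthologous protein families from reference
    genomes (reciprocal best hits and Markov clustering), defines the seven
    universal single-copy hallmark genes, builds calibrated position-specific
    profiles and runs iterative search-to-convergence mining, screens
    candidate contigs (polymerase length and ExDGxxxG motif filters, 99%
    global deduplication, seven-hallmark completeness with chimera flagging),
    detects integrated proviral regions in host contigs, predicts hosts by
    exact CRISPR-spacer matching, assigns species/genus/subfamily ranks from
    intergenomic similarity, builds gene-content networks and protein-family
    accumulation curves, compares hallmark phylogenies with strict
    Robinson-Foulds values, and quantifies inter-protein residue covariance
    with mean-field direct coupling analysis. Includes a deterministic
    synthetic-community generator with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    vegan,
    withr
Config/testthat/edition: 3
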