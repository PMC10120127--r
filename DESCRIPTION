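Package: crisprkas
Title: CRISPR-Cas9 Occupancy and Cleavage Mapping from ssDNA-Capture Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for kethoxal-assisted ssDNA sequencing (KAS-seq)
    applied to CRISPR ribonucleoproteins, where strand invasion by Cas9 or
    dCas9 exposes the non-target strand as single-stranded DNA that can be
    covalently labeled and enriched. Provides guide RNA off-target search
    with mismatches and bulges, strand-separated coverage and read 5'-end
    profiles in RPM units, de novo peak calling with a local-lambda Poisson
    model, a quantitative strand-asymmetry curation score, occupancy
    quantification in windows around predicted cut sites, treatment-minus-
    control occupancy for in vivo experiments, a cutting score that
    separates cleavage from binding, replicate agreement, sequencing-depth
    saturation analysis, and amplicon indel quantification. A fully seeded
    synthetic-data generator emulates the assay's biochemical signatures
    (guanine-dependent labeling of R-loop bubbles, asymmetric fragment
    pileups, phased cleavage 5' ends) so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    Rsamtools,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
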