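Package: vkorcall
Title: Codon-Level Vkorc1 Resistance Genotyping and Binding-Site Triage for
    Rodent Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Genotyping pipeline for anticoagulant-rodenticide resistance
    surveys of wild rodents. Locates Vkorc1 exons inside Sanger consensus
    amplicons on either strand, assembles the complete coding sequence per
    animal, calls codon-level variants with IUPAC-aware zygosity (double
    peaks encode heterozygotes), annotates calls against a resistance-mutation
    catalogue, and aggregates per-species mutation frequency tables and the
    cohort resistance prevalence. A structural module triages mutations by
    their position relative to the ligand binding site of the VKOR enzyme
    (5 Angstrom contact sets, Kabsch superposition RMSD, geometric hydrogen
    bonds). A synthetic-cohort generator emits exon amplicons, COI barcodes
    and a genotype truth table so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
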