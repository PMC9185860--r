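Package: circann
Title: Backsplice Junction Annotation, Circular ORF Prediction and
    Visualization for Circular RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotates circular RNA (circRNA) backsplice junctions against
    Ensembl-style gene models: assigns each junction a representative
    reference transcript and backsplice exon pair (M/N) by a deterministic
    ranking over junction fit, CCDS status, commonness among a gene's
    junctions, exon count and transcript length; assembles the circular
    sequence and enumerates rolling-circle open reading frames, classifying
    them by how often they cross the backsplice junction (0C, 1C5', 1C3',
    2C, endless); reconciles junction sets across circRNA databases; builds
    subcellular-compartment presence profiles from fractionated RNA-seq
    junction calls; and renders deterministic SVG transcript-track and
    protein-domain alignment plots. Ships a seeded synthetic-fixture
    generator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
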