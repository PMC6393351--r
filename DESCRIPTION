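Package: vitiflora
Title: Probe Remapping, Flower Volatile Chemotyping and Carbocation Flux
    Analysis for Grapevine Terpene Synthases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for linking grapevine (Vitis vinifera) terpene synthase
    gene expression to flower sesquiterpene chemotypes. Implements
    cross-hybridization-aware remapping of short microarray probes to curated
    gene models under a full-length k-mismatch rule, summarization of
    probe-level expression to gene level from uniquely binding probes,
    hierarchical clustering with expression-hotspot detection, GC-MS
    internal-standard quantification via calibration curves, compositional
    chemotype statistics and principal component analysis, assignment of
    sesquiterpenes to carbocation cascade classes with per-sample biosynthetic
    flux percentages, construction and export of enzyme-product bipartite
    networks, screening of transcript isolates for open reading frames and
    canonical terpene synthase motifs, and a seeded synthetic-data generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    igraph,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
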