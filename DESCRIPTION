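Package: vectortrace
Title: AAV Integration-Site Detection and CRISPR HDR Editing Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing CRISPR-Cas9/AAV6 homology-directed-repair (HDR)
    gene-correction experiments. Detects AAV vector integration sites from
    Cas9-enriched long reads aligned to a combined host+vector reference by
    parsing supplementary-alignment (SA) tags and CIGAR strings, clusters
    vector-host junctions into integration sites and classifies them as
    targeted or random. Quantifies editing outcomes with an in-silico
    three-primer PCR assay (HDR fraction from band intensities), calls indels
    in a window around the Cas9 cut site from amplicon reads with a banded
    affine-gap aligner, enumerates candidate off-target sites by mismatch
    scanning, and ships a truth-annotated synthetic-data generator emulating
    Cas9-enriched nanopore libraries and amplicon pools so every stage is
    testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
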