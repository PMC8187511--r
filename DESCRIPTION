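Package: srebscan
Title: Comparative Genomics of the SREB Receptor Family in Fishes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for characterizing the SREB (GPR27/85/173)
    family of orphan class-A G protein-coupled receptors across fish genomes:
    candidate-gene verification (ORF extraction, Kyte-Doolittle transmembrane
    counting, length filters), paralog-cluster assignment by neighbor-joining
    with bootstrap support, alignment-column conservation profiling including
    cluster-specific divergent-site detection and canonical GPCR motif
    (DRY/CWxP/NPxxY) deviation scanning, microsynteny-based gene presence,
    loss and assembly-gap calling from conserved flanking genes, and qPCR
    relative-expression quantification with standard-curve efficiency QC.
    Includes a synthetic-data generator that plants known cluster-specific
    sites, gene losses and fold changes so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    phangorn,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
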