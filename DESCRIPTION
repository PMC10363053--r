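Package: pmirscan
Title: Detection of Putative Plant MicroRNAs in Human Plasma Small RNA
    Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A self-contained, testable pipeline for detecting putative
    plant-derived microRNAs (pmiRNAs) in human plasma small RNA
    sequencing data. Reads are collapsed, subtracted against host
    references (genome, transcriptome, extra-chromosomal DNA), mapped to
    plant genomes, intersected with miRNA annotations, and classified by
    a competitive bit-score rule against four sequence databases (plant
    miRNAs, human miRNAs, other-species miRNAs, human mRNA). Includes an
    in-package Smith-Waterman / seeded local aligner with Karlin-Altschul
    bit scores, RPM quantification, kernel-density score diagnostics,
    plant-style target expectation scoring, hypergeometric enrichment,
    hierarchical clustering with project-distribution tables, consensus
    k-mer search, and a deterministic synthetic-data generator with
    ground-truth manifests for recovery-based validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
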