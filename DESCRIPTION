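Package: polyprobe
Title: Design and In Silico Evaluation of Gene-Targeted Polynucleotide FISH Probes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing and evaluating double-stranded polynucleotide
    probes for gene-targeted fluorescence in situ hybridization (direct-geneFISH).
    Tiles a target gene into consecutive probes with matched melting temperature
    and GC content, computes DNA:DNA duplex melting temperatures with the Wetmur
    model and the formamide/mismatch stringency trade-offs used to broaden probe
    specificity across taxa, screens probe sets against gene databases by
    semi-global pairwise alignment (percent identity, longest mismatch-or-gap
    stretch, set-level hit calls), detects candidate polysaccharide utilization
    loci on annotated contigs, and computes per-field-of-view gene detection
    efficiency and relative gene abundance statistics from microscopy count
    tables. Includes seed-deterministic synthetic-data generators for homolog
    families, annotated contigs and count tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
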