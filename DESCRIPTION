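Package: vsikit
Title: Virus Discovery and Virus-Derived Small RNA Profiling for Insect
    Metatranscriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to discover and characterize insect-specific negative-sense
    RNA viruses from assembled metatranscriptome contigs and small-RNA
    sequencing data. Provides a six-frame translation homology screen against
    a viral protein panel with Karlin-Altschul E-value filtering, ORF and UTR
    annotation of linear and circular viral genomes with gene-order typing
    (e.g. the chuvirus L-G-N-(x) architecture), a zero-mismatch strand- and
    circularity-aware exact read mapper with per-base coverage, profiling of
    virus-derived small interfering RNAs (size-by-strand distribution,
    5'-terminal nucleotide preference, positional distribution, hotspot
    calling), pairwise RdRP identity matrices with neighbor-joining trees,
    and a synthetic-data generator that plants known genome architectures,
    Dicer-like small-RNA populations, and RNA-seq coverage so that every
    stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    ape,
    jsonlite,
    stringi,
    withr,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
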