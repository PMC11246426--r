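Package: localtag
Title: Local Read Haplotagging for Long-Read Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Approximate local haplotagging of long sequencing reads without
    prior variant calls. Within independent 25 kb windows, putative
    heterozygous SNP candidates are identified from read pileups, an allele
    graph is built with read-support edges between consecutive candidate
    positions, and a pair-score dynamic program assigns each allele to one of
    two haplotypes; reads are then haplotagged (1, 2, or 0) by majority vote
    over the alleles they support and standard HP/PS tags are written back to
    the alignment file. Includes a diploid read simulator with per-read truth
    haplotypes and a switch-aware haplotagging accuracy evaluator, so the
    whole method is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
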