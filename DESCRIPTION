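Package: terminseq
Title: Positional Transcript Bias Analysis and Premature Termination Simulation for RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genes whose RNA-seq signal is depleted specifically at the
    3' end by bisecting each annotated gene into a 5' and a 3' half, counting
    aligned fragments per half, and testing each half for differential
    abundance between genotypes with a negative-binomial Wald test.
    Condition-specific 3'-end depleted genes are selected, cross-referenced
    against the wild-type response, and visualised as scaled metagene
    coverage profiles. Includes a generative simulator of RNA polymerase II
    elongation with a per-base premature-termination hazard and
    genotype-dependent nuclear-exosome degradation, used to benchmark the
    pipeline, plus relative qPCR quantification (2^-ddCt) and
    electrolyte-leakage EC50 comparison via an extra sum-of-squares F-test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tibble,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
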