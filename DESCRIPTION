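Package: heatmiR
Title: Discovery and Differential Expression of Heat-Responsive Plant
    miRNAs from Small RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for identifying heat-responsive
    microRNAs from unreplicated plant small RNA sequencing libraries. Cleans
    and collapses raw reads into counted sequence tags, annotates them against
    non-coding RNA classes, identifies known miRNAs, new members of known
    families and novel miRNAs via precursor excision, RNA secondary-structure
    folding and five structural hairpin criteria (including MFE and MFEI
    thresholds), predicts miRNA targets under six position-indexed
    complementarity rules with G-U wobble scoring, normalizes expression to
    tags per million, calls differential expression with an exact test for
    unreplicated tag counts, classifies miRNAs into nine expression-pattern
    types across a tolerant and a sensitive genotype, and joins differentially
    expressed miRNAs with differentially expressed genes into a
    negative-regulation network. Ships a synthetic-data generator with planted
    ground truth so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    S4Vectors,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: ViennaRNA (RNAfold, RNAduplex on the PATH)
Config/testthat/edition: 3
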