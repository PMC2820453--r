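Package: nifregulon
Title: Nitrogen-Fixation Regulon Inference and Expression-Island Analysis
    for Diazotrophic Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pipeline for transcriptional analysis of bacterial nitrogen
    fixation and its repression by ammonium. Classifies genes by linear
    fold change between growth conditions, infers the nitrogen-fixation
    regulon as the set of genes induced under nitrogen fixation and
    repressed within minutes of ammonium shock, derives core subsets via
    ortholog presence tables, scans upstream regions for the NifA upstream
    activator sequence (TGT-N10-ACA) and the sigma-54 (RpoN) -24/-12
    promoter, predicts NifA-sigma54-dependent operons from promoter flags
    and gene adjacency, and detects contiguous expression islands of
    co-regulated genes. Ships a synthetic-data generator with planted
    truth (genome, expression matrix, ortholog tables) so every stage is
    testable without external data, plus the printed worked example of
    the Pseudomonas stutzeri A1501 nif island.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
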