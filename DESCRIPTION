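Package: mirfree
Title: Genome-Free Discovery of MicroRNAs from Small RNA Deep Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reference-genome-free pipeline for discovering microRNAs in small RNA
    deep-sequencing libraries. Collapses and filters reads, clusters sequence
    variants by identity and coverage, annotates known miRNAs with per-family
    position-specific scoring matrices and miRNA* candidates against mature-masked
    hairpins, removes structural and endosymbiont contaminants, defines novel
    candidates through a sequence-similarity network with fast-greedy modularity
    communities, calls precursor hairpins and miRNA:miRNA* duplexes on assembled
    contigs by base-pair maximization folding, and provides the accompanying
    statistics: Shannon library diversity, read-count versus qPCR correlation, and
    an efficiency-corrected randomization test for RNAi knockdown validation. A
    ground-truthed synthetic library simulator makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    igraph,
    vegan,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
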