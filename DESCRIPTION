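Package: vh4rep
Title: B-Cell Receptor Repertoire Skew and VH4-34 Idiotope Hotspot Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for adaptive immune receptor repertoire (AIRR)
    rearrangement data centred on the self-reactive IGHV4-34 heavy chain.
    Reads, collapses and filters AIRR-C rearrangement tables; aligns
    transcripts to germline V genes and classifies clones by somatic
    mutations at the VH4-34 self-reactivity hotspots (the framework-1
    hydrophobic patch A24-V25-Y26 with auxiliary Q6-W7, the CDR2
    N-glycosylation site N57-H58-S59, and framework-3 K90-L91-S92); groups
    rearrangements into clones by junction Hamming distance and builds
    clonal connectivity graphs; computes repertoire skew statistics (Chao1
    richness, V-J pairing usage, CDR3 length by J gene, CDR3
    physicochemistry, distal-JH usage); and simulates AIRR repertoires with
    ground truth emulating healthy-donor and RAG-deficient-like repertoires
    so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    igraph,
    IRanges,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
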