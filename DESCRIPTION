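Package: selexr
Title: Simulation and Specificity Analysis of SELEX-seq Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for in vitro selection (SELEX-seq) experiments on
    protein-DNA binding specificity, built around the DUX4 double
    homeodomain. Simulates doped and randomized bait libraries and
    affinity-proportional pulldown rounds under an explicit binding-energy
    model; trims constant adapters and extracts variable regions; fits
    order-k Markov background models on unselected control reads to predict
    expected k-mer counts; calls significantly enriched k-mers with
    round-normalized relative affinities; computes per-position
    selection-bias ratios between pulled-down and control doped libraries;
    and scores candidate oligonucleotides against the derived binding
    preference matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Software, Sequencing, MotifDiscovery, Transcription
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
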