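Package: crispriscreen
Title: Design and Analysis of Pooled Inducible CRISPRi Fitness and Productivity Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for pooled, inducible CRISPR interference
    (CRISPRi) screens in microbes, modelled on genome-wide repression
    libraries in cyanobacteria. Covers genome-wide sgRNA library design with
    mismatch-bounded off-target counting (NGG/NAG PAMs, both strands),
    sgRNA counting from sequencing reads, generation-normalised fitness
    scores from turbidostat competition time courses (area under the log2
    fold-change curve), per-mutant growth-rate estimation from a discrete
    depletion model, Ward/Euclidean clustering of depletion trajectories,
    and hit selection for tolerance screens and fluorescence-activated
    droplet-sorting productivity screens. A synthetic-data module simulates
    annotated genomes, competition count time courses and droplet-sorting
    screens with recorded ground truth, so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    cluster,
    methods,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
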