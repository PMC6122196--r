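Package: dbgalign
Title: Short-Read Alignment to Unitig de Bruijn Graphs with Markov-Model
    Repeat Resolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a strand-aware, unitig-compacted de Bruijn graph from a
    reference genome and aligns short Illumina reads to it with a greedy,
    priority-queue-driven branch-and-bound seed-and-extend search that
    maximises Needleman-Wunsch similarity. Repeats are resolved implicitly by
    a two-pass strategy: a first unrestricted alignment pass trains a
    higher-order Markov model over graph walks, transitions are screened with
    a Poisson likelihood-ratio test under an expected-coverage model, and a
    second pass is guided by the surviving transitions. Includes an
    Illumina-style read simulator with error-free twin reads and the
    corrected-read accuracy metric, plus FASTA/FASTQ and GFA1 input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
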