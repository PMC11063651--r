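Package: escore
Title: Embedding-Based Substitution Scoring and Alignment Distance Metrics for Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores protein pairwise alignments with the E-score, the cosine
    similarity between per-residue embedding vectors, inside an affine-gap
    global or semi-global Needleman-Wunsch (Gotoh) aligner.  Provides a
    deterministic synthetic context-sensitive embedder so the toolkit runs
    without protein language model downloads, an adapter contract for real
    models, readers for FASTA/CLUSTAL alignments and NCBI substitution
    matrices, five alignment-comparison distances (sum-of-pairs, sequence-gap,
    positional-gap, relative-displacement and closest-context), and an
    MSA-based evaluation pipeline that compares scoring schemes against
    reference alignments with paired Wilcoxon signed-rank tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
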