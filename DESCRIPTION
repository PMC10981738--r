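Package: embedsearch
Title: Remote Homology Search with Protein Language Model Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-only homologous protein search. Candidate query-target
    pairs are pre-filtered by shared Pfam clan membership, ranked by a learned
    bilinear structural-similarity (TM-score) predictor over mean-pooled
    protein embeddings, and the top-ranked pairs are aligned by
    Smith-Waterman/Needleman-Wunsch dynamic programming over an
    embedding dot-product substitution matrix with a linear gap penalty.
    Includes the full retrieval-evaluation protocol (sensitivity up to the
    first false positive, size-weighted precision-recall, mean average
    precision, precision at k), a deterministic mock encoder, and a synthetic
    fixture generator with a planted fold hierarchy so every stage is
    testable without pretrained models or external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
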