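Package: litnet
Title: Entity Co-Occurrence Networks and Fuzzy Retrieval for Biomedical Literature Skimming
Version: 0.1.0
Authors@R: person("litnet", "developers", role = c("aut", "cre"),
    email = "litnet@example.org")
Description: Turns a corpus of biomedical abstracts (Medline XML or plain
    text) into a weighted entity network. Per-document entity co-occurrence
    is scored with a sentence-distance kernel, aggregated corpus-wide with
    frequency-scaled pointwise mutual information, and complemented with a
    cosine-similarity layer over co-occurrence context vectors. The
    resulting knowledge base is exposed through fuzzy term, statement and
    provenance indices supporting a fuzzy boolean query language with
    ranked article provenance, and through a path-based related-article
    index. An evaluation framework runs heuristic-guided random walks on
    the entity graphs and scores them with MeSH tree-code similarity,
    cluster entropies and graph-structure measures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
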