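# Deterministic fixtures: the worked-example bundle (mention positions,
# aggregation inputs, context vectors, the toy knowledge base and
# taxonomy code pairs) and seeded synthetic corpora, taxonomies and
# community graphs so every pipeline stage is testable without any
# external download.

#' Worked-example fixture bundle
#'
#' Returns the constants of the method's worked examples, hard-coded so
#' tests can pipe them through the implementation and compare against the
#' published arithmetic:
#'
#' * `ex1`: per-document mention sentence positions of the two entities
#'   in the two Parkinson's-disease abstracts (PMIDs 9629849 and
#'   8239569), with the expected per-document co-occurrence scores
#'   3.4166... and 3.25;
#' * `ex2`: aggregation inputs (joint weight 20/3, marginals 28.987 and
#'   220.354, pair frequency 2, 1414 basic statements, normalisation
#'   constant 2.061) with expected normalised weight 0.545;
#' * `ex3`: the two truncated co-occurrence context vectors with their
#'   full-vector norms (3.048, 2.491) and dot product (2.773), expected
#'   cosine 0.365;
#' * `ex4`: the two-statement toy knowledge base with provenance ids
#'   P1-P4 (P1 = 9629849, P2 = 8239569, P3 = 21832222, P4 = 22076870)
#'   and the three expected index matrices;
#' * `ex5`: the top-five fuzzy term degrees of the worked query, with the
#'   expected statement degrees 0.852 and 0.695;
#' * `ex7`: the two taxonomy code sets with expected similarity 2/3.
#'
#' @return Named list of fixture components.
#' @export
worked_example_fixtures <- function() {
  ex1 <- list(
    docs = list(
      "9629849" = list(parkinsonism = c(14L, 22L),
                       drd = c(12L, 12L, 14L, 17L, 22L, 23L)),
      "8239569" = list(parkinsonism = c(1L, 2L),
                       drd = c(1L, 2L, 5L))
    ),
    expected_scores = c("9629849" = 1 + 1/4 + 1/3 + 1/3 + 1 + 1/2,
                        "8239569" = 3.25)
  )

  ex2 <- list(joint = 20 / 3, marg_x = 28.987, marg_y = 220.354,
              freq = 2L, n_basic = 1414L, percentile = 95,
              norm_constant = 2.061, expected_weight = 0.545)

  comp <- c("t0", "t1", "t2", "t3", "t4", "t5", "t6", "t7", "t8", "t10",
            "t11", "t13", "t14", "t15", "t17", "t18")
  a <- stats::setNames(c(0.14, 0.39, 1.0, 0.08, 0.26, 0.06, 0.18, 0.4,
                         0.07, 0.27, 0.09, 0.7, 0.03, 0.14, 0.33, 0.25),
                       comp)
  b <- stats::setNames(c(0.26, 0.57, 1.0, 0.3, 0.82, 0.2, 0.33, 0.26,
                         0.39, 0.43, 0.36, 0.41, 0.06, 0.34, 1.0, 1.0),
                       comp)
  ex3 <- list(a = a, b = b, norm_a = 3.048, norm_b = 2.491, dot = 2.773,
              expected_similarity = 0.365)

  kb <- kb_from_statements(
    data.frame(term_a = c("parkinsonism", "parkinsonisms"),
               term_b = c("drd", "mrpi values"),
               relation = c("cooc", "sim"),
               weight = c(0.545, 0.365), stringsAsFactors = FALSE),
    list(c("P1", "P2"), c("P3", "P4"))
  )
  terms4 <- c("drd", "mrpi values", "parkinsonism", "parkinsonisms")
  tm <- matrix(0, 4, 4, dimnames = list(terms4, terms4))
  tm["parkinsonism", "drd"] <- tm["drd", "parkinsonism"] <- 0.545
  tm["parkinsonisms", "mrpi values"] <-
    tm["mrpi values", "parkinsonisms"] <- 0.365
  sids <- kb$statements$statement_id
  sm <- matrix(0, 4, 2, dimnames = list(terms4, sids))
  sm[c("parkinsonism", "drd"), 1] <- 1
  sm[c("parkinsonisms", "mrpi values"), 2] <- 1
  pm <- matrix(0, 2, 4, dimnames = list(sids, c("P1", "P2", "P3", "P4")))
  pm[1, c("P1", "P2")] <- 0.545
  pm[2, c("P3", "P4")] <- 0.365
  ex4 <- list(kb = kb,
              pmids = c(P1 = "9629849", P2 = "8239569",
                        P3 = "21832222", P4 = "22076870"),
              term_index = tm, statement_index = sm,
              provenance_index = pm)

  ex5 <- list(
    term_degrees = c("cup" = 1.0, "mrpi" = 1.0,
                     "magnetic resonance parkinsonism index" = 0.704,
                     "clinically unclassifiable parkinsonism" = 0.39,
                     "clinical evolution" = 0.34),
    expected_statement_degrees = c(0.852, 0.695)
  )

  ex7 <- list(
    codes_x = c("C10.228.662.700", "C23.888.592.636.447.690",
                "C11.590.472.500"),
    codes_y = "C10.228.662.600.700",
    abstract_x = c("C10", "C11", "C23"),
    abstract_y = "C10",
    expected_similarity = 2 / 3
  )

  list(ex1 = ex1, ex2 = ex2, ex3 = ex3, ex4 = ex4, ex5 = ex5, ex7 = ex7)
}

#' Synthetic corpus specification
#'
#' The generator emulates the structure the extraction pipeline relies
#' on: multi-sentence abstracts with entity mentions planted at known
#' sentence positions, organised in topical groups so that within-group
#' co-mentions dominate cross-group ones.
#'
#' @param n_docs Number of documents (default 40).
#' @param n_groups Number of planted entity groups (default 4).
#' @param entities_per_group Entities per group (default 6).
#' @param sentences_per_doc Sentences per document (default 8).
#' @param within_rate Per-sentence mention probability for entities of
#'   the document's own group (default 0.3).
#' @param cross_rate Same for entities of other groups (default 0.05).
#' @param seed Integer seed; generation is bit-reproducible.
#' @return A `litnet_synth_spec` list.
#' @export
synthetic_spec <- function(n_docs = 40L, n_groups = 4L,
                           entities_per_group = 6L,
                           sentences_per_doc = 8L,
                           within_rate = 0.3, cross_rate = 0.05,
                           seed = 42L) {
  stopifnot(n_docs >= 1L, n_groups >= 1L, entities_per_group >= 1L,
            sentences_per_doc >= 1L)
  structure(as.list(environment()), class = "litnet_synth_spec")
}

#' Generate a synthetic corpus with planted mentions
#'
#' Each document belongs to one group (round-robin); each sentence
#' mentions each within-group entity with probability `within_rate` and
#' each cross-group entity with probability `cross_rate`. Returns both
#' the documents (sentences are simple templated English) and the exact
#' planted mention positions, so numeric tests do not depend on any
#' extractor.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `documents` (list of [document()]), `mentions`
#'   (data frame `term`, `doc_id`, `sentence_idx`) and `groups` (named
#'   list group -> entity terms).
#' @export
synthetic_corpus <- function(spec = synthetic_spec()) {
  if (spec$n_docs < 1L) stop("degenerate spec: no documents")
  set.seed(spec$seed)
  groups <- lapply(seq_len(spec$n_groups), function(g)
    sprintf("g%de%d", g, seq_len(spec$entities_per_group)))
  names(groups) <- sprintf("group%d", seq_len(spec$n_groups))
  all_entities <- unlist(groups)
  entity_group <- rep(seq_len(spec$n_groups),
                      each = spec$entities_per_group)
  docs <- vector("list", spec$n_docs)
  mention_rows <- list()
  for (d in seq_len(spec$n_docs)) {
    doc_id <- sprintf("doc%03d", d)
    grp <- ((d - 1L) %% spec$n_groups) + 1L
    sentences <- character(spec$sentences_per_doc)
    for (s in seq_len(spec$sentences_per_doc)) {
      p <- ifelse(entity_group == grp, spec$within_rate, spec$cross_rate)
      hit <- stats::runif(length(all_entities)) < p
      ments <- all_entities[hit]
      sentences[s] <- if (length(ments))
        paste0("This study examined ", paste(ments, collapse = " and "),
               " in patients.")
      else "No relevant entities were observed in this context."
      for (m in ments)
        mention_rows[[length(mention_rows) + 1L]] <-
          list(term = m, doc_id = doc_id, sentence_idx = s)
    }
    docs[[d]] <- document(doc_id, sentences)
  }
  mentions <- if (length(mention_rows))
    data.frame(
      term = vapply(mention_rows, `[[`, character(1), "term"),
      doc_id = vapply(mention_rows, `[[`, character(1), "doc_id"),
      sentence_idx = vapply(mention_rows, `[[`, integer(1),
                            "sentence_idx"),
      stringsAsFactors = FALSE)
  else data.frame(term = character(0), doc_id = character(0),
                  sentence_idx = integer(0))
  list(documents = docs, mentions = mentions, groups = groups)
}

#' Generate a toy taxonomy for planted entity groups
#'
#' Assigns every entity of group `g` a tree code in a distinct top-level
#' subtree `G0g`, with `depth` random sub-segments, so within-group
#' taxonomy similarity is positive and cross-group similarity is zero.
#'
#' @param groups Named list group -> entity terms (see
#'   [synthetic_corpus()]).
#' @param depth Code depth below the top level (default 2).
#' @param seed Integer seed.
#' @return A `litnet_taxonomy`.
#' @export
synthetic_taxonomy <- function(groups, depth = 2L, seed = 42L) {
  set.seed(seed)
  codes <- list()
  for (g in seq_along(groups)) {
    top <- sprintf("G%02d", g)
    for (ent in groups[[g]]) {
      segs <- sprintf("%03d", sample.int(999L, depth, replace = TRUE))
      codes[[ent]] <- paste(c(top, segs), collapse = ".")
    }
  }
  taxonomy(codes)
}

#' Generate a synthetic community graph with a matching taxonomy
#'
#' A planted-partition graph: `n_nodes` nodes in `n_groups` communities;
#' within-community edges appear with probability `p_within` and carry
#' weights in (0.5, 1], cross-community edges with probability `p_cross`
#' and weights in (0, 0.5]. Each community occupies its own top-level
#' taxonomy subtree, so taxonomically similar nodes are exactly the
#' within-community ones.
#'
#' @param n_nodes Number of nodes (default 200).
#' @param n_groups Number of communities (default 4).
#' @param p_within,p_cross Edge probabilities (defaults 0.15 and 0.01).
#' @param seed Integer seed.
#' @return List with `graph` (igraph) and `taxonomy`
#'   (`litnet_taxonomy`).
#' @export
synthetic_community_graph <- function(n_nodes = 200L, n_groups = 4L,
                                      p_within = 0.15, p_cross = 0.01,
                                      seed = 42L) {
  set.seed(seed)
  grp <- rep(seq_len(n_groups), length.out = n_nodes)
  nodes <- sprintf("g%dn%03d", grp, seq_len(n_nodes))
  from <- character(0); to <- character(0); w <- numeric(0)
  for (i in seq_len(n_nodes - 1L)) {
    js <- seq((i + 1L), n_nodes)
    same <- grp[js] == grp[i]
    p <- ifelse(same, p_within, p_cross)
    hit <- stats::runif(length(js)) < p
    if (!any(hit)) next
    js <- js[hit]; same <- same[hit]
    from <- c(from, rep(nodes[i], length(js)))
    to <- c(to, nodes[js])
    w <- c(w, ifelse(same, stats::runif(length(js), 0.5, 1),
                     stats::runif(length(js), 0.01, 0.5)))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w),
    directed = FALSE,
    vertices = data.frame(name = nodes))
  codes <- list()
  for (i in seq_len(n_nodes)) {
    segs <- sprintf("%03d", sample.int(999L, 2L, replace = TRUE))
    codes[[nodes[i]]] <- paste(c(sprintf("G%02d", grp[i]), segs),
                               collapse = ".")
  }
  list(graph = g, taxonomy = taxonomy(codes))
}

#' Write fixture bundle files
#'
#' Serialises the worked-example constants and a synthetic corpus as
#' plain-text files (TSV/JSON-free formats) under `dir`:
#' `ex1_mentions.tsv`, `ex4_kb.tsv`, `synthetic_mentions.tsv` and the
#' synthetic documents as `*.txt`.
#'
#' @param dir Output directory.
#' @param spec A [synthetic_spec()].
#' @return Invisibly, `dir`.
#' @export
write_fixture_bundle <- function(dir, spec = synthetic_spec()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fx <- worked_example_fixtures()
  rows <- list()
  for (doc in names(fx$ex1$docs)) {
    for (term in names(fx$ex1$docs[[doc]])) {
      for (idx in fx$ex1$docs[[doc]][[term]])
        rows[[length(rows) + 1L]] <- data.frame(
          doc_id = doc, sentence_idx = idx, term = term,
          stringsAsFactors = FALSE)
    }
  }
  utils::write.table(do.call(rbind, rows),
                     file.path(dir, "ex1_mentions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_kb(fx$ex4$kb, file.path(dir, "ex4_kb.tsv"))
  synth <- synthetic_corpus(spec)
  utils::write.table(synth$mentions,
                     file.path(dir, "synthetic_mentions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_plaintext(synth$documents, file.path(dir, "synthetic_docs"))
  invisible(dir)
}
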