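# Corpus-wide knowledge base: frequency-scaled PMI aggregation of basic
# co-occurrence statements, and a cosine-similarity layer over the
# resulting co-occurrence context vectors.

#' Aggregate basic statements for PMI scoring
#'
#' For each unordered term pair: the joint weight (sum of per-document
#' scores), the pair document frequency `F` (number of basic statements
#' for the pair), and for each term the marginal weight (sum of scores
#' over all basic statements containing the term, joint statements
#' included). `n_basic` is the total number of basic statements, `|T|`.
#'
#' @param basic_statements Data frame from [extract_basic_statements()].
#' @return A `litnet_agg_stats` list with elements `pairs` (data frame
#'   `term_a`, `term_b`, `joint`, `freq`), `marginal` (named numeric) and
#'   `n_basic`.
#' @export
aggregate_statements <- function(basic_statements) {
  key <- paste(basic_statements$term_a, basic_statements$term_b, sep = "\r")
  joint <- tapply(basic_statements$score, key, sum)
  freq <- tapply(basic_statements$score, key, length)
  parts <- do.call(rbind, strsplit(names(joint), "\r", fixed = TRUE))
  marg <- c(tapply(
    c(basic_statements$score, basic_statements$score),
    c(basic_statements$term_a, basic_statements$term_b),
    sum
  ))  # c() drops the 1-d array dim, keeps names
  structure(list(
    pairs = data.frame(term_a = parts[, 1], term_b = parts[, 2],
                       joint = as.numeric(joint),
                       freq = as.integer(freq),
                       stringsAsFactors = FALSE),
    marginal = marg,
    n_basic = nrow(basic_statements)
  ), class = "litnet_agg_stats")
}

#' Frequency-scaled pointwise mutual information
#'
#' `fpmi(x, y) = F(x, y) * log2( p(x, y) / (p(x) p(y)) )` where the
#' distributions are the aggregated weights normalised by the total number
#' of basic statements `|T|`: `p(x, y) = joint(x, y)/|T|`,
#' `p(x) = marginal(x)/|T|`. Equivalently
#' `F * log2( joint * |T| / (marginal_x * marginal_y) )`. Positive values
#' indicate non-random association, negative values disassociation.
#'
#' @param joint Joint weight of the pair (sum of per-document scores).
#' @param marg_x,marg_y Marginal weights of the two terms.
#' @param freq Absolute pair frequency `F`.
#' @param n_basic Total number of basic statements `|T|`.
#' @return fPMI value (unnormalised; any real number).
#' @export
fpmi <- function(joint, marg_x, marg_y, freq, n_basic) {
  if (any(marg_x <= 0) || any(marg_y <= 0))
    stop("zero or negative marginal weight")
  stopifnot(all(joint > 0), n_basic > 0)
  freq * log2(joint * n_basic / (marg_x * marg_y))
}

#' Percentile normalisation of fPMI scores
#'
#' Filters out non-positive values, computes the normalisation constant as
#' the `P`-th percentile (nearest-rank: the value at position
#' `ceiling(P/100 * n)` of the ascending sort) of the remaining values,
#' divides by it and clips at 1, so only about `(100 - P)%` of the scores
#' touch the ceiling.
#'
#' @param fpmi_values Named numeric vector of fPMI scores.
#' @param P Percentile in (0, 100] (default 95).
#' @return List with `weights` (named numeric in (0, 1]) and
#'   `norm_constant`.
#' @export
normalize_scores <- function(fpmi_values, P = 95) {
  pos <- fpmi_values[fpmi_values > 0]
  if (length(pos) == 0L) {
    warning("no positive fPMI values; empty co-occurrence layer")
    return(list(weights = numeric(0), norm_constant = NA_real_))
  }
  nc <- nearest_rank_percentile(pos, P)
  list(weights = pmin(pos / nc, 1), norm_constant = nc)
}

#' Nearest-rank percentile
#'
#' The value at rank `ceiling(P/100 * n)` of the ascending sort.
#'
#' @param x Numeric vector (non-empty).
#' @param P Percentile in (0, 100].
#' @return The percentile value.
#' @export
nearest_rank_percentile <- function(x, P) {
  stopifnot(length(x) > 0, P > 0, P <= 100)
  unname(sort(x)[ceiling(P / 100 * length(x))])
}

#' Build the corpus-wide co-occurrence layer
#'
#' Aggregates basic statements, scores each pair with [fpmi()], drops
#' non-positive scores and normalises the rest with [normalize_scores()].
#'
#' @param basic_statements Data frame from [extract_basic_statements()].
#' @param P Normalisation percentile (default 95).
#' @return Data frame with columns `term_a`, `term_b`, `relation`
#'   (`"cooc"`), `weight`; attribute `norm_constant` carries the
#'   percentile constant.
#' @export
build_cooc_layer <- function(basic_statements, P = 95) {
  empty <- data.frame(term_a = character(0), term_b = character(0),
                      relation = character(0), weight = numeric(0))
  if (is.null(basic_statements) || nrow(basic_statements) == 0L) return(empty)
  agg <- aggregate_statements(basic_statements)
  p <- agg$pairs
  scores <- fpmi(p$joint, agg$marginal[p$term_a], agg$marginal[p$term_b],
                 p$freq, agg$n_basic)
  names(scores) <- paste(p$term_a, p$term_b, sep = "\r")
  norm <- suppressWarnings(normalize_scores(scores, P))
  if (length(norm$weights) == 0L) {
    warning("all fPMI scores non-positive; empty co-occurrence layer")
    return(empty)
  }
  keep <- match(names(norm$weights), names(scores))
  out <- data.frame(term_a = p$term_a[keep], term_b = p$term_b[keep],
                    relation = "cooc", weight = as.numeric(norm$weights),
                    stringsAsFactors = FALSE)
  attr(out, "norm_constant") <- norm$norm_constant
  out
}

#' Co-occurrence context vectors
#'
#' For every term in the co-occurrence layer, the vector of its aggregated
#' co-occurrence weights to all other terms (its "co-occurrence
#' complement"). These vectors are the operands of [cosine_similarity()].
#'
#' @param cooc_layer Data frame from [build_cooc_layer()].
#' @return Named list: term -> named numeric vector (co-occurring term ->
#'   weight).
#' @export
cooc_vectors <- function(cooc_layer) {
  if (nrow(cooc_layer) == 0L) return(list())
  terms <- sort(unique(c(cooc_layer$term_a, cooc_layer$term_b)))
  vecs <- stats::setNames(vector("list", length(terms)), terms)
  for (i in seq_len(nrow(cooc_layer))) {
    a <- cooc_layer$term_a[i]; b <- cooc_layer$term_b[i]
    w <- cooc_layer$weight[i]
    vecs[[a]][b] <- w
    vecs[[b]][a] <- w
  }
  vecs
}

#' Cosine similarity of two weighted vectors
#'
#' `dot(a, b) / (||a|| ||b||)` with norms taken over the full vectors.
#' Zero-norm input yields 0 by convention.
#'
#' @param a,b Named numeric vectors (component name -> weight).
#' @return Similarity in `[0, 1]` for non-negative weights.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  shared <- intersect(names(a), names(b))
  if (length(shared) == 0L) return(0)
  sum(a[shared] * b[shared]) / (na * nb)
}

#' Build the similarity layer
#'
#' Emits `(x, sim, y, s)` for every unordered term pair with cosine
#' similarity `s >= threshold` between their co-occurrence context
#' vectors. Candidate generation is restricted to pairs sharing at least
#' one nonzero component, which is lossless for cosine > 0.
#'
#' @param vectors Named list from [cooc_vectors()].
#' @param threshold Minimum similarity to keep (default 0.25).
#' @return Data frame with columns `term_a`, `term_b`, `relation`
#'   (`"sim"`), `weight`.
#' @export
build_sim_layer <- function(vectors, threshold = 0.25) {
  empty <- data.frame(term_a = character(0), term_b = character(0),
                      relation = character(0), weight = numeric(0))
  terms <- names(vectors)
  if (length(terms) < 2L) return(empty)
  # invert component -> owning terms to generate candidates by blocking
  comp_owner <- list()
  for (t in terms) {
    for (comp in names(vectors[[t]])) {
      comp_owner[[comp]] <- c(comp_owner[[comp]], t)
    }
  }
  cand <- new.env(parent = emptyenv())
  for (owners in comp_owner) {
    owners <- sort(unique(owners))
    if (length(owners) < 2L) next
    for (i in seq_len(length(owners) - 1L)) {
      for (j in seq((i + 1L), length(owners))) {
        assign(paste(owners[i], owners[j], sep = "\r"), TRUE, envir = cand)
      }
    }
  }
  keys <- ls(cand)
  if (length(keys) == 0L) return(empty)
  out <- vector("list", 0L)
  for (k in keys) {
    pr <- strsplit(k, "\r", fixed = TRUE)[[1]]
    s <- cosine_similarity(vectors[[pr[1]]], vectors[[pr[2]]])
    if (s >= threshold) {
      out[[length(out) + 1L]] <- data.frame(
        term_a = pr[1], term_b = pr[2], relation = "sim", weight = s,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res[order(res$term_a, res$term_b), , drop = FALSE]
}

#' Build the full knowledge base
#'
#' Convenience wrapper: co-occurrence layer plus similarity layer, with a
#' provenance map (statement -> source documents) derived from the basic
#' statements. Co-occurrence statements inherit the documents their pair
#' was observed in; similarity statements inherit the union of the two
#' terms' source documents.
#'
#' @param basic_statements Data frame from [extract_basic_statements()].
#' @param P Normalisation percentile (default 95).
#' @param sim_threshold Similarity threshold (default 0.25).
#' @return A `litnet_kb` list: `statements` (data frame `term_a`,
#'   `term_b`, `relation`, `weight`, plus `statement_id`) and `provenance`
#'   (named list statement_id -> character vector of doc ids).
#' @export
build_kb <- function(basic_statements, P = 95, sim_threshold = 0.25) {
  cooc <- build_cooc_layer(basic_statements, P)
  sim <- build_sim_layer(cooc_vectors(cooc), sim_threshold)
  statements <- rbind(cooc, sim)
  statements$statement_id <- statement_id(
    statements$term_a, statements$relation, statements$term_b)
  term_docs <- tapply(
    c(basic_statements$doc_id, basic_statements$doc_id),
    c(basic_statements$term_a, basic_statements$term_b),
    function(x) sort(unique(x))
  )
  pair_key <- paste(basic_statements$term_a, basic_statements$term_b,
                    sep = "\r")
  pair_docs <- tapply(basic_statements$doc_id, pair_key,
                      function(x) sort(unique(x)))
  prov <- stats::setNames(vector("list", nrow(statements)),
                          statements$statement_id)
  for (i in seq_len(nrow(statements))) {
    a <- statements$term_a[i]; b <- statements$term_b[i]
    prov[[i]] <- if (statements$relation[i] == "cooc")
      pair_docs[[paste(a, b, sep = "\r")]]
    else
      sort(unique(c(term_docs[[a]], term_docs[[b]])))
  }
  structure(list(statements = statements, provenance = prov,
                 norm_constant = attr(cooc, "norm_constant")),
            class = "litnet_kb")
}

#' Stable statement identifier
#'
#' Content-derived key of a binary statement, stable across rebuilds.
#'
#' @param term_a,relation,term_b Statement components.
#' @return Character identifier.
#' @export
statement_id <- function(term_a, relation, term_b) {
  paste(term_a, relation, term_b, sep = "|")
}

#' @export
print.litnet_kb <- function(x, ...) {
  cat(sprintf("<knowledge base: %d cooc + %d sim statements, %d terms>\n",
              sum(x$statements$relation == "cooc"),
              sum(x$statements$relation == "sim"),
              length(unique(c(x$statements$term_a, x$statements$term_b)))))
  invisible(x)
}

#' Write a knowledge base as TSV
#'
#' Columns `term_a`, `relation`, `term_b`, `weight`, `sources`
#' (comma-separated doc ids).
#'
#' @param kb A `litnet_kb`.
#' @param path Output path.
#' @export
write_kb <- function(kb, path) {
  s <- kb$statements
  df <- data.frame(term_a = s$term_a, relation = s$relation,
                   term_b = s$term_b,
                   weight = formatC(s$weight, digits = 12, format = "g"),
                   sources = vapply(kb$provenance[s$statement_id],
                                    paste, character(1), collapse = ","),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a knowledge base from TSV
#' @param path Path written by [write_kb()].
#' @return A `litnet_kb`.
#' @export
read_kb <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  statements <- data.frame(term_a = df$term_a, term_b = df$term_b,
                           relation = df$relation,
                           weight = as.numeric(df$weight),
                           stringsAsFactors = FALSE)
  statements$statement_id <- statement_id(
    statements$term_a, statements$relation, statements$term_b)
  prov <- stats::setNames(
    lapply(strsplit(df$sources, ",", fixed = TRUE), sort),
    statements$statement_id)
  structure(list(statements = statements, provenance = prov,
                 norm_constant = NA_real_), class = "litnet_kb")
}

#' Assemble a knowledge base from explicit statements
#'
#' Mainly for tests and worked examples: build a `litnet_kb` directly from
#' a statement table and a provenance list.
#'
#' @param statements Data frame with `term_a`, `term_b`, `relation`,
#'   `weight`.
#' @param provenance List of character vectors, one per statement row
#'   (source doc ids).
#' @return A `litnet_kb`.
#' @export
kb_from_statements <- function(statements, provenance) {
  stopifnot(nrow(statements) == length(provenance))
  statements$statement_id <- statement_id(
    statements$term_a, statements$relation, statements$term_b)
  structure(list(statements = statements,
                 provenance = stats::setNames(provenance,
                                              statements$statement_id),
                 norm_constant = NA_real_),
            class = "litnet_kb")
}
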