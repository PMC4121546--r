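# Per-document distance-weighted co-occurrence scoring and basic
# co-occurrence statements.

#' Co-occurrence scoring parameters
#'
#' Mention pairs at sentence distance `d` contribute `1/(d + 1)` to the
#' pair score; pairs farther apart than `max_sentence_distance` sentences
#' contribute nothing. The defaults (window 3, kernel 1/(d+1)) are pinned
#' by the worked per-document arithmetic: a distance-3 pair contributes
#' 1/4 and is counted, a distance-4 pair is excluded.
#'
#' @param max_sentence_distance Non-negative integer window (default 3).
#' @return A `litnet_cooc_params` object.
#' @export
cooc_params <- function(max_sentence_distance = 3L) {
  stopifnot(max_sentence_distance >= 0L)
  structure(list(max_sentence_distance = as.integer(max_sentence_distance)),
            class = "litnet_cooc_params")
}

#' Document-level co-occurrence score of two entities
#'
#' `score = sum over all mention pairs (i, j) with |i - j| <= window of
#' 1 / (|i - j| + 1)`, where `i` ranges over the sentence positions of the
#' first entity's mentions and `j` over the second's. Multiplicity counts:
#' two mentions in the same sentence yield two pairs.
#'
#' @param mentions_a,mentions_b Integer vectors of sentence indices
#'   (multisets; repeats allowed).
#' @param params A [cooc_params()] object.
#' @return Non-negative numeric score (0 for empty input).
#' @export
document_cooc_score <- function(mentions_a, mentions_b,
                                params = cooc_params()) {
  if (length(mentions_a) == 0L || length(mentions_b) == 0L) return(0)
  d <- abs(outer(as.numeric(mentions_a), as.numeric(mentions_b), "-"))
  sum(1 / (d[d <= params$max_sentence_distance] + 1))
}

#' Extract basic co-occurrence statements from corpus mentions
#'
#' For every document and every unordered pair of distinct entities
#' mentioned in it, emits one statement `(term_a, term_b, score, doc_id)`
#' whenever the document co-occurrence score is positive. Pairs are
#' stored canonically with `term_a < term_b` (lexicographic).
#'
#' @param corpus_mentions Data frame with columns `term`, `doc_id`,
#'   `sentence_idx` (see [extract_corpus_mentions()]).
#' @param params A [cooc_params()] object.
#' @return Data frame with columns `term_a`, `term_b`, `score`, `doc_id`.
#' @export
extract_basic_statements <- function(corpus_mentions,
                                     params = cooc_params()) {
  empty <- data.frame(term_a = character(0), term_b = character(0),
                      score = numeric(0), doc_id = character(0))
  if (is.null(corpus_mentions) || nrow(corpus_mentions) == 0L) return(empty)
  out <- vector("list", 0L)
  for (doc in unique(corpus_mentions$doc_id)) {
    m <- corpus_mentions[corpus_mentions$doc_id == doc, , drop = FALSE]
    positions <- split(m$sentence_idx, m$term)
    terms <- sort(names(positions))
    if (length(terms) < 2L) next
    for (i in seq_len(length(terms) - 1L)) {
      for (j in seq((i + 1L), length(terms))) {
        s <- document_cooc_score(positions[[terms[i]]],
                                 positions[[terms[j]]], params)
        if (s > 0) {
          out[[length(out) + 1L]] <- data.frame(
            term_a = terms[i], term_b = terms[j], score = s, doc_id = doc,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Write basic statements as TSV
#'
#' Columns `term_a`, `term_b`, `score`, `doc_id`; scores printed with 12
#' significant digits so re-aggregation from the dump is lossless at
#' working precision.
#'
#' @param statements Data frame from [extract_basic_statements()].
#' @param path Output file path.
#' @export
write_basic_statements <- function(statements, path) {
  df <- statements
  df$score <- formatC(df$score, digits = 12, format = "g")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read basic statements from TSV
#' @param path TSV path written by [write_basic_statements()].
#' @return Data frame with columns `term_a`, `term_b`, `score`, `doc_id`.
#' @export
read_basic_statements <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(doc_id = "character"))
  df$score <- as.numeric(df$score)
  df
}
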