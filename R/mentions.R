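# Entity mention extraction. The original pipeline used an external
# statistical NER; here extraction is a pluggable interface with two
# built-ins (a gazetteer with longest-match semantics and a naive noun
# phrase chunker) plus a loader for externally produced annotations, so
# all downstream numerics are independent of any particular NER model.

#' Normalise a surface form to a canonical term
#'
#' Lower-cases, collapses internal whitespace and strips surrounding
#' punctuation. Idempotent. All-punctuation input yields an empty string,
#' which callers must discard.
#'
#' @param surface Character vector of surface strings.
#' @return Character vector of canonical terms.
#' @export
normalize_term <- function(surface) {
  x <- tolower(surface)
  x <- gsub("[[:space:]]+", " ", x)
  x <- trimws(x)
  # strip leading/trailing punctuation but keep internal hyphens etc.
  x <- gsub("^[[:punct:][:space:]]+|[[:punct:][:space:]]+$", "", x)
  gsub("[[:space:]]+", " ", x)
}

#' Extractor configuration
#'
#' Exactly one extraction mode is active: `"dictionary"` (gazetteer with
#' longest-match-wins), `"chunker"` (naive noun-phrase chunking), or
#' `"external"` (annotations read from a TSV file, see
#' [read_annotations_tsv()]).
#'
#' @param mode One of `"dictionary"`, `"chunker"`, `"external"`.
#' @param dictionary Character vector of terms (dictionary mode).
#' @param annotation_path TSV path (external mode).
#' @return An `litnet_extractor_config` object.
#' @export
extractor_config <- function(mode = c("dictionary", "chunker", "external"),
                             dictionary = NULL, annotation_path = NULL) {
  mode <- match.arg(mode)
  if (mode == "dictionary" && is.null(dictionary))
    stop("dictionary mode requires a dictionary")
  if (mode == "external" && is.null(annotation_path))
    stop("external mode requires annotation_path")
  structure(list(mode = mode,
                 dictionary = if (!is.null(dictionary))
                   unique(normalize_term(dictionary)) else NULL,
                 annotation_path = annotation_path),
            class = "litnet_extractor_config")
}

# Tokenise a sentence keeping character offsets; used by the gazetteer.
.tokenize_offsets <- function(sentence) {
  m <- gregexpr("[^[:space:]]+", sentence)[[1]]
  if (m[1] == -1L) return(data.frame(token = character(0), start = integer(0)))
  data.frame(
    token = regmatches(sentence, gregexpr("[^[:space:]]+", sentence))[[1]],
    start = as.integer(m),
    stringsAsFactors = FALSE
  )
}

# Gazetteer matching within one sentence: scan token positions left to
# right, at each position try the longest dictionary entry first; matched
# spans are consumed so no emitted span is contained in another.
.match_dictionary <- function(sentence, dict_tokens) {
  toks <- .tokenize_offsets(sentence)$token
  toks_norm <- normalize_term(toks)
  n <- length(toks_norm)
  if (n == 0L) return(character(0))
  max_len <- max(vapply(dict_tokens, length, integer(1)))
  dict_keys <- vapply(dict_tokens, paste, character(1), collapse = " ")
  hits <- character(0)
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    for (len in seq(min(max_len, n - i + 1L), 1L)) {
      cand <- paste(toks_norm[i:(i + len - 1L)], collapse = " ")
      if (cand %in% dict_keys) {
        hits <- c(hits, cand)
        i <- i + len
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  hits
}

# Very small heuristic noun-phrase chunker: maximal runs of lower-case
# alphabetic tokens not in a stop list, emitted as candidate entities.
.chunker_stopwords <- c(
  "a", "an", "the", "and", "or", "but", "of", "in", "on", "for", "with",
  "to", "from", "by", "at", "as", "is", "are", "was", "were", "be",
  "been", "has", "have", "had", "that", "this", "these", "those", "we",
  "it", "its", "their", "our", "which", "who", "than", "then", "there",
  "not", "no", "can", "may", "might", "also", "such", "both", "between",
  "into", "over", "under", "after", "before", "during", "whereas"
)

.match_chunker <- function(sentence) {
  toks <- normalize_term(.tokenize_offsets(sentence)$token)
  keep <- nzchar(toks) & grepl("^[a-z][a-z-]*$", toks) &
    !(toks %in% .chunker_stopwords)
  if (!any(keep)) return(character(0))
  runs <- rle(keep)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- character(0)
  for (k in which(runs$values)) {
    span <- toks[starts[k]:ends[k]]
    if (length(span) >= 1L) out <- c(out, paste(span, collapse = " "))
  }
  out
}

#' Extract entity mentions from a document
#'
#' Emits one mention per surface occurrence (a term occurring twice in one
#' sentence yields two rows, which is what makes per-document
#' co-occurrence scores additive over occurrences). In dictionary mode,
#' matching is longest-match-wins: a shorter dictionary entry contained in
#' a longer matched span is not additionally emitted.
#'
#' @param doc A [document()].
#' @param config An [extractor_config()].
#' @return Data frame with columns `term`, `doc_id`, `sentence_idx`.
#' @export
extract_mentions <- function(doc, config) {
  stopifnot(inherits(doc, "litnet_document"),
            inherits(config, "litnet_extractor_config"))
  rows <- list()
  if (config$mode == "external") {
    ann <- read_annotations_tsv(config$annotation_path)
    ann <- ann[ann$doc_id == doc$doc_id, , drop = FALSE]
    bad <- ann$sentence_idx < 1L | ann$sentence_idx > length(doc$sentences)
    if (any(bad)) stop("annotation sentence index out of range for doc ",
                       doc$doc_id)
    return(ann[, c("term", "doc_id", "sentence_idx")])
  }
  if (config$mode == "dictionary") {
    dict <- config$dictionary[nzchar(config$dictionary)]
    if (length(dict) == 0L)
      return(data.frame(term = character(0), doc_id = character(0),
                        sentence_idx = integer(0)))
    dict_tokens <- strsplit(dict, " ", fixed = TRUE)
    for (i in seq_along(doc$sentences)) {
      hits <- .match_dictionary(doc$sentences[i], dict_tokens)
      for (h in hits)
        rows[[length(rows) + 1L]] <- list(term = h, idx = i)
    }
  } else {  # chunker
    for (i in seq_along(doc$sentences)) {
      hits <- .match_chunker(doc$sentences[i])
      for (h in hits)
        rows[[length(rows) + 1L]] <- list(term = h, idx = i)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(term = character(0), doc_id = character(0),
                      sentence_idx = integer(0)))
  data.frame(
    term = vapply(rows, `[[`, character(1), "term"),
    doc_id = doc$doc_id,
    sentence_idx = vapply(rows, `[[`, integer(1), "idx"),
    stringsAsFactors = FALSE
  )
}

#' Extract mentions for a whole corpus
#'
#' @param corpus List of documents.
#' @param config An [extractor_config()].
#' @return Data frame with columns `term`, `doc_id`, `sentence_idx`.
#' @export
extract_corpus_mentions <- function(corpus, config) {
  do.call(rbind, c(lapply(corpus, extract_mentions, config = config),
                   make.row.names = FALSE))
}

#' Read externally produced mention annotations
#'
#' Expected format: UTF-8 TSV with a header line and columns `doc_id`,
#' `sentence_idx`, `term`. Terms are normalised on load.
#'
#' @param path TSV file path.
#' @return Data frame with columns `term`, `doc_id`, `sentence_idx`.
#' @export
read_annotations_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(doc_id = "character"))
  need <- c("doc_id", "sentence_idx", "term")
  if (!all(need %in% names(df)))
    stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
  df$term <- normalize_term(df$term)
  df <- df[nzchar(df$term), , drop = FALSE]
  df$sentence_idx <- as.integer(df$sentence_idx)
  df[, c("term", "doc_id", "sentence_idx")]
}
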