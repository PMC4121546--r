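# Corpus ingestion: Medline/PubMed XML exports or one-abstract-per-file
# plain text, sentence segmentation, and corpus-level statistics.

#' Construct a document
#'
#' A document is a sentence-segmented abstract together with a provenance
#' identifier (a PubMed ID for Medline input, a file stem for plain text).
#' Sentence indices are 1-based and contiguous.
#'
#' @param doc_id Provenance identifier (non-empty string).
#' @param sentences Character vector of sentences, in order.
#' @param title Optional article title.
#' @return An object of class `litnet_document`.
#' @export
document <- function(doc_id, sentences, title = NULL) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id))
  sentences <- as.character(sentences)
  structure(
    list(doc_id = doc_id, title = title, sentences = sentences),
    class = "litnet_document"
  )
}

#' @export
print.litnet_document <- function(x, ...) {
  cat(sprintf("<document %s: %d sentences>\n", x$doc_id, length(x$sentences)))
  invisible(x)
}

# Abbreviations that never terminate a sentence even though they end in a
# period. Matching is case-insensitive on the token preceding the break.
.non_splitting_abbrev <- c(
  "e.g", "i.e", "cf", "vs", "etc", "et al", "al", "fig", "figs", "eq",
  "eqs", "ref", "refs", "no", "nos", "approx", "ca", "dr", "prof", "mr",
  "mrs", "ms", "st", "inc", "ltd", "dept", "univ", "resp", "wt", "mol",
  "spp", "sp", "var", "ssp"
)

#' Segment text into sentences
#'
#' Rule-based splitter: a sentence ends at `.`, `?`, `!` or `;` followed by
#' whitespace and (for `.`) an upper-case letter, digit or opening bracket,
#' unless the period terminates a known abbreviation (e.g. "e.g.", "et al.",
#' "Fig.") or a single initial. Numbering is 1-based and contiguous;
#' concatenating the sentences (with single spaces) reconstructs the text
#' modulo the collapsed inter-sentence whitespace.
#'
#' @param text A single character string.
#' @return Character vector of sentences (empty for empty input).
#' @export
segment_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("[[:space:]]+", " ", trimws(text))
  if (!nzchar(text)) return(character(0))

  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  breaks <- integer(0)
  for (i in seq_len(n - 1L)) {
    ch <- chars[i]
    if (!ch %in% c(".", "?", "!", ";")) next
    if (chars[i + 1L] != " ") next
    nxt <- if (i + 2L <= n) chars[i + 2L] else ""
    if (ch == ".") {
      # require a plausible sentence opener after the break
      if (!grepl("^[A-Z0-9(\\[\"']$", nxt)) next
      prefix <- substr(text, max(1L, i - 12L), i - 1L)
      last_tok <- sub(".*[[:space:]]", "", prefix)
      if (tolower(last_tok) %in% .non_splitting_abbrev) next
      # single initial inside a name ("Jeon B. Smith"), i.e. a lone
      # capital preceded by a capitalised word
      if (grepl("[A-Z][[:alpha:]]+[[:space:]][A-Z]$", prefix)) next
      two_tok <- sub(".*[[:space:]]([[:alpha:]]+[[:space:]][[:alpha:]]+)$",
                     "\\1", prefix)
      if (tolower(two_tok) %in% .non_splitting_abbrev) next
    }
    breaks <- c(breaks, i)
  }

  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  out <- character(length(starts))
  for (k in seq_along(starts)) {
    out[k] <- trimws(substr(text, starts[k], ends[k]))
  }
  out[nzchar(out)]
}

#' Read abstracts from a Medline/PubMed XML export
#'
#' Parses a `PubmedArticleSet` (or `ArticleSet`-like) XML file as produced
#' by PubMed's *send to file* feature. One document is produced per
#' citation with a non-empty abstract; citations lacking an abstract are
#' skipped with a warning. Multi-part abstracts (several `AbstractText`
#' nodes) are concatenated in order.
#'
#' @param path Path to the XML file.
#' @return List of [document()] objects.
#' @export
read_medline_xml <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0L) return(list())
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) stop("malformed XML in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  citations <- xml2::xml_find_all(doc, ".//MedlineCitation")
  out <- list()
  for (cit in citations) {
    pmid <- xml2::xml_text(xml2::xml_find_first(cit, "./PMID"))
    abst <- xml2::xml_find_all(cit, ".//Article/Abstract/AbstractText")
    text <- paste(trimws(xml2::xml_text(abst)), collapse = " ")
    if (!nzchar(trimws(text))) {
      warning("citation ", pmid, " has no abstract; skipped", call. = FALSE)
      next
    }
    title <- xml2::xml_text(
      xml2::xml_find_first(cit, ".//Article/ArticleTitle"))
    out[[length(out) + 1L]] <- document(
      doc_id = pmid,
      sentences = segment_sentences(text),
      title = if (is.na(title)) NULL else title
    )
  }
  ids <- vapply(out, function(d) d$doc_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate PMIDs in corpus: ",
                               paste(unique(ids[duplicated(ids)]),
                                     collapse = ", "))
  out
}

#' Read abstracts from a directory of plain-text files
#'
#' Each `*.txt` file holds one abstract; the document identifier is the
#' file stem. Files are processed in lexicographic order. Unreadable or
#' whitespace-only files are skipped with a warning.
#'
#' @param dir Directory containing UTF-8 text files.
#' @return List of [document()] objects, ordered by file name.
#' @export
read_plaintext <- function(dir) {
  stopifnot(dir.exists(dir))
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  out <- list()
  for (f in files) {
    text <- tryCatch(
      paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = " "),
      error = function(e) NA_character_
    )
    if (is.na(text) || !validUTF8(text)) {
      warning("cannot read '", f, "' as UTF-8 text; skipped", call. = FALSE)
      next
    }
    if (!nzchar(trimws(text))) {
      warning("file '", f, "' is empty; skipped", call. = FALSE)
      next
    }
    stem <- sub("\\.txt$", "", basename(f))
    out[[length(out) + 1L]] <- document(stem, segment_sentences(text))
  }
  out
}

#' Write documents as plain text files
#'
#' Inverse of [read_plaintext()]: one `<doc_id>.txt` per document, one
#' sentence per line (so re-reading yields identical sentence lists).
#'
#' @param corpus List of documents.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
write_plaintext <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(corpus, function(d) {
    p <- file.path(dir, paste0(d$doc_id, ".txt"))
    writeLines(d$sentences, p, useBytes = TRUE)
    p
  }, character(1))
  invisible(paths)
}

#' Count word tokens in a corpus
#'
#' Tokens are whitespace-delimited strings that contain at least one
#' alphanumeric character after stripping surrounding punctuation.
#'
#' @param corpus List of documents.
#' @return Integer token count.
#' @export
count_tokens <- function(corpus) {
  n <- 0L
  for (d in corpus) {
    toks <- unlist(strsplit(d$sentences, "[[:space:]]+"))
    toks <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", toks)
    n <- n + sum(grepl("[[:alnum:]]", toks))
  }
  n
}

#' Corpus and knowledge-base statistics
#'
#' Computes the basic counts (sources, tokens, basic statements, lexicon,
#' co-occurrence and similarity statements) and the six derived ratios
#' T/S, B/S, L/T, SM/KB, KB/S and KB/L, each the exact quotient of the
#' corresponding counts.
#'
#' @param corpus List of documents.
#' @param basic_statements Data frame of basic statements (see
#'   [extract_basic_statements()]).
#' @param kb Knowledge base data frame (see [build_kb()]); may be `NULL`
#'   when only text-level statistics are wanted.
#' @return A `litnet_corpus_stats` object (a named list of counts and
#'   ratios).
#' @export
corpus_statistics <- function(corpus, basic_statements = NULL, kb = NULL) {
  n_src <- length(corpus)
  if (n_src == 0L) stop("empty corpus: ratios are undefined")
  n_tok <- count_tokens(corpus)
  n_bc <- if (is.null(basic_statements)) 0L else nrow(basic_statements)
  lex <- if (is.null(basic_statements) || n_bc == 0L) character(0) else
    unique(c(basic_statements$term_a, basic_statements$term_b))
  n_lex <- length(lex)
  n_cooc <- if (is.null(kb)) 0L else sum(kb$relation == "cooc")
  n_sim <- if (is.null(kb)) 0L else sum(kb$relation == "sim")
  n_kb <- n_cooc + n_sim
  structure(list(
    n_sources = n_src, n_tokens = n_tok, n_basic_statements = n_bc,
    lexicon_size = n_lex, n_kb_cooc = n_cooc, n_kb_sim = n_sim,
    t_per_s = n_tok / n_src,
    b_per_s = n_bc / n_src,
    l_per_t = if (n_tok > 0) n_lex / n_tok else NA_real_,
    sm_per_kb = if (n_kb > 0) n_sim / n_kb else NA_real_,
    kb_per_s = n_kb / n_src,
    kb_per_l = if (n_lex > 0) n_kb / n_lex else NA_real_
  ), class = "litnet_corpus_stats")
}

#' @export
print.litnet_corpus_stats <- function(x, ...) {
  cat("corpus statistics:\n")
  cat(sprintf("  SRC=%d TOK=%d BC=%d LEX=%d KB_cooc=%d KB_sim=%d\n",
              x$n_sources, x$n_tokens, x$n_basic_statements,
              x$lexicon_size, x$n_kb_cooc, x$n_kb_sim))
  cat(sprintf("  T/S=%.3f B/S=%.3f L/T=%.3f SM/KB=%.3f KB/S=%.3f KB/L=%.3f\n",
              x$t_per_s, x$b_per_s, x$l_per_t, x$sm_per_kb, x$kb_per_s,
              x$kb_per_l))
  invisible(x)
}

#' Write corpus statistics as a one-row TSV
#'
#' Fixed column order: SRC, TOK, BC, LEX, KB_cooc, KB_sim, T/S, B/S, L/T,
#' SM/KB, KB/S, KB/L.
#'
#' @param stats A `litnet_corpus_stats` object.
#' @param path Output file path.
#' @export
write_corpus_statistics <- function(stats, path) {
  df <- data.frame(
    SRC = stats$n_sources, TOK = stats$n_tokens,
    BC = stats$n_basic_statements, LEX = stats$lexicon_size,
    KB_cooc = stats$n_kb_cooc, KB_sim = stats$n_kb_sim,
    `T/S` = stats$t_per_s, `B/S` = stats$b_per_s, `L/T` = stats$l_per_t,
    `SM/KB` = stats$sm_per_kb, `KB/S` = stats$kb_per_s,
    `KB/L` = stats$kb_per_l, check.names = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
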