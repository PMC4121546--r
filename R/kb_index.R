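# Knowledge-base indices: a symmetric term-term matrix of maximal
# statement weights, a binary term-statement incidence matrix, a
# statement-source provenance matrix, and a lemmatised full-text lookup
# over the canonical terms.

#' Build the three knowledge-base indices
#'
#' * term index: square symmetric sparse matrix over terms; entry (i, j)
#'   is the maximum weight among statements of all types between the two
#'   terms, 0 on the diagonal;
#' * statement index: terms x statements binary incidence matrix (each
#'   statement column has exactly two nonzero entries);
#' * provenance index: statements x sources matrix whose nonzero entries
#'   equal the statement's weight.
#'
#' @param kb A `litnet_kb` (see [build_kb()], [kb_from_statements()]).
#' @return A `litnet_indices` list: `term_index`, `statement_index`,
#'   `provenance_index` (sparse `Matrix::dgCMatrix`), `terms`,
#'   `statement_ids`, `sources`, `statements` (the statement table) and
#'   `fulltext` (the lookup structure from [build_fulltext_index()]).
#' @export
build_indices <- function(kb) {
  s <- kb$statements
  terms <- sort(unique(c(s$term_a, s$term_b)))
  m <- nrow(s)
  sources <- sort(unique(unlist(kb$provenance, use.names = FALSE)))
  if (m > 0L && anyNA(match(c(s$term_a, s$term_b), terms)))
    stop("statement references unknown term")

  ti <- Matrix::sparseMatrix(
    i = integer(0), j = integer(0), x = numeric(0),
    dims = c(length(terms), length(terms)),
    dimnames = list(terms, terms)
  )
  # max weight among statements of all types between each pair
  if (m > 0L) {
    key <- paste(pmin(s$term_a, s$term_b), pmax(s$term_a, s$term_b),
                 sep = "\r")
    w <- tapply(s$weight, key, max)
    parts <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
    ti <- Matrix::sparseMatrix(
      i = match(c(parts[, 1], parts[, 2]), terms),
      j = match(c(parts[, 2], parts[, 1]), terms),
      x = rep(as.numeric(w), 2L),
      dims = c(length(terms), length(terms)),
      dimnames = list(terms, terms)
    )
  }

  si <- Matrix::sparseMatrix(
    i = match(c(s$term_a, s$term_b), terms),
    j = rep(seq_len(m), 2L),
    x = 1,
    dims = c(length(terms), m),
    dimnames = list(terms, s$statement_id)
  )

  prov_i <- integer(0); prov_j <- integer(0); prov_x <- numeric(0)
  for (k in seq_len(m)) {
    src <- kb$provenance[[s$statement_id[k]]]
    prov_i <- c(prov_i, rep(k, length(src)))
    prov_j <- c(prov_j, match(src, sources))
    prov_x <- c(prov_x, rep(s$weight[k], length(src)))
  }
  pi_ <- Matrix::sparseMatrix(
    i = prov_i, j = prov_j, x = prov_x,
    dims = c(m, length(sources)),
    dimnames = list(s$statement_id, sources)
  )

  structure(list(
    term_index = ti, statement_index = si, provenance_index = pi_,
    terms = terms, statement_ids = s$statement_id, sources = sources,
    statements = s, fulltext = build_fulltext_index(terms),
    version = "litnet-index-1"
  ), class = "litnet_indices")
}

#' @export
print.litnet_indices <- function(x, ...) {
  cat(sprintf("<indices: %d terms, %d statements, %d sources>\n",
              length(x$terms), length(x$statement_ids), length(x$sources)))
  invisible(x)
}

#' Light English stemmer for term lookup
#'
#' A conservative plural ("s") stemmer: strips a final `'s`, maps
#' `...ies -> ...y` and removes a final `s` unless the word ends in `ss`,
#' `us` or `is`. Enough to unify singular/plural spelling variants
#' ("parkinsonism" / "parkinsonisms") without an external stemming
#' library; applied token-wise to multi-word terms.
#'
#' @param x Character vector of words or multi-word terms.
#' @return Stemmed character vector.
#' @export
stem_term <- function(x) {
  stem_word <- function(w) {
    w <- sub("'s$", "", w)
    if (nchar(w) > 3 && grepl("ies$", w)) return(sub("ies$", "y", w))
    if (nchar(w) > 3 && grepl("s$", w) && !grepl("(ss|us|is)$", w))
      return(sub("s$", "", w))
    w
  }
  vapply(strsplit(tolower(x), " ", fixed = TRUE), function(toks)
    paste(vapply(toks, stem_word, character(1)), collapse = " "),
    character(1))
}

#' Build the full-text term lookup
#'
#' Maps stemmed variants of every canonical term back to the term; every
#' canonical term is retrievable by its own exact form.
#'
#' @param terms Character vector of canonical terms.
#' @return A `litnet_fulltext` list with `terms` and their `stems`.
#' @export
build_fulltext_index <- function(terms) {
  structure(list(terms = terms, stems = stem_term(terms)),
            class = "litnet_fulltext")
}

#' Look up canonical terms for a query string
#'
#' Supports: stem-equivalent matching (`"parkinsonism"` matches both
#' `"parkinsonism"` and `"parkinsonisms"`), trailing-`*` prefix wildcards
#' (`"park*"`), and boolean combinations `AND` / `OR` / `NOT` inside the
#' lookup string (applied over the crisp per-token match sets, with the
#' indexed vocabulary as NOT's universe).
#'
#' @param fulltext A `litnet_fulltext` (or `litnet_indices`, whose lookup
#'   is used).
#' @param query_term The lookup string.
#' @return Character vector of matching canonical terms (possibly empty).
#' @export
fulltext_match <- function(fulltext, query_term) {
  if (inherits(fulltext, "litnet_indices")) fulltext <- fulltext$fulltext
  q <- trimws(query_term)
  if (!nzchar(q)) return(character(0))
  toks <- strsplit(q, "[[:space:]]+")[[1]]
  ops <- toupper(toks) %in% c("AND", "OR", "NOT")
  if (any(ops)) {
    return(.fulltext_boolean(fulltext, toks, ops))
  }
  .fulltext_atomic(fulltext, q)
}

.fulltext_atomic <- function(fulltext, q) {
  q <- trimws(tolower(q))
  if (grepl("\\*$", q)) {  # before normalisation, which strips the star
    prefix <- normalize_term(sub("\\*$", "", q))
    return(fulltext$terms[startsWith(fulltext$terms, prefix)])
  }
  q <- normalize_term(q)
  if (!nzchar(q)) return(character(0))
  hit <- fulltext$stems == stem_term(q) | fulltext$terms == q
  fulltext$terms[hit]
}

# Boolean combinations inside one lookup string; grouped left to right,
# NOT binds to the following atom, AND before OR.
.fulltext_boolean <- function(fulltext, toks, ops) {
  # split token stream into atoms and operators
  items <- list(); cur <- character(0)
  for (i in seq_along(toks)) {
    if (ops[i]) {
      if (length(cur)) items[[length(items) + 1L]] <- paste(cur, collapse = " ")
      items[[length(items) + 1L]] <- toupper(toks[i])
      cur <- character(0)
    } else cur <- c(cur, toks[i])
  }
  if (length(cur)) items[[length(items) + 1L]] <- paste(cur, collapse = " ")
  universe <- fulltext$terms
  eval_atom <- function(x) .fulltext_atomic(fulltext, x)
  # NOT pass
  vals <- list(); i <- 1L
  while (i <= length(items)) {
    if (identical(items[[i]], "NOT")) {
      if (i == length(items)) stop("dangling NOT in term lookup")
      vals[[length(vals) + 1L]] <- setdiff(universe, eval_atom(items[[i + 1L]]))
      i <- i + 2L
    } else if (items[[i]] %in% c("AND", "OR")) {
      vals[[length(vals) + 1L]] <- items[[i]]; i <- i + 1L
    } else {
      vals[[length(vals) + 1L]] <- eval_atom(items[[i]]); i <- i + 1L
    }
  }
  # AND pass
  merged <- list(); i <- 1L
  while (i <= length(vals)) {
    v <- vals[[i]]
    if (is.character(v) && length(v) == 1L && identical(v, "AND"))
      stop("malformed boolean lookup")
    cur <- v; i <- i + 1L
    while (i + 1L <= length(vals) && identical(vals[[i]], "AND")) {
      cur <- intersect(cur, vals[[i + 1L]]); i <- i + 2L
    }
    merged[[length(merged) + 1L]] <- cur
    if (i <= length(vals) && identical(vals[[i]], "OR")) i <- i + 1L
  }
  sort(unique(unlist(merged)))
}

#' Export the indices as TSV files for audit
#'
#' Writes `term_index.tsv`, `statement_index.tsv` and
#' `provenance_index.tsv` (dense, row/column labelled) plus a
#' `version.txt` tag into `dir`.
#'
#' @param indices A `litnet_indices`.
#' @param dir Output directory.
#' @export
export_indices_tsv <- function(indices, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(mat, path) {
    df <- as.data.frame(as.matrix(mat))
    utils::write.table(cbind(id = rownames(df), df), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wr(indices$term_index, file.path(dir, "term_index.tsv"))
  wr(indices$statement_index, file.path(dir, "statement_index.tsv"))
  wr(indices$provenance_index, file.path(dir, "provenance_index.tsv"))
  writeLines(indices$version, file.path(dir, "version.txt"))
  invisible(dir)
}
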