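# Fuzzy boolean query language over the knowledge-base indices. Results
# are fuzzy sets (named numeric vectors of membership degrees in [0, 1]);
# an absent element has degree 0.

#' Parse a fuzzy boolean query
#'
#' Grammar: atoms are bare (possibly multi-word) or double-quoted term
#' strings; operators `AND`, `OR`, `NOT` (case-insensitive); parentheses
#' nest. Precedence `NOT > AND > OR`. `AND`/`OR` parse n-ary, `NOT` is
#' unary.
#'
#' @param text Query string.
#' @return A `litnet_query` tree: leaves are
#'   `list(type = "atom", term = ...)`, internal nodes
#'   `list(type = "op", op = "AND"|"OR"|"NOT", children = list(...))`.
#' @export
parse_query <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- .query_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L
  tree <- .parse_or(st)
  if (st$pos <= length(st$toks))
    stop("query syntax error at token ", st$pos, " ('",
         st$toks[[st$pos]]$value, "')")
  structure(tree, class = "litnet_query")
}

.query_tokenize <- function(text) {
  toks <- list(); i <- 1L; n <- nchar(text)
  push <- function(type, value, at)
    toks[[length(toks) + 1L]] <<- list(type = type, value = value, at = at)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^[[:space:]]$", ch)) { i <- i + 1L; next }
    if (ch == "(") { push("lpar", "(", i); i <- i + 1L; next }
    if (ch == ")") { push("rpar", ")", i); i <- i + 1L; next }
    if (ch == "\"") {
      j <- regexpr("\"", substr(text, i + 1L, n), fixed = TRUE)
      if (j == -1L) stop("unbalanced quote at position ", i)
      push("word", substr(text, i + 1L, i + j - 1L), i)
      i <- i + j + 1L
      next
    }
    m <- regexpr("^[^()\"[:space:]]+", substr(text, i, n))
    w <- regmatches(substr(text, i, n), m)
    up <- toupper(w)
    if (up %in% c("AND", "OR", "NOT")) push(tolower(up), up, i)
    else push("word", w, i)
    i <- i + attr(m, "match.length")
  }
  toks
}

.peek <- function(st) if (st$pos <= length(st$toks)) st$toks[[st$pos]] else NULL

.parse_or <- function(st) {
  children <- list(.parse_and(st))
  while (!is.null(tk <- .peek(st)) && tk$type == "or") {
    st$pos <- st$pos + 1L
    children[[length(children) + 1L]] <- .parse_and(st)
  }
  if (length(children) == 1L) children[[1]]
  else list(type = "op", op = "OR", children = children)
}

.parse_and <- function(st) {
  children <- list(.parse_not(st))
  while (!is.null(tk <- .peek(st)) && tk$type == "and") {
    st$pos <- st$pos + 1L
    children[[length(children) + 1L]] <- .parse_not(st)
  }
  if (length(children) == 1L) children[[1]]
  else list(type = "op", op = "AND", children = children)
}

.parse_not <- function(st) {
  tk <- .peek(st)
  if (!is.null(tk) && tk$type == "not") {
    st$pos <- st$pos + 1L
    list(type = "op", op = "NOT", children = list(.parse_not(st)))
  } else .parse_primary(st)
}

.parse_primary <- function(st) {
  tk <- .peek(st)
  if (is.null(tk)) stop("query syntax error: unexpected end of input")
  if (tk$type == "lpar") {
    st$pos <- st$pos + 1L
    inner <- .parse_or(st)
    close <- .peek(st)
    if (is.null(close) || close$type != "rpar")
      stop("unbalanced parentheses at position ", tk$at)
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tk$type != "word")
    stop("query syntax error at position ", tk$at, ": unexpected '",
         tk$value, "'")
  words <- character(0)
  while (!is.null(tk <- .peek(st)) && tk$type == "word") {
    words <- c(words, tk$value)
    st$pos <- st$pos + 1L
  }
  list(type = "atom", term = paste(words, collapse = " "))
}

#' Evaluate an atomic query against the term index
#'
#' Full-text-matches the query term to canonical terms (stemming and
#' wildcards, see [fulltext_match()]) and returns the element-wise
#' maximum of the matched terms' rows of the term index: the fuzzy set of
#' entities related by any relation to the query term.
#'
#' @param term Atomic query string.
#' @param indices A `litnet_indices`.
#' @return Named numeric fuzzy set (possibly empty).
#' @export
eval_atomic <- function(term, indices) {
  hits <- fulltext_match(indices$fulltext, term)
  if (length(hits) == 0L) return(stats::setNames(numeric(0), character(0)))
  rows <- indices$term_index[hits, , drop = FALSE]
  degrees <- apply(as.matrix(rows), 2, max)
  degrees[degrees > 0]
}

#' Evaluate a query tree to a fuzzy term set
#'
#' Fuzzy semantics with max/min as t-conorm/t-norm: `OR` is element-wise
#' maximum, `AND` element-wise minimum, `NOT` the complement `1 - degree`
#' over the universe of all indexed terms.
#'
#' @param tree A `litnet_query` from [parse_query()] (or a raw node).
#' @param indices A `litnet_indices`.
#' @return Named numeric fuzzy set over the indexed terms (zero-degree
#'   elements dropped).
#' @export
eval_tree <- function(tree, indices) {
  res <- .eval_node(tree, indices)
  res[res > 0]
}

.eval_node <- function(node, indices) {
  if (node$type == "atom") return(eval_atomic(node$term, indices))
  kids <- lapply(node$children, .eval_node, indices = indices)
  switch(node$op,
    OR = fuzzy_union(kids),
    AND = fuzzy_intersection(kids),
    NOT = fuzzy_complement(kids[[1]], universe = indices$terms)
  )
}

#' Fuzzy set algebra
#'
#' `fuzzy_union()` takes the element-wise maximum over a list of fuzzy
#' sets, `fuzzy_intersection()` the element-wise minimum (absent elements
#' count as 0), and `fuzzy_complement()` maps every universe element `x`
#' to `1 - degree(x)`.
#'
#' @param sets List of named numeric fuzzy sets.
#' @param set A named numeric fuzzy set.
#' @param universe Character vector of all elements (for the complement).
#' @return A named numeric fuzzy set.
#' @export
fuzzy_union <- function(sets) {
  elems <- unique(unlist(lapply(sets, names)))
  if (length(elems) == 0L) return(stats::setNames(numeric(0), character(0)))
  out <- stats::setNames(numeric(length(elems)), elems)
  for (s in sets) {
    if (length(s) == 0L) next
    out[names(s)] <- pmax(out[names(s)], s)
  }
  out
}

#' @rdname fuzzy_union
#' @export
fuzzy_intersection <- function(sets) {
  elems <- unique(unlist(lapply(sets, names)))
  if (length(elems) == 0L) return(stats::setNames(numeric(0), character(0)))
  out <- stats::setNames(rep(Inf, length(elems)), elems)
  for (s in sets) {
    full <- stats::setNames(numeric(length(elems)), elems)
    if (length(s)) full[names(s)[names(s) %in% elems]] <-
        s[names(s) %in% elems]
    out <- pmin(out, full)
  }
  out[out > 0 & is.finite(out)]
}

#' @rdname fuzzy_union
#' @export
fuzzy_complement <- function(set, universe) {
  out <- stats::setNames(rep(1, length(universe)), universe)
  common <- intersect(names(set), universe)
  out[common] <- 1 - set[common]
  out
}

#' Rank a fuzzy set
#'
#' Descending by degree, ties broken by element name for determinism.
#'
#' @param set Named numeric fuzzy set.
#' @return The set sorted descending.
#' @export
rank_fuzzy <- function(set) {
  if (length(set) == 0L) return(set)
  set[order(-set, names(set))]
}

#' Fuzzy statement set for a term result set
#'
#' Restricts the term result set to its `top_k` highest-degree terms, then
#' scores every statement as the normalised dot product of the restricted
#' degrees with the statement's (binary) column of the statement index.
#' With two terms per statement and normalisation `1/2`, this is the
#' arithmetic mean of the two term degrees. Zero-degree statements are
#' excluded.
#'
#' @param R_T Named numeric fuzzy set of terms.
#' @param indices A `litnet_indices`.
#' @param top_k Number of top terms retained (default 5).
#' @return Named numeric fuzzy set of statement ids, ranked descending.
#' @export
statements_for_terms <- function(R_T, indices, top_k = 5L) {
  if (length(R_T) == 0L) return(stats::setNames(numeric(0), character(0)))
  R_T <- rank_fuzzy(R_T)
  R_T <- R_T[seq_len(min(top_k, length(R_T)))]
  tvec <- stats::setNames(numeric(length(indices$terms)), indices$terms)
  common <- intersect(names(R_T), indices$terms)
  tvec[common] <- R_T[common]
  w <- as.numeric(Matrix::crossprod(indices$statement_index, tvec)) / 2
  names(w) <- indices$statement_ids
  rank_fuzzy(w[w > 0])
}

#' Fuzzy provenance set for a statement result set
#'
#' Restricts the statement result set to its `top_k` highest-degree
#' statements, computes `w_P = sum_j w_S_j * p_(j,i)` against the
#' provenance index, and normalises by the maximum so the best source has
#' degree 1.
#'
#' @param R_S Named numeric fuzzy set of statement ids.
#' @param indices A `litnet_indices`.
#' @param top_k Number of top statements retained (default 7).
#' @return Named numeric fuzzy set of source ids, ranked descending.
#' @export
provenance_for_statements <- function(R_S, indices, top_k = 7L) {
  if (length(R_S) == 0L) return(stats::setNames(numeric(0), character(0)))
  R_S <- rank_fuzzy(R_S)
  R_S <- R_S[seq_len(min(top_k, length(R_S)))]
  svec <- stats::setNames(numeric(length(indices$statement_ids)),
                          indices$statement_ids)
  common <- intersect(names(R_S), indices$statement_ids)
  svec[common] <- R_S[common]
  w <- as.numeric(Matrix::crossprod(indices$provenance_index, svec))
  names(w) <- indices$sources
  w <- w[w > 0]
  if (length(w) == 0L) return(stats::setNames(numeric(0), character(0)))
  rank_fuzzy(w / max(w))
}

#' Run a full query: terms, statements and ranked provenance
#'
#' @param indices A `litnet_indices`.
#' @param text Query string (see [parse_query()]).
#' @param top_terms Top term results kept for statement expansion
#'   (default 5).
#' @param top_statements Top statements kept for provenance expansion
#'   (default 7).
#' @return A `litnet_result` list with ranked fuzzy sets `terms`,
#'   `statements`, `sources`.
#' @export
run_query <- function(indices, text, top_terms = 5L, top_statements = 7L) {
  tree <- parse_query(text)
  R_T <- rank_fuzzy(eval_tree(tree, indices))
  R_S <- statements_for_terms(R_T, indices, top_terms)
  R_P <- provenance_for_statements(R_S, indices, top_statements)
  structure(list(terms = R_T, statements = R_S, sources = R_P,
                 query = text),
            class = "litnet_result")
}

#' @export
print.litnet_result <- function(x, ...) {
  cat("query:", x$query, "\n")
  show <- function(lbl, s, k = 5L) {
    cat(lbl, ":\n", sep = "")
    for (i in seq_len(min(k, length(s))))
      cat(sprintf("  %-50s %.3f\n", names(s)[i], s[i]))
  }
  show("terms", x$terms)
  show("statements", x$statements)
  show("sources", x$sources)
  invisible(x)
}
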