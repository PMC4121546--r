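# MeSH-style taxonomy support: loading descriptor data (ASCII or XML),
# cluster assignment of free-text entities, and tree-code semantic
# similarity.

#' Construct a taxonomy from a term -> tree-code mapping
#'
#' @param codes Named list: term (canonical) -> character vector of
#'   dot-separated tree codes (e.g. `"C10.228.662"`).
#' @return A `litnet_taxonomy` with a lemmatised lookup structure.
#' @export
taxonomy <- function(codes) {
  terms <- normalize_term(names(codes))
  keep <- nzchar(terms)
  codes <- stats::setNames(codes[keep], terms[keep])
  structure(list(codes = codes,
                 terms = names(codes),
                 stems = stem_term(names(codes))),
            class = "litnet_taxonomy")
}

#' @export
print.litnet_taxonomy <- function(x, ...) {
  cat(sprintf("<taxonomy: %d terms, %d tree codes>\n", length(x$codes),
              length(unique(unlist(x$codes)))))
  invisible(x)
}

#' Load MeSH descriptor data
#'
#' Two input formats are supported:
#' * ASCII descriptor records (blank-line separated) with `MH = ` (main
#'   heading), `ENTRY = ` / `PRINT ENTRY = ` (synonyms; only the field
#'   before the first `|` is used) and `MN = ` (tree number) lines;
#' * descriptor XML with `DescriptorRecord / DescriptorName / String`,
#'   `TermList/Term/String` synonyms and `TreeNumberList/TreeNumber`
#'   nodes.
#'
#' Terms and synonyms map to the union of the record's tree codes; records
#' without tree numbers are skipped with a warning.
#'
#' @param path Descriptor file path.
#' @param format `"ascii"` or `"xml"` (guessed from the extension by
#'   default).
#' @return A `litnet_taxonomy`.
#' @export
load_mesh <- function(path, format = c("auto", "ascii", "xml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xml$", path, ignore.case = TRUE)) "xml"
      else "ascii"
  codes <- if (format == "xml") .load_mesh_xml(path) else
    .load_mesh_ascii(path)
  taxonomy(codes)
}

.load_mesh_ascii <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  recs <- split(lines, cumsum(!nzchar(trimws(lines))))
  out <- list()
  for (rec in recs) {
    rec <- rec[nzchar(trimws(rec))]
    if (!length(rec)) next
    field <- function(tag) {
      v <- rec[startsWith(rec, paste0(tag, " = "))]
      sub("^[A-Z ]+ = ", "", v)
    }
    mh <- field("MH")
    if (!length(mh)) next
    mns <- field("MN")
    if (!length(mns)) {
      warning("descriptor '", mh[1], "' has no tree numbers; skipped",
              call. = FALSE)
      next
    }
    entries <- vapply(strsplit(c(field("ENTRY"), field("PRINT ENTRY")),
                               "|", fixed = TRUE),
                      `[[`, character(1), 1L)
    for (t in unique(c(mh[1], entries)))
      out[[t]] <- sort(unique(c(out[[t]], mns)))
  }
  out
}

.load_mesh_xml <- function(path) {
  doc <- xml2::read_xml(path)
  out <- list()
  for (rec in xml2::xml_find_all(doc, ".//DescriptorRecord")) {
    name <- xml2::xml_text(
      xml2::xml_find_first(rec, "./DescriptorName/String"))
    mns <- xml2::xml_text(
      xml2::xml_find_all(rec, "./TreeNumberList/TreeNumber"))
    if (!length(mns)) {
      warning("descriptor '", name, "' has no tree numbers; skipped",
              call. = FALSE)
      next
    }
    syns <- xml2::xml_text(xml2::xml_find_all(rec, ".//Term/String"))
    for (t in unique(c(name, syns)))
      out[[t]] <- sort(unique(c(out[[t]], mns)))
  }
  out
}

#' Assign taxonomy clusters to an entity term
#'
#' Looks the term up in the lemmatised index (exact normalised form, then
#' stem-equivalent form). Failing that, tries sub-terms: contiguous token
#' n-grams, longest first (leftmost first within a length), taking the
#' first that matches. The specific clusters `C_S` are the matched tree
#' codes; the abstract clusters `C_A` are their top-level segments.
#'
#' @param entity Free-text entity term.
#' @param taxonomy A `litnet_taxonomy`.
#' @return List with `abstract` and `specific` character vectors (both
#'   empty when nothing matches).
#' @export
assign_clusters <- function(entity, taxonomy) {
  codes <- .lookup_codes(entity, taxonomy)
  if (is.null(codes)) {
    toks <- strsplit(normalize_term(entity), " ", fixed = TRUE)[[1]]
    n <- length(toks)
    for (len in rev(seq_len(max(n - 1L, 0L)))) {
      for (start in seq_len(n - len + 1L)) {
        sub <- paste(toks[start:(start + len - 1L)], collapse = " ")
        codes <- .lookup_codes(sub, taxonomy)
        if (!is.null(codes)) break
      }
      if (!is.null(codes)) break
    }
  }
  if (is.null(codes))
    return(list(abstract = character(0), specific = character(0)))
  list(abstract = sort(unique(vapply(strsplit(codes, ".", fixed = TRUE),
                                     `[[`, character(1), 1L))),
       specific = sort(unique(codes)))
}

.lookup_codes <- function(term, taxonomy) {
  t <- normalize_term(term)
  if (!nzchar(t)) return(NULL)
  hit <- which(taxonomy$terms == t)
  if (!length(hit)) hit <- which(taxonomy$stems == stem_term(t))
  if (!length(hit)) return(NULL)
  sort(unique(unlist(taxonomy$codes[hit])))
}

#' Tree-code semantic similarity of two terms
#'
#' For tree codes `c_x`, `c_y` (dot-separated segment paths, depth =
#' number of segments), the code-pair similarity is
#' `2 * depth(LCS) / (depth(c_x) + depth(c_y))` where the least common
#' subsumer LCS is the longest shared segment prefix. The term similarity
#' is the maximum over all pairs of the two terms' specific cluster codes;
#' it is 0 when either term has no assignment or no code pair shares even
#' the top-level segment, and 1 for identical codes.
#'
#' @param x,y Entity terms.
#' @param taxonomy A `litnet_taxonomy`.
#' @return Similarity in `[0, 1]`.
#' @export
mesh_similarity <- function(x, y, taxonomy) {
  cx <- assign_clusters(x, taxonomy)$specific
  cy <- assign_clusters(y, taxonomy)$specific
  code_set_similarity(cx, cy)
}

#' Similarity of two tree-code sets
#'
#' The code-pair maximum described in [mesh_similarity()], operating
#' directly on code sets.
#'
#' @param cx,cy Character vectors of tree codes.
#' @return Similarity in `[0, 1]`.
#' @export
code_set_similarity <- function(cx, cy) {
  if (length(cx) == 0L || length(cy) == 0L) return(0)
  sx <- strsplit(cx, ".", fixed = TRUE)
  sy <- strsplit(cy, ".", fixed = TRUE)
  best <- 0
  for (a in sx) {
    for (b in sy) {
      k <- 0L
      for (i in seq_len(min(length(a), length(b)))) {
        if (a[i] == b[i]) k <- i else break
      }
      if (k > 0L) best <- max(best, 2 * k / (length(a) + length(b)))
    }
  }
  best
}
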