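# Independent oracles and small fixture builders shared across tests.
# These deliberately re-derive quantities by brute force, not by calling
# the implementation under test.

# naive O(n^2) per-document co-occurrence score
oracle_cooc_score <- function(a, b, window = 3) {
  s <- 0
  for (i in a) for (j in b) {
    d <- abs(i - j)
    if (d <= window) s <- s + 1 / (d + 1)
  }
  s
}

# re-aggregate fPMI from raw basic-statement tuples
oracle_fpmi_table <- function(basic) {
  n <- nrow(basic)
  keys <- unique(paste(basic$term_a, basic$term_b, sep = "|"))
  out <- numeric(0)
  for (k in keys) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    sel <- basic$term_a == parts[1] & basic$term_b == parts[2]
    joint <- sum(basic$score[sel])
    freq <- sum(sel)
    mx <- sum(basic$score[basic$term_a == parts[1] |
                            basic$term_b == parts[1]])
    my <- sum(basic$score[basic$term_a == parts[2] |
                            basic$term_b == parts[2]])
    out[k] <- freq * log2((joint / n) / ((mx / n) * (my / n)))
  }
  out
}

# exhaustive simple-path enumeration related-article oracle
oracle_related_index <- function(graph, prov, max_len = 3, prune = 0.1) {
  nodes <- igraph::V(graph)$name
  W <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  el <- igraph::as_data_frame(graph, what = "edges")
  if (nrow(el)) {
    W[cbind(el$from, el$to)] <- el$weight
    W[cbind(el$to, el$from)] <- el$weight
  }
  best <- matrix(0, length(nodes), length(nodes),
                 dimnames = list(nodes, nodes))
  dfs <- function(path, weight) {
    cur <- path[length(path)]
    if (length(path) > 1L) {
      s <- path[1]
      if (weight > best[s, cur]) best[s, cur] <<- weight
    }
    if (length(path) > max_len) return()
    for (nb in nodes[W[cur, ] > 0]) {
      if (nb %in% path) next
      dfs(c(path, nb), weight * W[cur, nb])
    }
  }
  for (s in nodes) dfs(s, 1)
  sources <- sort(unique(unlist(prov)))
  MP <- matrix(0, length(sources), length(sources),
               dimnames = list(sources, sources))
  for (x in nodes) for (y in nodes) {
    if (x == y || best[x, y] == 0) next
    for (p in prov[[x]]) for (q in prov[[y]]) {
      if (p == q) next
      MP[p, q] <- max(MP[p, q], best[x, y])
    }
  }
  MP[MP < prune] <- 0
  out <- list()
  for (p in sources) {
    w <- MP[p, ]; w <- w[w > 0]
    if (!length(w)) next
    ord <- order(-w, names(w))
    out[[p]] <- data.frame(related = names(w)[ord],
                           weight = as.numeric(w)[ord],
                           stringsAsFactors = FALSE)
  }
  out
}

related_to_df <- function(idx) {
  if (length(idx) == 0L)
    return(data.frame(pmid = character(0), related = character(0),
                      weight = numeric(0)))
  df <- do.call(rbind, lapply(names(idx), function(p)
    cbind(pmid = p, idx[[p]])))
  df[order(df$pmid, df$related), ]
}

# direct-formula cluster entropy over a list of cluster sets
oracle_entropy <- function(sets) {
  counts <- table(unlist(sets))
  if (!length(counts)) return(0)
  q <- as.numeric(counts) / sum(counts)
  -sum(q * log2(q))
}

# random fuzzy set over a fixed element universe
random_fuzzy <- function(universe, p = 0.6) {
  sel <- universe[stats::runif(length(universe)) < p]
  stats::setNames(stats::runif(length(sel)), sel)
}

# fuzzy sets as full vectors over a universe, for algebra checks
as_full <- function(s, universe) {
  out <- stats::setNames(numeric(length(universe)), universe)
  common <- intersect(names(s), universe)
  out[common] <- s[common]
  out
}

# random small weighted graph with named nodes
random_weighted_graph <- function(n, p = 0.4) {
  nodes <- sprintf("n%02d", seq_len(n))
  from <- character(0); to <- character(0); w <- numeric(0)
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    if (stats::runif(1) < p) {
      from <- c(from, nodes[i]); to <- c(to, nodes[j])
      w <- c(w, stats::runif(1, 0.05, 1))
    }
  }
  igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w), directed = FALSE,
    vertices = data.frame(name = nodes))
}

# toy Medline XML writer
write_toy_medline <- function(path, citations) {
  lines <- c("<?xml version=\"1.0\"?>", "<PubmedArticleSet>")
  for (cit in citations) {
    lines <- c(lines, "<PubmedArticle><MedlineCitation>",
               sprintf("<PMID>%s</PMID>", cit$pmid),
               "<Article>",
               sprintf("<ArticleTitle>%s</ArticleTitle>",
                       cit$title %||% "Untitled"))
    if (!is.null(cit$abstract))
      lines <- c(lines, "<Abstract>",
                 sprintf("<AbstractText>%s</AbstractText>", cit$abstract),
                 "</Abstract>")
    lines <- c(lines, "</Article>", "</MedlineCitation></PubmedArticle>")
  }
  writeLines(c(lines, "</PubmedArticleSet>"), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# toy MeSH ASCII descriptor file covering the worked taxonomy examples
write_toy_mesh <- function(path) {
  recs <- c(
    "MH = Supranuclear Palsy, Progressive, 3",
    "ENTRY = PSP3|T047",
    "MN = C10.228.662.700",
    "MN = C23.888.592.636.447.690",
    "MN = C11.590.472.500",
    "",
    "MH = Parkinson Disease, Secondary",
    "ENTRY = Secondary Parkinson Disease|T047",
    "MN = C10.228.662.600.700",
    "",
    "MH = Parkinson Disease",
    "ENTRY = Idiopathic Parkinson Disease",
    "MN = C10.228.662.600",
    "",
    "MH = Dystonia",
    "MN = C10.228.662.300",
    ""
  )
  writeLines(recs, path)
  path
}
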