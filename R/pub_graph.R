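# Entity graphs derived from the knowledge base (and from MeSH
# annotation baselines), graph-level statistics, and the path-based
# related-article index.

#' Build the entity graph of a knowledge base
#'
#' Undirected weighted graph: nodes are terms, one edge per term pair with
#' weight equal to the maximum weight among that pair's statements.
#' Relation types (co-occurrence vs similarity) are collapsed.
#'
#' @param kb A `litnet_kb`.
#' @return An `igraph` graph with a `weight` edge attribute.
#' @export
build_entity_graph <- function(kb) {
  s <- kb$statements
  if (nrow(s) == 0L)
    return(igraph::make_empty_graph(0, directed = FALSE))
  key <- paste(pmin(s$term_a, s$term_b), pmax(s$term_a, s$term_b),
               sep = "\r")
  w <- tapply(s$weight, key, max)
  parts <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
  edges <- data.frame(from = parts[, 1], to = parts[, 2],
                      weight = as.numeric(w), stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE)
}

#' Build a MeSH-annotation baseline entity graph
#'
#' For every document, connects all pairs of its annotated terms into a
#' clique with implicit edge weight 1.0; the graph is the union of the
#' per-document cliques. Single-term documents contribute isolated nodes.
#'
#' @param annotations Named list: doc id -> character vector of annotated
#'   terms.
#' @return An `igraph` graph with a `weight` edge attribute (all 1).
#' @export
build_mesh_baseline_graph <- function(annotations) {
  nodes <- sort(unique(unlist(annotations)))
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  pairs <- character(0)
  for (terms in annotations) {
    terms <- sort(unique(terms))
    if (length(terms) < 2L) next
    cmb <- utils::combn(terms, 2L)
    pairs <- c(pairs, paste(cmb[1, ], cmb[2, ], sep = "\r"))
  }
  pairs <- unique(pairs)
  if (length(pairs)) {
    parts <- do.call(rbind, strsplit(pairs, "\r", fixed = TRUE))
    g <- igraph::add_edges(g, rbind(parts[, 1], parts[, 2]))
  }
  igraph::E(g)$weight <- rep(1, igraph::ecount(g))
  g
}

#' Entity-to-provenance map from a knowledge base
#'
#' @param kb A `litnet_kb`.
#' @return Named list: term -> sorted character vector of source doc ids.
#' @export
entity_provenance_map <- function(kb) {
  s <- kb$statements
  out <- list()
  for (i in seq_len(nrow(s))) {
    src <- kb$provenance[[s$statement_id[i]]]
    for (t in c(s$term_a[i], s$term_b[i]))
      out[[t]] <- unique(c(out[[t]], src))
  }
  lapply(out, sort)
}

# (max, *) matrix product: C[i, j] = max_k A[i, k] * B[k, j].
.maxprod <- function(A, B) {
  n <- nrow(A); m <- ncol(B)
  C <- matrix(0, n, m)
  for (k in seq_len(ncol(A))) {
    if (all(A[, k] == 0) || all(B[k, ] == 0)) next
    C <- pmax(C, outer(A[, k], B[k, ]))
  }
  C
}

#' Path-based related-article index
#'
#' For every pair of entities connected by a path of at most
#' `max_path_len` edges, the path weight is the product of its edge
#' weights; the entity-pair weight is the maximum over connecting paths
#' (since all weights are at most 1, walks revisiting nodes never beat a
#' simple path, so the max-product closure over walks is exact). Each
#' entity-pair weight is then propagated to all pairs of source articles
#' of the two entities, again aggregated by maximum; pairs below `prune`
#' are dropped. The result maps every article to the descending-weight
#' list of its related articles.
#'
#' @param graph Entity graph (igraph, `weight` edge attribute in (0, 1]).
#' @param prov Named list: entity -> character vector of source doc ids
#'   (see [entity_provenance_map()]).
#' @param max_path_len Maximum path length in edges (default 3).
#' @param prune Minimum retained weight (default 0.1); entries strictly
#'   below it are removed.
#' @return A `litnet_related` named list: doc id -> data frame
#'   (`related`, `weight`) sorted by descending weight.
#' @export
related_article_index <- function(graph, prov, max_path_len = 3L,
                                  prune = 0.1) {
  nodes <- igraph::V(graph)$name
  n <- length(nodes)
  sources <- sort(unique(unlist(prov)))
  empty <- structure(stats::setNames(list(), character(0)),
                     class = "litnet_related")
  if (n == 0L || length(sources) == 0L) return(empty)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  el <- igraph::as_data_frame(graph, what = "edges")
  if (nrow(el)) {
    W[cbind(el$from, el$to)] <- el$weight
    W[cbind(el$to, el$from)] <- el$weight
  }
  ME <- W
  Wk <- W
  for (len in seq_len(max_path_len - 1L)) {
    if (max_path_len < 2L) break
    Wk <- .maxprod(Wk, W)
    ME <- pmax(ME, Wk)
  }
  diag(ME) <- 0
  # provenance incidence: article x entity
  A <- matrix(0, length(sources), n, dimnames = list(sources, nodes))
  for (ent in names(prov)) {
    if (ent %in% nodes) A[prov[[ent]], ent] <- 1
  }
  MP <- .maxprod(.maxprod(A, ME), t(A))
  dimnames(MP) <- list(sources, sources)
  diag(MP) <- 0
  MP[MP < prune] <- 0
  out <- list()
  for (p in sources) {
    w <- MP[p, ]
    w <- w[w > 0]
    if (length(w) == 0L) next
    ord <- order(-w, names(w))
    out[[p]] <- data.frame(related = names(w)[ord],
                           weight = as.numeric(w)[ord],
                           stringsAsFactors = FALSE)
  }
  structure(out, class = "litnet_related")
}

#' Write a related-article index as TSV
#'
#' Columns `pmid`, `related_pmid`, `weight`, sorted by key then descending
#' weight.
#'
#' @param index A `litnet_related`.
#' @param path Output path.
#' @export
write_related_index <- function(index, path) {
  rows <- lapply(names(index), function(p)
    data.frame(pmid = p, related_pmid = index[[p]]$related,
               weight = index[[p]]$weight, stringsAsFactors = FALSE))
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pmid = character(0), related_pmid = character(0),
               weight = numeric(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a related-article index from TSV
#'
#' Accepts the format of [write_related_index()]; a `weight` (or
#' `rank_or_relevance`) column orders each list.
#'
#' @param path TSV path.
#' @return A `litnet_related`.
#' @export
read_related_index <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  wcol <- intersect(c("weight", "rank_or_relevance"), names(df))[1]
  w <- if (!is.na(wcol)) as.numeric(df[[wcol]]) else
    rev(seq_len(nrow(df)))
  out <- list()
  for (p in unique(df$pmid)) {
    sel <- df$pmid == p
    ord <- order(-w[sel])
    out[[p]] <- data.frame(related = df$related_pmid[sel][ord],
                           weight = w[sel][ord], stringsAsFactors = FALSE)
  }
  structure(out, class = "litnet_related")
}

#' Graph statistics
#'
#' Node and edge counts, edges per node, density
#' `D = 2|E| / (|V|(|V|-1))`, diameter and average shortest path length
#' (hop counts, computed per connected component and averaged weighted by
#' component size in nodes), and the number of connected components.
#'
#' @param graph An igraph graph (nonempty).
#' @return A `litnet_graph_stats` named list.
#' @export
graph_statistics <- function(graph) {
  nv <- igraph::vcount(graph)
  if (nv == 0L) stop("empty graph")
  ne <- igraph::ecount(graph)
  comp <- igraph::components(graph)
  sizes <- comp$csize
  diam <- numeric(length(sizes)); apl <- numeric(length(sizes))
  for (k in seq_along(sizes)) {
    sub <- igraph::induced_subgraph(graph, which(comp$membership == k))
    if (igraph::vcount(sub) == 1L) {
      diam[k] <- 0; apl[k] <- 0
    } else {
      diam[k] <- igraph::diameter(sub, weights = NA)
      apl[k] <- igraph::mean_distance(sub, weights = NA)
    }
  }
  wmean <- function(x) sum(x * sizes) / sum(sizes)
  structure(list(
    n_nodes = nv, n_edges = ne, edges_per_node = ne / nv,
    density = if (nv > 1L) 2 * ne / (nv * (nv - 1)) else NA_real_,
    diameter = wmean(diam), avg_shortest_path = wmean(apl),
    n_components = comp$no
  ), class = "litnet_graph_stats")
}

#' @export
print.litnet_graph_stats <- function(x, ...) {
  cat(sprintf(
    "|V|=%d |E|=%d E/V=%.3f D=%.4g d=%.3f l_G=%.3f |C|=%d\n",
    x$n_nodes, x$n_edges, x$edges_per_node, x$density, x$diameter,
    x$avg_shortest_path, x$n_components))
  invisible(x)
}

#' Export an entity graph
#'
#' GraphML (via igraph) or a weighted edge-list TSV
#' (`from`, `to`, `weight`).
#'
#' @param graph An igraph graph.
#' @param path Output path.
#' @param format `"graphml"` or `"tsv"`.
#' @export
write_entity_graph <- function(graph, path,
                               format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(graph, what = "edges")
    utils::write.table(el, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
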