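# Random-walk evaluation of entity graphs: heuristic next-node
# selection, walk envelopes, and the A-T measure battery (semantic
# coherence, cluster entropies, graph structure, auxiliary cluster
# statistics).

#' Walk configuration
#'
#' @param heuristic Neighbour-ordering heuristic: 1 = prefer unvisited,
#'   2 = prefer higher edge weight, 3 = prefer taxonomically more similar,
#'   4 = prefer less similar.
#' @param length Walk length in edges (2, 5, 10 or 50 in the reference
#'   grid; any positive integer accepted).
#' @param radius Envelope radius in hops (0, 1 or 2 in the reference
#'   grid).
#' @param repetitions Walks per configuration (default 100).
#' @param accept_base Acceptance threshold base `e_i` in (0, 1)
#'   (default 0.9).
#' @return A `litnet_walk_config`.
#' @export
walk_config <- function(heuristic = 1L, length = 10L, radius = 1L,
                        repetitions = 100L, accept_base = 0.9) {
  stopifnot(heuristic %in% 1:4, length >= 1L, radius >= 0L,
            repetitions >= 1L, accept_base > 0, accept_base < 1)
  structure(list(heuristic = as.integer(heuristic),
                 length = as.integer(length),
                 radius = as.integer(radius),
                 repetitions = as.integer(repetitions),
                 accept_base = accept_base),
            class = "litnet_walk_config")
}

#' Precompute a walk context for a graph and taxonomy
#'
#' Caches per-node cluster assignments, adjacency lists, and pairwise
#' taxonomy similarities (filled lazily) so batches of walks stay cheap.
#'
#' @param graph igraph entity graph with `weight` edge attribute and
#'   vertex names.
#' @param taxonomy A `litnet_taxonomy` (may be `NULL` when only
#'   heuristics 1-2 and structural measures are needed).
#' @return A `litnet_walk_ctx` environment.
#' @export
walk_context <- function(graph, taxonomy = NULL) {
  ctx <- new.env(parent = emptyenv())
  ctx$graph <- graph
  ctx$taxonomy <- taxonomy
  nodes <- igraph::V(graph)$name
  ctx$nodes <- nodes
  adj <- igraph::as_adj_list(graph)
  ctx$neighbors <- lapply(adj, function(v) igraph::V(graph)$name[v])
  names(ctx$neighbors) <- nodes
  el <- igraph::as_data_frame(graph, what = "edges")
  ctx$edge_w <- stats::setNames(
    c(el$weight, el$weight),
    c(paste(el$from, el$to, sep = "\r"), paste(el$to, el$from, sep = "\r")))
  if (!is.null(taxonomy)) {
    ctx$clusters <- lapply(stats::setNames(nodes, nodes), assign_clusters,
                           taxonomy = taxonomy)
  } else {
    ctx$clusters <- lapply(stats::setNames(nodes, nodes), function(x)
      list(abstract = character(0), specific = character(0)))
  }
  ctx$sim_cache <- new.env(parent = emptyenv())
  class(ctx) <- "litnet_walk_ctx"
  ctx
}

# cached node-pair similarity over specific cluster codes
.node_sim <- function(ctx, x, y) {
  key <- if (x <= y) paste(x, y, sep = "\r") else paste(y, x, sep = "\r")
  val <- ctx$sim_cache[[key]]
  if (!is.null(val)) return(val)
  val <- code_set_similarity(ctx$clusters[[x]]$specific,
                             ctx$clusters[[y]]$specific)
  ctx$sim_cache[[key]] <- val
  val
}

#' Select the next node of a walk
#'
#' The current node's neighbours are sorted by the heuristic criterion
#' (ties broken by node name for determinism under a fixed seed), then
#' scanned with a geometrically decaying acceptance threshold: starting
#' at `e = accept_base`, each candidate is accepted when a fresh uniform
#' draw `r <= e`, otherwise `e` is multiplied by `accept_base` and the
#' scan continues. If no candidate is accepted, a uniform random
#' neighbour is returned. Heads of the list are therefore favoured by all
#' heuristics.
#'
#' @param ctx A [walk_context()].
#' @param current Current node name.
#' @param visited Character vector of already-visited nodes (heuristic 1).
#' @param heuristic Integer 1-4 (see [walk_config()]).
#' @param accept_base Acceptance base `e_i`.
#' @return The next node name, or `NA_character_` for an isolated node.
#' @export
select_next_node <- function(ctx, current, visited = character(0),
                             heuristic = 1L, accept_base = 0.9) {
  nb <- ctx$neighbors[[current]]
  if (length(nb) == 0L) return(NA_character_)
  key <- switch(as.character(heuristic),
    "1" = as.numeric(nb %in% visited),             # unvisited first
    "2" = -ctx$edge_w[paste(current, nb, sep = "\r")],  # heavy edges first
    "3" = -vapply(nb, function(u) .node_sim(ctx, current, u), numeric(1)),
    "4" = vapply(nb, function(u) .node_sim(ctx, current, u), numeric(1))
  )
  nb <- nb[order(key, nb)]
  e <- accept_base
  for (u in nb) {
    if (stats::runif(1) <= e) return(u)
    e <- e * accept_base
  }
  nb[sample.int(length(nb), 1L)]
}

#' Run one random walk
#'
#' Performs up to `length` next-node selections from `start`, stopping
#' early at dead ends.
#'
#' @param ctx A [walk_context()].
#' @param start Start node name.
#' @param length Walk length in edges.
#' @param heuristic Integer 1-4.
#' @param accept_base Acceptance base `e_i` (default 0.9).
#' @return A `litnet_walk`: list with `path` (ordered node names,
#'   `length + 1` entries unless stuck).
#' @export
random_walk <- function(ctx, start, length, heuristic = 1L,
                        accept_base = 0.9) {
  stopifnot(start %in% ctx$nodes)
  path <- start
  current <- start
  for (step in seq_len(length)) {
    nxt <- select_next_node(ctx, current, visited = path,
                            heuristic = heuristic,
                            accept_base = accept_base)
    if (is.na(nxt)) break
    path <- c(path, nxt)
    current <- nxt
  }
  structure(list(path = path), class = "litnet_walk")
}

#' Envelope of a walk
#'
#' All graph nodes within hop distance `radius` of any path node
#' (the path itself included; radius 0 gives exactly the path node set).
#'
#' @param graph igraph graph.
#' @param walk A `litnet_walk` or character vector of path nodes.
#' @param radius Non-negative integer hop radius.
#' @return Character vector of envelope node names.
#' @export
walk_envelope <- function(graph, walk, radius = 0L) {
  nodes <- if (inherits(walk, "litnet_walk")) walk$path else walk
  nodes <- unique(nodes)
  if (radius == 0L) return(sort(nodes))
  balls <- igraph::ego(graph, order = radius, nodes = nodes)
  sort(unique(unlist(lapply(balls, function(v) igraph::V(graph)$name[v]))))
}

#' Semantic coherence of a walk (measures A-C)
#'
#' A: similarity of source and target nodes; B: product of consecutive
#' step similarities; C: sum of step similarities divided by the node
#' count `n` (as printed: the divisor is `n`, not the `n - 1` step
#' count). Conventions for a single-node walk: B = 1 (empty product),
#' C = 0.
#'
#' @param ctx A [walk_context()] built with a taxonomy.
#' @param walk A `litnet_walk`.
#' @return Named numeric vector `c(A = , B = , C = )`.
#' @export
coherence_measures <- function(ctx, walk) {
  p <- walk$path
  n <- length(p)
  A <- .node_sim(ctx, p[1], p[n])
  if (n == 1L) return(c(A = A, B = 1, C = 0))
  steps <- vapply(seq_len(n - 1L), function(i)
    .node_sim(ctx, p[i], p[i + 1L]), numeric(1))
  c(A = A, B = prod(steps), C = sum(steps) / n)
}

# Shannon entropy (bits) of cluster membership counts over a node set:
# cs(C_i) = number of nodes carrying cluster C_i, q_i = cs_i / sum(cs).
.cluster_entropy <- function(cluster_sets) {
  counts <- table(unlist(cluster_sets))
  if (length(counts) == 0L) return(0)
  q <- as.numeric(counts) / sum(counts)
  -sum(q * log2(q))
}

#' Cluster-entropy measures of a walk (D-H)
#'
#' D/E: entropy of abstract / specific MeSH-cluster membership over the
#' path nodes; F/G: the same over path plus envelope; H: entropy of
#' biconnected-component membership in the envelope subgraph (a
#' structure-only clustering; articulation nodes belong to several
#' components). Zero clusters yield entropy 0.
#'
#' @param ctx A [walk_context()].
#' @param walk A `litnet_walk`.
#' @param envelope Character vector from [walk_envelope()].
#' @return Named numeric vector `c(D = , E = , F = , G = , H = )`.
#' @export
entropy_measures <- function(ctx, walk, envelope) {
  path <- unique(walk$path)
  env_nodes <- unique(c(path, envelope))
  cl <- ctx$clusters
  D <- .cluster_entropy(lapply(cl[path], `[[`, "abstract"))
  E <- .cluster_entropy(lapply(cl[path], `[[`, "specific"))
  F_ <- .cluster_entropy(lapply(cl[env_nodes], `[[`, "abstract"))
  G <- .cluster_entropy(lapply(cl[env_nodes], `[[`, "specific"))
  sub <- igraph::induced_subgraph(ctx$graph, env_nodes)
  bic <- igraph::biconnected_components(sub)
  membership <- lapply(igraph::V(sub)$name, function(x) character(0))
  names(membership) <- igraph::V(sub)$name
  for (k in seq_along(bic$components)) {
    for (v in igraph::V(sub)$name[bic$components[[k]]])
      membership[[v]] <- c(membership[[v]], as.character(k))
  }
  H <- .cluster_entropy(membership)
  c(D = D, E = E, F = F_, G = G, H = H)
}

#' Graph-structure measures of an envelope (I-L)
#'
#' I: envelope size in nodes; J: number of biconnected components of the
#' envelope subgraph; K: their average size in nodes (0 when there are
#' none); L: average local clustering coefficient (nodes of degree < 2
#' contribute 0).
#'
#' @param ctx A [walk_context()].
#' @param envelope Character vector of envelope nodes.
#' @return Named numeric vector `c(I = , J = , K = , L = )`.
#' @export
structure_measures <- function(ctx, envelope) {
  sub <- igraph::induced_subgraph(ctx$graph, unique(envelope))
  bic <- igraph::biconnected_components(sub)
  sizes <- vapply(bic$components, length, integer(1))
  lcc <- igraph::transitivity(sub, type = "localundirected",
                              isolates = "zero")
  c(I = igraph::vcount(sub),
    J = bic$no,
    K = if (length(sizes)) mean(sizes) else 0,
    L = if (igraph::vcount(sub)) mean(lcc) else 0)
}

#' Auxiliary cluster statistics (M-T)
#'
#' Counts and average sizes of abstract/specific clusters over the path
#' and over the envelope: M/N abstract over path, O/P abstract over
#' envelope, Q/R specific over path, S/T specific over envelope. Cluster
#' size is the mention frequency `cs` within the respective node set;
#' empty sets yield 0.
#'
#' @param ctx A [walk_context()].
#' @param walk A `litnet_walk`.
#' @param envelope Character vector of envelope nodes.
#' @return Named numeric vector with components M-T.
#' @export
auxiliary_measures <- function(ctx, walk, envelope) {
  path <- unique(walk$path)
  env_nodes <- unique(c(path, envelope))
  cn_cs <- function(nodes, type) {
    counts <- table(unlist(lapply(ctx$clusters[nodes], `[[`, type)))
    c(n = length(counts),
      s = if (length(counts)) mean(as.numeric(counts)) else 0)
  }
  mp <- cn_cs(path, "abstract"); me <- cn_cs(env_nodes, "abstract")
  sp <- cn_cs(path, "specific"); se <- cn_cs(env_nodes, "specific")
  c(M = mp[["n"]], N = mp[["s"]], O = me[["n"]], P = me[["s"]],
    Q = sp[["n"]], R = sp[["s"]], S = se[["n"]], T = se[["s"]])
}

#' Measure one walk completely (A-T)
#'
#' @param ctx A [walk_context()].
#' @param walk A `litnet_walk`.
#' @param radius Envelope radius.
#' @return Named numeric vector of the 20 measures A-T.
#' @export
walk_measures <- function(ctx, walk, radius = 0L) {
  env_nodes <- walk_envelope(ctx$graph, walk, radius)
  c(coherence_measures(ctx, walk),
    entropy_measures(ctx, walk, env_nodes),
    structure_measures(ctx, env_nodes),
    auxiliary_measures(ctx, walk, env_nodes))
}

#' Run a batch of random-walk simulations
#'
#' Runs `repetitions` walks for every combination of heuristics, walk
#' lengths and envelope radii, each from a uniformly sampled start node,
#' and aggregates the 20 measures by arithmetic mean per combination.
#' With a fixed seed the report is bit-identical across reruns.
#'
#' @param graph igraph entity graph.
#' @param taxonomy A `litnet_taxonomy` (or `NULL`).
#' @param heuristics Integer vector (subset of 1:4).
#' @param lengths Integer vector of walk lengths (default
#'   `c(2, 5, 10, 50)`).
#' @param radii Integer vector of envelope radii (default `0:2`).
#' @param repetitions Walks per combination (default 100).
#' @param accept_base Acceptance base `e_i` (default 0.9).
#' @param seed Optional integer seed.
#' @return Data frame: one row per (heuristic, length, radius) with the
#'   mean of each measure A-T.
#' @export
run_simulation_batch <- function(graph, taxonomy = NULL,
                                 heuristics = 1:4,
                                 lengths = c(2L, 5L, 10L, 50L),
                                 radii = 0:2,
                                 repetitions = 100L,
                                 accept_base = 0.9,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ctx <- walk_context(graph, taxonomy)
  nodes <- ctx$nodes
  rows <- list()
  for (H in heuristics) {
    for (L in lengths) {
      for (r in radii) {
        acc <- matrix(0, nrow = repetitions, ncol = 20)
        for (rep in seq_len(repetitions)) {
          start <- nodes[sample.int(length(nodes), 1L)]
          w <- random_walk(ctx, start, L, heuristic = H,
                           accept_base = accept_base)
          acc[rep, ] <- walk_measures(ctx, w, radius = r)
        }
        means <- colMeans(acc)
        names(means) <- c("A", "B", "C", "D", "E", "F", "G", "H_", "I",
                          "J", "K", "L_", "M", "N", "O", "P", "Q", "R",
                          "S", "T_")
        rows[[length(rows) + 1L]] <- c(list(heuristic = H, length = L,
                                            radius = r),
                                       as.list(means))
      }
    }
  }
  do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Write a simulation report as TSV
#'
#' One row per (heuristic, length, radius) combination.
#'
#' @param report Data frame from [run_simulation_batch()].
#' @param path Output path.
#' @export
write_measure_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
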