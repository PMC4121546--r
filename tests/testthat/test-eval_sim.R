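# taxonomy loading, cluster assignment, tree-code similarity, walks and
# the measure battery

test_that("ASCII descriptor loading maps terms and synonyms to codes", {
  f <- withr::local_tempfile(fileext = ".txt")
  write_toy_mesh(f)
  tax <- load_mesh(f)
  cl <- assign_clusters("supranuclear palsy, progressive, 3", tax)
  expect_setequal(cl$abstract, c("C10", "C11", "C23"))
  expect_true("C10.228.662.700" %in% cl$specific)
  # synonym resolves to the canonical record's codes
  cl2 <- assign_clusters("secondary parkinson disease", tax)
  expect_equal(cl2$specific, "C10.228.662.600.700")
  expect_equal(assign_clusters("zzqx gibberish", tax)$specific,
               character(0))
})

test_that("records without tree numbers are skipped with a warning", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("MH = Orphan Term", "", "MH = Good Term",
               "MN = C01.100"), f)
  expect_warning(tax <- load_mesh(f), "no tree numbers")
  expect_equal(assign_clusters("good term", tax)$specific, "C01.100")
})

test_that("XML descriptor loading matches the ASCII loader", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<DescriptorRecordSet>',
    '<DescriptorRecord>',
    '<DescriptorName><String>Parkinson Disease</String></DescriptorName>',
    '<TreeNumberList><TreeNumber>C10.228.662.600</TreeNumber>',
    '</TreeNumberList>',
    '<TermList><Term><String>Idiopathic Parkinson Disease</String>',
    '</Term></TermList>',
    '</DescriptorRecord></DescriptorRecordSet>'), f)
  tax <- load_mesh(f)
  expect_equal(assign_clusters("idiopathic parkinson disease",
                               tax)$specific, "C10.228.662.600")
})

test_that("round trip: every fixture key is retrievable", {
  codes <- stats::setNames(
    lapply(1:10, function(i) sprintf("C%02d.%03d", i, i * 7)),
    sprintf("term number %d", 1:10))
  tax <- taxonomy(codes)
  for (t in names(codes))
    expect_equal(assign_clusters(t, tax)$specific, codes[[t]])
})

test_that("sub-term fallback matches the longest matching n-gram", {
  tax <- taxonomy(list("parkinson disease" = "C10.228.662.600",
                       disease = "C23.550"))
  cl <- assign_clusters("advanced parkinson disease patients", tax)
  expect_equal(cl$specific, "C10.228.662.600")  # bigram beats unigram
})

test_that("tree-code similarity reproduces the worked value", {
  fx <- worked_example_fixtures()
  expect_equal(code_set_similarity(fx$ex7$codes_x, fx$ex7$codes_y), 2 / 3)
  expect_equal(code_set_similarity("C10.228", "C10.228"), 1.0)
  expect_equal(code_set_similarity("C10", "D12"), 0)
  expect_equal(code_set_similarity(character(0), "C10"), 0)
  # symmetry and range on random code sets
  set.seed(41)
  for (rep in 1:30) {
    mk <- function() vapply(1:sample(1:3, 1), function(i)
      paste(sample(c("C10", "C11", "D12"), 1),
            paste(sample(100:999, sample(1:4, 1)), collapse = "."),
            sep = "."), character(1))
    x <- mk(); y <- mk()
    expect_equal(code_set_similarity(x, y), code_set_similarity(y, x))
    expect_gte(code_set_similarity(x, y), 0)
    expect_lte(code_set_similarity(x, y), 1)
  }
})

test_that("mesh_similarity composes assignment and code similarity", {
  f <- withr::local_tempfile(fileext = ".txt")
  write_toy_mesh(f)
  tax <- load_mesh(f)
  expect_equal(
    mesh_similarity("supranuclear palsy, progressive, 3",
                    "secondary parkinson disease", tax), 2 / 3)
})

make_toy_ctx <- function() {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "b", "c", "a"),
               to = c("b", "c", "d", "c"),
               weight = c(0.9, 0.8, 0.3, 0.5)), directed = FALSE)
  tax <- taxonomy(list(a = "C10.1", b = "C10.1", c = "C10.2",
                       d = "D05.1"))
  walk_context(g, tax)
}

test_that("next-node selection follows the sorted acceptance process", {
  ctx <- make_toy_ctx()
  # near-deterministic acceptance: head of the sorted list is chosen
  set.seed(1)
  nxt <- select_next_node(ctx, "b", heuristic = 2L,
                          accept_base = 1 - 1e-12)
  expect_equal(nxt, "a")  # heaviest edge from b (0.9 > 0.8)

  # H3 prefers the taxonomically similar neighbour, H4 the dissimilar
  set.seed(1)
  expect_equal(select_next_node(ctx, "c", heuristic = 3L,
                                accept_base = 1 - 1e-12), "a")
  set.seed(1)
  expect_equal(select_next_node(ctx, "c", heuristic = 4L,
                                accept_base = 1 - 1e-12), "d")

  # exact acceptance enumeration for two neighbours, e_i = 0.9:
  # P(head) = 0.9 + 0.1 * (1 - 0.81) / 2 = 0.9095
  set.seed(99)
  draws <- replicate(20000, select_next_node(ctx, "a", heuristic = 2L,
                                             accept_base = 0.9))
  p_head <- mean(draws == "b")  # a's heavier edge is b (0.9 > 0.5)
  expect_equal(p_head, 0.9095, tolerance = 0.02)
  expect_equal(p_head + mean(draws == "c"), 1)  # totals sum to one
})

test_that("walks are adjacent chains; envelopes equal BFS balls", {
  ctx <- make_toy_ctx()
  set.seed(2)
  w <- random_walk(ctx, "a", length = 5L, heuristic = 1L)
  expect_lte(length(w$path), 6L)
  for (i in seq_len(length(w$path) - 1L))
    expect_true(w$path[i + 1L] %in% ctx$neighbors[[w$path[i]]])

  expect_equal(walk_envelope(ctx$graph, w, 0L), sort(unique(w$path)))
  # star graph: hub path with r = 1 covers the whole graph
  star <- igraph::graph_from_data_frame(
    data.frame(from = "hub", to = paste0("leaf", 1:4), weight = 1),
    directed = FALSE)
  expect_setequal(walk_envelope(star, "hub", 1L),
                  igraph::V(star)$name)
  # BFS-ball oracle on random graphs
  set.seed(3)
  for (rep in 1:10) {
    g <- random_weighted_graph(8, 0.35)
    nodes <- sample(igraph::V(g)$name, 2)
    for (r in 0:2) {
      want <- sort(unique(unlist(lapply(nodes, function(s)
        igraph::V(g)$name[igraph::distances(g, v = s,
                                            weights = NA) <= r]))))
      expect_equal(walk_envelope(g, nodes, r), want)
    }
  }
})

test_that("coherence measures follow the printed conventions", {
  tax <- taxonomy(list(a = "C10.1.2", b = "C10.1.2", c = "C10.9"))
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "b"), to = c("b", "c"), weight = 1),
    directed = FALSE)
  ctx <- walk_context(g, tax)
  w_same <- structure(list(path = c("a", "b")), class = "litnet_walk")
  m <- coherence_measures(ctx, w_same)
  expect_equal(unname(m["A"]), 1)
  expect_equal(unname(m["B"]), 1)
  # hand computation on the 3-node walk: codes a = b = C10.1.2,
  # c = C10.9; sim(a,b) = 1, sim(b,c) = 2*1/(3+2) = 0.4 = sim(a,c)
  w3 <- structure(list(path = c("a", "b", "c")), class = "litnet_walk")
  m3 <- coherence_measures(ctx, w3)
  expect_equal(unname(m3["A"]), 0.4)
  expect_equal(unname(m3["B"]), 1 * 0.4)
  expect_equal(unname(m3["C"]), (1 + 0.4) / 3)  # divisor = node count
  # zero-similarity step annihilates the product
  tax2 <- taxonomy(list(a = "C10.1", b = "D05.1"))
  g2 <- igraph::graph_from_data_frame(
    data.frame(from = "a", to = "b", weight = 1), directed = FALSE)
  ctx2 <- walk_context(g2, tax2)
  m2 <- coherence_measures(
    ctx2, structure(list(path = c("a", "b")), class = "litnet_walk"))
  expect_equal(unname(m2["B"]), 0)
  # single-node conventions
  m1 <- coherence_measures(
    ctx2, structure(list(path = "a"), class = "litnet_walk"))
  expect_equal(unname(m1), c(1, 1, 0))
})

test_that("entropies match the direct-formula oracle", {
  tax <- taxonomy(list(a = "C10.1", b = "C10.2", c = "C11.1",
                       d = "C11.2", e = "C10.3", f = "D05.1"))
  g <- igraph::make_full_graph(6)
  igraph::V(g)$name <- letters[1:6]
  igraph::E(g)$weight <- 1
  ctx <- walk_context(g, tax)
  w <- structure(list(path = c("a", "b", "c")), class = "litnet_walk")
  env <- walk_envelope(g, w, 0L)
  m <- entropy_measures(ctx, w, env)
  # path abstract clusters: C10 x2, C11 x1
  expect_equal(unname(m["D"]),
               oracle_entropy(list("C10", "C10", "C11")))
  # specific codes all distinct -> log2(3)
  expect_equal(unname(m["E"]), log2(3))
  # all nodes in one cluster -> 0 bits; two equal clusters -> 1 bit
  expect_equal(oracle_entropy(list("X", "X", "X")), 0)
  expect_equal(oracle_entropy(list("X", "X", "Y", "Y")), 1)
  tax_one <- taxonomy(list(a = "C10.1", b = "C10.9", c = "C10.5"))
  ctx1 <- walk_context(igraph::induced_subgraph(g, 1:3), tax_one)
  m1 <- entropy_measures(ctx1, w, w$path)
  expect_equal(unname(m1["D"]), 0)
  # full-scan F/G over path + envelope equal direct formula
  m_full <- entropy_measures(ctx, w, letters[1:6])
  expect_equal(unname(m_full["F"]),
               oracle_entropy(list("C10", "C10", "C11", "C11", "C10",
                                   "D05")))
})

test_that("structure and auxiliary measures match hand counts", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  igraph::E(tri)$weight <- 1
  tax <- taxonomy(list(a = "C10.1", b = "C10.1", c = "C11.2"))
  ctx <- walk_context(tri, tax)
  sm <- structure_measures(ctx, c("a", "b", "c"))
  expect_equal(unname(sm["L"]), 1)  # triangle
  expect_equal(unname(sm["J"]), 1)
  expect_equal(unname(sm["I"]), 3)

  star <- igraph::graph_from_data_frame(
    data.frame(from = "hub", to = paste0("l", 1:3), weight = 1),
    directed = FALSE)
  ctx_s <- walk_context(star, NULL)
  expect_equal(unname(structure_measures(ctx_s,
                                         igraph::V(star)$name)["L"]), 0)

  w <- structure(list(path = c("a", "b")), class = "litnet_walk")
  aux <- auxiliary_measures(ctx, w, c("a", "b", "c"))
  expect_equal(unname(aux["M"]), 1)       # one abstract cluster on path
  expect_equal(unname(aux["N"]), 2)       # mentioned by both nodes
  expect_equal(unname(aux["O"]), 2)       # C10, C11 in envelope
  expect_equal(unname(aux["Q"]), 1)       # one specific code on path
  expect_equal(unname(aux["S"]), 2)
})

test_that("simulation batches are deterministic under a fixed seed", {
  sc <- synthetic_community_graph(n_nodes = 30L, seed = 6L)
  r1 <- run_simulation_batch(sc$graph, sc$taxonomy, heuristics = c(1, 3),
                             lengths = c(2, 5), radii = 0:1,
                             repetitions = 5L, seed = 123L)
  r2 <- run_simulation_batch(sc$graph, sc$taxonomy, heuristics = c(1, 3),
                             lengths = c(2, 5), radii = 0:1,
                             repetitions = 5L, seed = 123L)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 2 * 2 * 2)
  expect_true(all(c("A", "B", "C", "H_", "L_", "T_") %in% names(r1)))
})

test_that("precision/recall/correlation match their definitions", {
  cand <- structure(list(
    p1 = data.frame(related = c("p2", "p3"), weight = c(0.9, 0.8))),
    class = "litnet_related")
  gold <- structure(list(
    p1 = data.frame(related = c("p2", "p4"), weight = c(1, 0.5))),
    class = "litnet_related")
  r <- related_precision_recall(cand, gold)
  expect_equal(r$pre_avg, 0.5)
  expect_equal(r$rec_avg, 0.5)

  ident <- structure(list(
    p1 = data.frame(related = c("a", "b", "c"), weight = 3:1)),
    class = "litnet_related")
  r2 <- related_precision_recall(ident, ident)
  expect_equal(r2$corr_fraction, 1)

  # permuted fixtures vs the textbook Pearson formula
  set.seed(51)
  for (rep in 1:10) {
    items <- paste0("x", 1:6)
    c_ord <- sample(items); g_ord <- sample(items)
    cand3 <- structure(list(k = data.frame(related = c_ord,
                                           weight = 6:1)),
                       class = "litnet_related")
    gold3 <- structure(list(k = data.frame(related = g_ord,
                                           weight = 6:1)),
                       class = "litnet_related")
    r3 <- related_precision_recall(cand3, gold3)
    r1v <- match(items, c_ord); r2v <- match(items, g_ord)
    pearson <- sum((r1v - mean(r1v)) * (r2v - mean(r2v))) /
      sqrt(sum((r1v - mean(r1v))^2) * sum((r2v - mean(r2v))^2))
    expect_equal(r3$corr_fraction, as.numeric(pearson >= 0.7),
                 tolerance = 1e-12)
  }
  expect_error(related_precision_recall(
    structure(list(a = data.frame(related = "x", weight = 1)),
              class = "litnet_related"),
    structure(list(b = data.frame(related = "x", weight = 1)),
              class = "litnet_related")), "no shared keys")
})
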