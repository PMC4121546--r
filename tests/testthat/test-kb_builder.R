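# corpus-wide aggregation: fPMI, percentile normalisation, similarity

test_that("fpmi reproduces the worked normalised weight", {
  fx <- worked_example_fixtures()
  e <- fx$ex2
  raw <- fpmi(e$joint, e$marg_x, e$marg_y, e$freq, e$n_basic)
  expect_equal(round(raw, 3), 1.123)
  expect_equal(round(raw / e$norm_constant, 3), 0.545)
  # one-statement corpus with unit score: joint = marginals = |T| = 1,
  # F = 1 -> log2(1) = 0 (for scores w != 1 the value is log2(1/w))
  expect_equal(fpmi(1, 1, 1, 1, 1), 0)
  expect_equal(fpmi(0.5, 0.5, 0.5, 1, 1), 1)  # log2(1/0.5)
  expect_error(fpmi(1, 0, 1, 1, 10), "marginal")
})

test_that("fpmi matches independent re-aggregation on a random corpus", {
  set.seed(9)
  for (rep in 1:5) {
    terms <- letters[1:6]
    basic <- data.frame(
      term_a = character(0), term_b = character(0), score = numeric(0),
      doc_id = character(0))
    for (d in 1:8) {
      pair <- sort(sample(terms, 2))
      basic <- rbind(basic, data.frame(
        term_a = pair[1], term_b = pair[2],
        score = round(stats::runif(1, 0.5, 4), 3),
        doc_id = sprintf("d%d", d), stringsAsFactors = FALSE))
    }
    agg <- aggregate_statements(basic)
    got <- fpmi(agg$pairs$joint, agg$marginal[agg$pairs$term_a],
                agg$marginal[agg$pairs$term_b], agg$pairs$freq,
                agg$n_basic)
    names(got) <- paste(agg$pairs$term_a, agg$pairs$term_b, sep = "|")
    want <- oracle_fpmi_table(basic)
    expect_equal(got[names(want)], want, tolerance = 1e-12)
  }
})

test_that("percentile normalisation follows nearest-rank + clip", {
  res <- normalize_scores(stats::setNames(as.numeric(1:100),
                                          paste0("p", 1:100)), P = 95)
  expect_equal(res$norm_constant, 95)
  expect_equal(unname(res$weights[["p95"]]), 1.0)
  expect_equal(unname(res$weights[["p100"]]), 1.0)       # clipped
  expect_equal(unname(res$weights[["p19"]]), 19 / 95)
  expect_equal(round(1.123 / 2.061, 3), 0.545)
  expect_warning(normalize_scores(c(a = -1, b = 0)), "no positive")
})

test_that("about 5% of pre-clip scores exceed the 95th-percentile constant", {
  set.seed(13)
  x <- stats::rexp(10000) + 1e-6
  nc <- nearest_rank_percentile(x, 95)
  expect_lte(mean(x / nc > 1), 0.051)
  expect_gte(mean(x / nc > 1), 0.04)
})

test_that("cooc layer drops non-positive fPMI and stays within (0,1]", {
  # single document, one pair: fpmi = 0 -> filtered out
  one <- data.frame(term_a = "a", term_b = "b", score = 2, doc_id = "d")
  expect_warning(layer <- build_cooc_layer(one), "non-positive")
  expect_equal(nrow(layer), 0L)

  set.seed(21)
  spec <- synthetic_spec(n_docs = 20L, seed = 77L)
  synth <- synthetic_corpus(spec)
  basic <- extract_basic_statements(synth$mentions)
  layer <- build_cooc_layer(basic)
  expect_gt(nrow(layer), 0L)
  expect_true(all(layer$weight > 0 & layer$weight <= 1))
})

test_that("document order does not change KB weights", {
  synth <- synthetic_corpus(synthetic_spec(n_docs = 12L, seed = 5L))
  basic <- extract_basic_statements(synth$mentions)
  set.seed(1)
  shuffled <- basic[sample.int(nrow(basic)), , drop = FALSE]
  a <- build_cooc_layer(basic); b <- build_cooc_layer(shuffled)
  key <- function(df) stats::setNames(df$weight,
                                      paste(df$term_a, df$term_b))
  expect_equal(key(a)[order(names(key(a)))], key(b)[order(names(key(b)))])
})

test_that("cosine similarity behaves on shared, identical, disjoint vectors", {
  fx <- worked_example_fixtures()
  a <- fx$ex3$a; b <- fx$ex3$b
  # visible components only: dot below the printed full-vector dot
  expect_lt(sum(a * b[names(a)]), fx$ex3$dot)
  expect_equal(round(fx$ex3$dot / (fx$ex3$norm_a * fx$ex3$norm_b), 3),
               0.365)
  expect_equal(cosine_similarity(a, a), 1.0)
  expect_equal(cosine_similarity(c(x = 1), c(y = 1)), 0)
  expect_equal(cosine_similarity(numeric(0), c(y = 1)), 0)
  v <- cosine_similarity(a, b)
  expect_true(v > 0 && v <= 1)
})

test_that("blocked similarity layer equals the all-pairs oracle", {
  set.seed(31)
  comps <- paste0("c", 1:12)
  vecs <- lapply(1:50, function(i) {
    sel <- sample(comps, sample(2:5, 1))
    stats::setNames(round(stats::runif(length(sel), 0.05, 1), 3), sel)
  })
  names(vecs) <- sprintf("t%02d", 1:50)
  got <- build_sim_layer(vecs, threshold = 0.25)
  want <- list()
  nm <- names(vecs)
  for (i in 1:49) for (j in (i + 1):50) {
    s <- cosine_similarity(vecs[[i]], vecs[[j]])
    if (s >= 0.25)
      want[[length(want) + 1L]] <- data.frame(
        term_a = min(nm[i], nm[j]), term_b = max(nm[i], nm[j]),
        weight = s, stringsAsFactors = FALSE)
  }
  want <- do.call(rbind, want)
  want <- want[order(want$term_a, want$term_b), ]
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$term_a, want$term_a)
  expect_equal(got$weight, want$weight, tolerance = 1e-12)
  # threshold is inclusive at 0.25, exclusive below
  expect_true(all(got$weight >= 0.25))
})

test_that("knowledge base TSV round trips", {
  synth <- synthetic_corpus(synthetic_spec(n_docs = 12L, seed = 8L))
  basic <- extract_basic_statements(synth$mentions)
  kb <- build_kb(basic)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_kb(kb, f)
  back <- read_kb(f)
  expect_equal(back$statements$weight, kb$statements$weight,
               tolerance = 1e-9)
  expect_equal(back$provenance, kb$provenance)
})
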