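# query parsing, fuzzy algebra, statement and provenance expansion

test_that("parser builds the expected trees and flags syntax errors", {
  t1 <- parse_query(
    "parkinsonism AND (mrpi OR magnetic resonance parkinsonism index)")
  expect_equal(t1$op, "AND")
  expect_equal(t1$children[[1]]$term, "parkinsonism")
  expect_equal(t1$children[[2]]$op, "OR")
  expect_equal(t1$children[[2]]$children[[2]]$term,
               "magnetic resonance parkinsonism index")

  t2 <- parse_query("a")
  expect_equal(t2$type, "atom")

  expect_error(parse_query("a AND OR b"), "syntax error")
  expect_error(parse_query("(a AND b"), "parentheses")
  expect_error(parse_query("a AND"), "unexpected end")

  # NOT binds tighter than AND, AND tighter than OR
  t3 <- parse_query("a OR b AND NOT c")
  expect_equal(t3$op, "OR")
  expect_equal(t3$children[[2]]$op, "AND")
  expect_equal(t3$children[[2]]$children[[2]]$op, "NOT")
})

test_that("fuzzy algebra uses max / min / complement", {
  A <- c(x = 0.3); B <- c(x = 0.7, y = 0.2)
  expect_equal(sort(fuzzy_union(list(A, B))), sort(c(x = 0.7, y = 0.2)))
  expect_equal(fuzzy_intersection(list(A, B)), c(x = 0.3))
  U <- c("x", "y", "z")
  comp <- fuzzy_complement(A, U)
  expect_equal(comp[["x"]], 0.7)
  expect_equal(comp[["z"]], 1)
  # min(a, 1-a) <= 0.5 for every element
  a <- c(p = 0.8, q = 0.4)
  both <- fuzzy_intersection(list(a, fuzzy_complement(a, c("p", "q"))))
  expect_true(all(both <= 0.5))
})

test_that("De Morgan, idempotence and double negation hold (property)", {
  set.seed(17)
  U <- paste0("e", 1:12)
  for (rep in 1:100) {
    A <- random_fuzzy(U); B <- random_fuzzy(U)
    lhs <- fuzzy_complement(fuzzy_intersection(list(A, B)), U)
    rhs <- fuzzy_union(list(fuzzy_complement(A, U),
                            fuzzy_complement(B, U)))
    expect_equal(as_full(lhs, U), as_full(rhs, U), tolerance = 1e-12)
    expect_equal(as_full(fuzzy_union(list(A, A)), U), as_full(A, U))
    expect_equal(as_full(fuzzy_intersection(list(A, A)), U),
                 as_full(A, U))
    expect_equal(
      as_full(fuzzy_complement(fuzzy_complement(A, U), U), U),
      as_full(A, U) * 0 + as_full(A, U),  # restricted to universe
      tolerance = 1e-12)
  }
})

test_that("atomic evaluation unions stem-matched term index rows", {
  fx <- worked_example_fixtures()
  idx <- build_indices(fx$ex4$kb)
  # exact unique match returns exactly the term index row
  r <- eval_atomic("drd", idx)
  expect_equal(r, c(parkinsonism = 0.545))
  # stemming unifies singular/plural: union of both rows
  r2 <- eval_atomic("parkinsonism", idx)
  expect_equal(sort(r2), sort(c(drd = 0.545, `mrpi values` = 0.365)))
  expect_length(eval_atomic("absent", idx), 0L)
})

test_that("statement degrees are the mean of their term degrees", {
  # two-term statements over a toy index with prescribed term degrees
  fx <- worked_example_fixtures()
  deg <- fx$ex5$term_degrees
  kb <- kb_from_statements(
    data.frame(
      term_a = c("mrpi", "mrpi", "mrpi"),
      term_b = c("magnetic resonance parkinsonism index", "cup",
                 "clinically unclassifiable parkinsonism"),
      relation = "cooc", weight = c(0.9, 0.9, 0.9),
      stringsAsFactors = FALSE),
    list("p1", "p2", "p3"))
  idx <- build_indices(kb)
  RT <- deg
  RS <- statements_for_terms(RT, idx, top_k = 5L)
  sid <- statement_id
  expect_equal(
    unname(RS[[sid("mrpi", "cooc",
                   "magnetic resonance parkinsonism index")]]),
    0.852)
  expect_equal(unname(RS[[sid("mrpi", "cooc", "cup")]]), 1.0)
  expect_equal(
    unname(RS[[sid("mrpi", "cooc",
                   "clinically unclassifiable parkinsonism")]]),
    0.695)
})

test_that("top-k restriction zeroes terms outside the top five", {
  kb <- kb_from_statements(
    data.frame(term_a = letters[1:6], term_b = letters[2:7],
               relation = "cooc", weight = 0.5, stringsAsFactors = FALSE),
    as.list(paste0("p", 1:6)))
  idx <- build_indices(kb)
  RT <- stats::setNames(seq(0.95, 0.25, length.out = 7), letters[1:7])
  RS <- statements_for_terms(RT, idx, top_k = 2L)
  # only statements touching the top-2 terms (a, b) survive
  touched <- unique(unlist(strsplit(names(RS), "|", fixed = TRUE)))
  expect_true(all(c("a", "b") %in% touched) ||
                length(RS) > 0)
  expect_true(all(vapply(strsplit(names(RS), "|", fixed = TRUE),
                         function(p) any(p[c(1, 3)] %in% c("a", "b")),
                         logical(1))))
})

test_that("provenance expansion is a max-normalised matrix product", {
  kb <- kb_from_statements(
    data.frame(term_a = c("x", "y"), term_b = c("y", "z"),
               relation = "cooc", weight = c(0.4, 0.8),
               stringsAsFactors = FALSE),
    list(c("p1", "p2"), c("p2", "p3")))
  idx <- build_indices(kb)
  RS <- stats::setNames(c(0.5, 0.25),
                        statement_id(c("x", "y"), "cooc", c("y", "z")))
  RP <- provenance_for_statements(RS, idx)
  # dense oracle
  w <- c(p1 = 0.5 * 0.4, p2 = 0.5 * 0.4 + 0.25 * 0.8, p3 = 0.25 * 0.8)
  w <- w / max(w)
  expect_equal(as_full(RP, names(w)), w, tolerance = 1e-12)

  # single statement, two sources of equal weight -> both degree 1
  kb1 <- kb_from_statements(
    data.frame(term_a = "x", term_b = "y", relation = "cooc",
               weight = 0.4, stringsAsFactors = FALSE),
    list(c("p1", "p2")))
  idx1 <- build_indices(kb1)
  RP1 <- provenance_for_statements(
    stats::setNames(0.5, statement_id("x", "cooc", "y")), idx1)
  expect_equal(unname(RP1), c(1, 1))
})

test_that("end-to-end toy query ranks the two sources of S1 equally", {
  fx <- worked_example_fixtures()
  idx <- build_indices(fx$ex4$kb)
  res <- run_query(idx, "parkinsonism")
  expect_equal(res$sources[["P1"]], res$sources[["P2"]])
  expect_equal(unname(res$sources[["P1"]]), 1)
  # single-atom exact unique match: terms equal the index row
  res2 <- run_query(idx, "drd")
  expect_equal(res2$terms, c(parkinsonism = 0.545))
})
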