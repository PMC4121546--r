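# End-to-end convenience wrappers and a minimal command-line front end.

#' Build a knowledge base and its indices from a corpus
#'
#' Full pipeline: mention extraction, per-document co-occurrence scoring,
#' corpus-wide fPMI aggregation, similarity layer, and index
#' construction.
#'
#' @param corpus List of [document()]s.
#' @param config An [extractor_config()].
#' @param params A [cooc_params()].
#' @param P fPMI normalisation percentile (default 95).
#' @param sim_threshold Similarity layer threshold (default 0.25).
#' @return List with `mentions`, `basic_statements`, `kb`, `indices` and
#'   `stats` (a `litnet_corpus_stats`).
#' @export
build_pipeline <- function(corpus, config, params = cooc_params(),
                           P = 95, sim_threshold = 0.25) {
  mentions <- extract_corpus_mentions(corpus, config)
  basic <- extract_basic_statements(mentions, params)
  kb <- build_kb(basic, P = P, sim_threshold = sim_threshold)
  indices <- build_indices(kb)
  stats <- corpus_statistics(corpus, basic, kb$statements)
  list(mentions = mentions, basic_statements = basic, kb = kb,
       indices = indices, stats = stats)
}

#' Command-line entry point
#'
#' Two subcommands, intended for `Rscript -e 'litnet::litnet_cli()'`-style
#' invocation:
#'
#' * `query "<expr>" --kb <kb.tsv> [--top-terms 5] [--top-statements 7]
#'   [--format json|tsv]` - evaluate a fuzzy boolean query against a
#'   knowledge base written by [write_kb()] and print ranked terms,
#'   statements and sources;
#' * `fixtures make --out <dir> [--seed 42]` - write the fixture bundle
#'   (see [write_fixture_bundle()]).
#'
#' @param args Character vector of arguments (defaults to
#'   [commandArgs()]).
#' @return Invisibly, the result object of the subcommand.
#' @export
litnet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L)
    stop("usage: query \"<expr>\" --kb <kb.tsv> | fixtures make --out <dir>")
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i)) args[i[1] + 1L] else default
  }
  if (args[1] == "query") {
    kb <- read_kb(opt("--kb", stop("--kb required")))
    indices <- build_indices(kb)
    res <- run_query(indices, args[2],
                     top_terms = as.integer(opt("--top-terms", "5")),
                     top_statements = as.integer(
                       opt("--top-statements", "7")))
    fmt <- opt("--format", "tsv")
    if (fmt == "json" && requireNamespace("jsonlite", quietly = TRUE)) {
      cat(jsonlite::toJSON(list(
        terms = as.list(res$terms), statements = as.list(res$statements),
        sources = as.list(res$sources)), auto_unbox = TRUE, digits = NA))
      cat("\n")
    } else {
      for (part in c("terms", "statements", "sources")) {
        s <- res[[part]]
        for (i in seq_along(s))
          cat(part, names(s)[i], format(s[i], digits = 10), sep = "\t",
              fill = TRUE)
      }
    }
    return(invisible(res))
  }
  if (args[1] == "fixtures" && length(args) >= 2L && args[2] == "make") {
    out <- opt("--out", stop("--out required"))
    seed <- as.integer(opt("--seed", "42"))
    write_fixture_bundle(out, synthetic_spec(seed = seed))
    message("fixture bundle written to ", out)
    return(invisible(out))
  }
  stop("unknown subcommand: ", args[1])
}
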