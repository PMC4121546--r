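# Comparison of related-article indices against a gold standard:
# precision, recall, and rank correlation of shared items.

#' Precision, recall and rank correlation of related-article indices
#'
#' For every key present in both indices (lists truncated to their
#' `top_k` highest-weight entries): precision is the fraction of the
#' candidate list found in the gold list, recall the fraction of the
#' gold list recovered; both are averaged arithmetically over shared
#' keys. For the ranking agreement, Pearson's correlation is computed on
#' the ranks of the articles present in *both* truncated lists (keys with
#' fewer than two shared articles, or with degenerate constant ranks, are
#' skipped); `corr_fraction` is the fraction of evaluated keys with
#' correlation at least `corr_threshold`.
#'
#' @param candidate,gold `litnet_related` indices (see
#'   [related_article_index()], [read_related_index()]).
#' @param top_k Maximum list length considered (default `Inf`).
#' @param corr_threshold Correlation counted as significant
#'   (default 0.7).
#' @return List with `pre_avg`, `rec_avg`, `corr_fraction`,
#'   `n_keys` (shared keys) and `n_corr_keys` (keys entering the
#'   correlation fraction).
#' @export
related_precision_recall <- function(candidate, gold, top_k = Inf,
                                     corr_threshold = 0.7) {
  keys <- intersect(names(candidate), names(gold))
  if (length(keys) == 0L) stop("no shared keys between the indices")
  trunc_list <- function(df) {
    k <- min(top_k, nrow(df))
    df$related[seq_len(k)]
  }
  pre <- numeric(length(keys)); rec <- numeric(length(keys))
  cors <- numeric(0)
  for (i in seq_along(keys)) {
    cl <- trunc_list(candidate[[keys[i]]])
    gl <- trunc_list(gold[[keys[i]]])
    shared <- intersect(cl, gl)
    pre[i] <- length(shared) / length(cl)
    rec[i] <- length(shared) / length(gl)
    if (length(shared) >= 2L) {
      r1 <- match(shared, cl); r2 <- match(shared, gl)
      if (stats::sd(r1) > 0 && stats::sd(r2) > 0)
        cors <- c(cors, stats::cor(r1, r2))
    }
  }
  list(pre_avg = mean(pre), rec_avg = mean(rec),
       corr_fraction = if (length(cors))
         mean(cors >= corr_threshold) else NA_real_,
       n_keys = length(keys), n_corr_keys = length(cors))
}
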