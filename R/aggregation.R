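# Rank aggregation: Borda count and robust rank aggregation (beta
# order-statistics with Bonferroni correction).

# split a bound ranked_list tibble (or list of them) into per-method
# tibbles, checking they cover the same feature set
split_rankings <- function(rankings) {
  if (is.data.frame(rankings)) {
    rankings <- split(as_tibble(rankings), rankings$method)
  }
  sets <- purrr::map(rankings, function(r) sort(unique(r$feature)))
  if (length(unique(purrr::map_chr(sets, paste, collapse = "\r"))) != 1)
    abort("all rankings must cover the same feature set")
  rankings
}

#' Borda count aggregation
#'
#' Each feature collects `N - position + 1` points from every input
#' ranking (position 1 = best, `N` features), and features are ordered by
#' descending total points — so the feature with the highest Borda value is
#' the consensus best. This is order-equivalent to ascending rank-sum.
#' Ties break by ascending feature index.
#'
#' @param rankings A `ranked_list` tibble holding several methods (or a
#'   list of single-method `ranked_list`s), all over the same features.
#' @return A `ranked_list` tibble with `method = "borda"`; `score` is the
#'   total points.
#' @examples
#' tab <- simulate_feature_table(n = 100, effect = 2, seed = 1) |>
#'   standardize_features()
#' rank_features(tab, c("fisher", "chi2")) |> aggregate_borda()
#' @export
aggregate_borda <- function(rankings) {
  rankings <- split_rankings(rankings)
  feats <- sort(unique(rankings[[1]]$feature))
  feats <- feats[order(feature_index(feats))]
  N <- length(feats)
  pts <- stats::setNames(numeric(N), feats)
  for (r in rankings) pts[r$feature] <- pts[r$feature] + (N - r$rank + 1)
  new_ranked_list(feats, unname(pts[feats]), "borda")
}

#' Robust rank aggregation
#'
#' For each feature, the positions assigned by the `m` input rankings are
#' normalized to `(0, 1]`, sorted ascending, and compared with the order
#' statistics of `m` uniform draws: the feature's rho score is
#' `min_k P(Beta(k, m - k + 1) <= r_(k))`, Bonferroni-corrected to
#' `min(1, m * rho)`. Small scores mean the feature sits higher across the
#' rankings than chance would allow; output is ordered by ascending score.
#'
#' @inheritParams aggregate_borda
#' @return A `ranked_list` tibble with `method = "rra"`; `score` is the
#'   corrected rho (smaller is better).
#' @export
aggregate_rra <- function(rankings) {
  rankings <- split_rankings(rankings)
  if (length(rankings) < 2) abort("RRA needs at least 2 rankings")
  feats <- sort(unique(rankings[[1]]$feature))
  feats <- feats[order(feature_index(feats))]
  N <- length(feats)
  m <- length(rankings)
  pos <- vapply(rankings, function(r) r$rank[match(feats, r$feature)],
                numeric(N))
  rho <- apply(pos / N, 1, function(r) {
    r <- sort(r)
    min(stats::pbeta(r, seq_len(m), m - seq_len(m) + 1))
  })
  # order by the raw rho (the Bonferroni clamp at 1 would erase the
  # ordering of clearly non-significant features); report the corrected
  # score
  ord <- order(rho, feature_index(feats))
  out <- tibble(method = "rra", rank = seq_along(feats),
                feature = feats[ord],
                score = unname(pmin(1, rho * m))[ord])
  class(out) <- c("ranked_list", class(out))
  out
}
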