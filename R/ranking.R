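# The seven filter feature-ranking methods. Each takes a (standardized)
# feature table with a `stage` class column and returns a `ranked_list`
# tibble: one row per feature, best first, with the method's criterion
# value as `score`. All rankers are deterministic; ties are broken by
# ascending feature index.

new_ranked_list <- function(features, scores, method, decreasing = TRUE) {
  scores <- unname(scores)
  ord <- order(if (decreasing) -scores else scores, feature_index(features))
  out <- tibble(method = method, rank = seq_along(features),
                feature = features[ord], score = scores[ord])
  class(out) <- c("ranked_list", class(out))
  out
}

# class vector + feature matrix from a feature table
split_xy <- function(df) {
  cols <- feature_cols(df)
  y <- factor(as.character(df$stage))
  if (nlevels(y) < 2) abort("need at least 2 classes in `stage`")
  list(X = as.matrix(df[cols]), y = y, features = cols)
}

#' Equal-width discretization
#'
#' Maps a numeric column to integer labels `0 ... n_bins - 1` over
#' equal-width intervals spanning its range, the top bin right-closed.
#' A constant column maps to all zeros. Labels are invariant under affine
#' rescaling of the data.
#'
#' @param x Numeric vector.
#' @param n_bins Number of bins (>= 2), default 10.
#' @return Integer labels in `[0, n_bins - 1]`.
#' @examples
#' discretize(c(0, 0.5, 1), 2) # 0 1 1
#' @export
discretize <- function(x, n_bins = 10) {
  if (n_bins < 2) abort("`n_bins` must be >= 2")
  r <- range(x)
  if (r[1] == r[2]) return(integer(length(x)))
  i <- floor((x - r[1]) / (r[2] - r[1]) * n_bins)
  as.integer(pmin(i, n_bins - 1))
}

#' Plug-in mutual information of discrete labels
#'
#' Empirical mutual information (natural log) from the joint contingency
#' table; `conditional_mutual_information()` is the conditional version
#' `I(a; b | c)` averaged over the conditioning levels.
#'
#' @param a,b,c Integer/factor label vectors of equal length.
#' @return Non-negative value in nats.
#' @export
mutual_information <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  px <- rowSums(tab) / n
  py <- colSums(tab) / n
  p <- tab / n
  e <- outer(px, py)
  keep <- p > 0
  sum(p[keep] * log(p[keep] / e[keep]))
}

#' @rdname mutual_information
#' @export
conditional_mutual_information <- function(a, b, c) {
  n <- length(c)
  s <- 0
  for (lev in unique(c)) {
    idx <- c == lev
    s <- s + sum(idx) / n * mutual_information(a[idx], b[idx])
  }
  s
}

#' Fisher score ranking
#'
#' Ratio of between-class to within-class scatter per feature:
#' `sum_c n_c (mu_cj - mu_j)^2 / (sum_c n_c sigma_cj^2 + eps)`, ranked
#' descending.
#'
#' @param df A standardized feature table with a `stage` class column.
#' @param eps Denominator guard for zero within-class variance.
#' @return A `ranked_list` tibble.
#' @export
rank_fisher <- function(df, eps = 1e-12) {
  d <- split_xy(df)
  mu <- colMeans(d$X)
  num <- den <- numeric(ncol(d$X))
  for (lev in levels(d$y)) {
    idx <- d$y == lev
    nc <- sum(idx)
    if (nc == 0) next
    muc <- colMeans(d$X[idx, , drop = FALSE])
    varc <- colMeans(sweep(d$X[idx, , drop = FALSE], 2, muc)^2)
    num <- num + nc * (muc - mu)^2
    den <- den + nc * varc
  }
  new_ranked_list(d$features, num / (den + eps), "fisher")
}

#' Chi-square ranking
#'
#' Pearson chi-square statistic of the feature-bin by class contingency
#' table after equal-width discretization, ranked descending.
#'
#' @inheritParams rank_fisher
#' @param n_bins Discretization bins (default 10).
#' @return A `ranked_list` tibble.
#' @export
rank_chi2 <- function(df, n_bins = 10) {
  d <- split_xy(df)
  scores <- apply(d$X, 2, function(col) {
    tab <- table(discretize(col, n_bins), d$y)
    n <- sum(tab)
    e <- outer(rowSums(tab), colSums(tab)) / n
    keep <- e > 0
    sum((tab[keep] - e[keep])^2 / e[keep])
  })
  new_ranked_list(d$features, scores, "chi2")
}

#' Information-gain ranking
#'
#' Mutual information between the discretized feature and the class
#' (equivalently the reduction of class entropy given the feature),
#' ranked descending.
#'
#' @inheritParams rank_chi2
#' @return A `ranked_list` tibble.
#' @export
rank_infogain <- function(df, n_bins = 10) {
  d <- split_xy(df)
  scores <- apply(d$X, 2, function(col)
    mutual_information(discretize(col, n_bins), d$y))
  new_ranked_list(d$features, scores, "infogain")
}

#' ReliefF ranking
#'
#' Multi-class ReliefF with every instance used as an update anchor: for
#' each anchor, the k nearest same-class hits pull a feature's weight down
#' by its normalized value difference, and the k nearest misses of each
#' other class push it up, weighted by the class prior renormalized over
#' non-target classes. Distances are Manhattan on all features; value
#' differences are normalized by the feature range. Input should be
#' standardized (the pipeline always standardizes first) since the weights
#' are not scale-invariant.
#'
#' @inheritParams rank_fisher
#' @param k Number of nearest hits/misses per class (default 10); every
#'   class must have more than `k` members.
#' @return A `ranked_list` tibble.
#' @export
rank_relieff <- function(df, k = 10) {
  d <- split_xy(df)
  n <- nrow(d$X)
  tab <- table(d$y)
  if (any(tab <= k))
    abort(sprintf("class `%s` has <= k = %d members; reduce `k`",
                  names(tab)[which.min(tab)], k))
  prior <- tab / n
  rng <- apply(d$X, 2, function(v) diff(range(v)))
  rng[rng == 0] <- 1
  Xn <- sweep(d$X, 2, rng, "/")
  D <- as.matrix(stats::dist(Xn, method = "manhattan"))
  w <- numeric(ncol(d$X))
  lv <- levels(d$y)
  idx_by_class <- lapply(lv, function(l) which(d$y == l))
  names(idx_by_class) <- lv
  for (i in seq_len(n)) {
    yi <- as.character(d$y[i])
    hits <- idx_by_class[[yi]]
    hits <- hits[hits != i]
    hits <- hits[order(D[i, hits])][seq_len(k)]
    w <- w - colSums(abs(Xn[hits, , drop = FALSE] -
                           matrix(Xn[i, ], k, ncol(Xn), byrow = TRUE))) / k
    for (cl in setdiff(lv, yi)) {
      miss <- idx_by_class[[cl]]
      miss <- miss[order(D[i, miss])][seq_len(k)]
      wc <- prior[[cl]] / (1 - prior[[yi]])
      w <- w + wc * colSums(abs(Xn[miss, , drop = FALSE] -
                     matrix(Xn[i, ], k, ncol(Xn), byrow = TRUE))) / k
    }
  }
  new_ranked_list(d$features, w / n, "relieff")
}

#' CMIM ranking
#'
#' Conditional mutual information maximization: the first feature maximizes
#' `I(f; Y)`; each later pick maximizes the minimum over already-selected
#' features of `I(f; Y | g)`, so exact duplicates of selected features
#' collapse to the bottom. Produces a full ordering; the score is the
#' criterion value at selection time.
#'
#' @inheritParams rank_chi2
#' @return A `ranked_list` tibble.
#' @export
rank_cmim <- function(df, n_bins = 10) {
  d <- split_xy(df)
  k <- ncol(d$X)
  B <- apply(d$X, 2, discretize, n_bins = n_bins)
  rel <- apply(B, 2, mutual_information, b = d$y)
  ps <- rep(Inf, k)              # running min_{g in selected} I(f; Y | g)
  picked <- integer(0)
  scores <- numeric(k)
  order_out <- integer(k)
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(k), picked)
    crit <- if (step == 1) rel[cand] else ps[cand]
    best <- cand[order(-crit, cand)][1]
    order_out[step] <- best
    scores[best] <- if (step == 1) rel[best] else ps[best]
    picked <- c(picked, best)
    if (step < k) {
      for (f in setdiff(cand, best)) {
        v <- conditional_mutual_information(B[, f], d$y, B[, best])
        if (v < ps[f]) ps[f] <- v
      }
    }
  }
  out <- tibble(method = "cmim", rank = seq_len(k),
                feature = d$features[order_out],
                score = unname(scores[order_out]))
  class(out) <- c("ranked_list", class(out))
  out
}

#' MRMR ranking
#'
#' Minimum-redundancy maximum-relevance greedy forward selection: the first
#' feature maximizes relevance `D = I(f; Y)`; later picks maximize
#' `D - R` (`variant = "MID"`) or `D / R` (`variant = "MIQ"`), where `R` is
#' the mean mutual information with already-selected features (`R = 0` in
#' MIQ is guarded by `eps`).
#'
#' @inheritParams rank_chi2
#' @param variant `"MID"` (difference) or `"MIQ"` (quotient).
#' @param eps Zero-redundancy guard for the MIQ quotient.
#' @return A `ranked_list` tibble.
#' @export
rank_mrmr <- function(df, variant = c("MID", "MIQ"), n_bins = 10,
                      eps = 1e-12) {
  variant <- match.arg(variant)
  d <- split_xy(df)
  k <- ncol(d$X)
  B <- apply(d$X, 2, discretize, n_bins = n_bins)
  rel <- apply(B, 2, mutual_information, b = d$y)
  red_sum <- numeric(k)
  picked <- integer(0)
  scores <- numeric(k)
  order_out <- integer(k)
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(k), picked)
    crit <- if (step == 1) rel[cand] else {
      R <- red_sum[cand] / length(picked)
      if (variant == "MID") rel[cand] - R
      else rel[cand] / pmax(R, eps)
    }
    best <- cand[order(-crit, cand)][1]
    order_out[step] <- best
    scores[best] <- crit[match(best, cand)]
    picked <- c(picked, best)
    if (step < k) {
      mi_new <- apply(B[, setdiff(cand, best), drop = FALSE], 2,
                      mutual_information, b = B[, best])
      red_sum[setdiff(cand, best)] <-
        red_sum[setdiff(cand, best)] + mi_new
    }
  }
  out <- tibble(method = paste0("mrmr_", tolower(variant)),
                rank = seq_len(k), feature = d$features[order_out],
                score = unname(scores[order_out]))
  class(out) <- c("ranked_list", class(out))
  out
}

#' Rank features with one or several methods
#'
#' Dispatcher over the seven filter rankers (and, with
#' `methods = ranking_methods(aggregates = TRUE)`, the Borda and RRA
#' aggregates of the seven).
#'
#' @param df A standardized feature table with a `stage` column.
#' @param methods Character vector of method names, see
#'   [ranking_methods()].
#' @param relieff_k ReliefF neighbour count.
#' @param n_bins Discretization bins for the information-theoretic rankers.
#' @return A single `ranked_list` tibble, row-bound across methods.
#' @examples
#' tab <- simulate_feature_table(n = 120, effect = 2, seed = 1) |>
#'   standardize_features()
#' rank_features(tab, methods = "fisher")
#' @export
rank_features <- function(df, methods = ranking_methods(),
                          relieff_k = 10, n_bins = 10) {
  base <- setdiff(methods, c("borda", "rra"))
  lists <- purrr::map(base, function(m) {
    switch(m,
      relieff  = rank_relieff(df, k = relieff_k),
      fisher   = rank_fisher(df),
      chi2     = rank_chi2(df, n_bins = n_bins),
      infogain = rank_infogain(df, n_bins = n_bins),
      cmim     = rank_cmim(df, n_bins = n_bins),
      mrmr_mid = rank_mrmr(df, "MID", n_bins = n_bins),
      mrmr_miq = rank_mrmr(df, "MIQ", n_bins = n_bins),
      abort(sprintf("unknown ranking method `%s`", m)))
  })
  out <- dplyr::bind_rows(lists)
  if ("borda" %in% methods) out <- dplyr::bind_rows(out, aggregate_borda(out))
  if ("rra" %in% methods) {
    sevens <- out |> dplyr::filter(!.data$method %in% c("borda", "rra"))
    out <- dplyr::bind_rows(out, aggregate_rra(sevens))
  }
  class(out) <- c("ranked_list", class(out))
  out
}

#' Names of the available ranking methods
#' @param aggregates Include the two rank-aggregation methods?
#' @return Character vector.
#' @export
ranking_methods <- function(aggregates = FALSE) {
  m <- c("relieff", "fisher", "chi2", "infogain", "cmim",
         "mrmr_mid", "mrmr_miq")
  if (aggregates) c(m, "borda", "rra") else m
}
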