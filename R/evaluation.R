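# Evaluation protocol: Tanimoto set overlap, bootstrap stability profiles,
# between-method similarity, the balanced per-subject epoch sampler,
# repeated random sub-sampling classification accuracy (1-NN and MLFN),
# and Kneedle knee-point selection.

#' Tanimoto index of two feature sets
#'
#' Set overlap `|a intersect b| / |a union b|`, i.e.
#' `1 - (|a| + |b| - 2|ab|) / (|a| + |b| - |ab|)`: 0 for disjoint sets,
#' 1 for identical sets. Two empty sets count as identical (1), one empty
#' set as disjoint (0).
#'
#' @param a,b Vectors interpreted as sets.
#' @return Value in `[0, 1]`.
#' @examples
#' tanimoto(c(1, 2, 3), c(2, 3, 4)) # 0.5
#' @export
tanimoto <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0) return(1)
  if (length(a) == 0 || length(b) == 0) return(0)
  i <- length(intersect(a, b))
  i / (length(a) + length(b) - i)
}

# resolve a ranker argument: built-in method name or function(df) ->
# ranked_list
as_ranker <- function(ranker, relieff_k = 10, n_bins = 10) {
  if (is.function(ranker)) return(ranker)
  force(ranker)
  function(df) rank_features(df, methods = ranker,
                             relieff_k = relieff_k, n_bins = n_bins)
}

#' Bootstrap stability profile of a ranking method
#'
#' Draws `n_boot` bootstrap replicates (rows sampled with replacement,
#' same size), re-standardizes and re-ranks each, and for every subset
#' size `d` reports the mean Tanimoto overlap of the replicates' top-`d`
#' sets over all `n_boot (n_boot - 1) / 2` pairs. A data-independent
#' ranker therefore scores exactly 1 at every `d`.
#'
#' @param df A raw (unstandardized) feature table with a `stage` column.
#' @param ranker A method name from [ranking_methods()] (including
#'   `"borda"`/`"rra"`) or a function `df -> ranked_list`.
#' @param d_values Subset sizes (default the odd sizes 1-29); must not
#'   exceed the feature count.
#' @param n_boot Number of bootstrap replicates (default 50).
#' @param seed Integer seed.
#' @param restandardize Re-standardize each replicate before ranking
#'   (default `TRUE`).
#' @param relieff_k,n_bins Passed to the built-in rankers.
#' @return A tibble of class `stability_profile` with columns `method`,
#'   `d`, `stability`.
#' @export
stability_profile <- function(df, ranker, d_values = seq(1, 29, 2),
                              n_boot = 50, seed = 1, restandardize = TRUE,
                              relieff_k = 10, n_bins = 10) {
  if (max(d_values) > length(feature_cols(df)))
    abort("`d_values` exceeds the number of features")
  if (n_boot < 2) abort("`n_boot` must be >= 2")
  label <- if (is.function(ranker)) "custom" else paste(ranker,
                                                        collapse = "+")
  fn <- as_ranker(ranker, relieff_k, n_bins)
  orders <- purrr::map(seq_len(n_boot), function(b) {
    idx <- with_seed(mix_seed(seed, b), sample.int(nrow(df), replace = TRUE))
    rep_df <- df[idx, , drop = FALSE]
    if (restandardize) rep_df <- standardize_features(rep_df)
    fn(rep_df)$feature
  })
  prof <- purrr::map_dfr(d_values, function(d) {
    tops <- purrr::map(orders, ~ .x[seq_len(d)])
    pairs <- utils::combn(n_boot, 2)
    s <- mean(vapply(seq_len(ncol(pairs)), function(j)
      tanimoto(tops[[pairs[1, j]]], tops[[pairs[2, j]]]), numeric(1)))
    tibble(method = label, d = d, stability = s)
  })
  class(prof) <- c("stability_profile", class(prof))
  prof
}

#' Stability profiles for several methods on shared bootstraps
#'
#' Efficient batch version of [stability_profile()]: the bootstrap
#' replicates are drawn once, every filter method (plus the aggregates)
#' ranks each replicate, and the per-`d` mean pairwise Tanimoto values are
#' assembled for all methods.
#'
#' @inheritParams stability_profile
#' @param methods Method names (default all seven plus Borda and RRA).
#' @return A `stability_profile` tibble covering all methods.
#' @export
stability_profiles <- function(df, methods = ranking_methods(aggregates = TRUE),
                               d_values = seq(1, 29, 2), n_boot = 50,
                               seed = 1, restandardize = TRUE,
                               relieff_k = 10, n_bins = 10) {
  if (max(d_values) > length(feature_cols(df)))
    abort("`d_values` exceeds the number of features")
  all_orders <- purrr::map(seq_len(n_boot), function(b) {
    idx <- with_seed(mix_seed(seed, b), sample.int(nrow(df), replace = TRUE))
    rep_df <- df[idx, , drop = FALSE]
    if (restandardize) rep_df <- standardize_features(rep_df)
    rl <- rank_features(rep_df, methods = methods,
                        relieff_k = relieff_k, n_bins = n_bins)
    split(rl$feature, rl$method)[methods]
  })
  pairs <- utils::combn(n_boot, 2)
  prof <- purrr::map_dfr(methods, function(m) {
    orders <- purrr::map(all_orders, m)
    purrr::map_dfr(d_values, function(d) {
      tops <- purrr::map(orders, ~ .x[seq_len(d)])
      s <- mean(vapply(seq_len(ncol(pairs)), function(j)
        tanimoto(tops[[pairs[1, j]]], tops[[pairs[2, j]]]), numeric(1)))
      tibble(method = m, d = d, stability = s)
    })
  })
  class(prof) <- c("stability_profile", class(prof))
  prof
}

#' Between-method similarity matrix
#'
#' Tanimoto overlap of the top-`d` feature sets of every pair of ranking
#' methods, each derived from the complete table. Symmetric with unit
#' diagonal.
#'
#' @param rankings A bound `ranked_list` tibble over several methods.
#' @param d Subset size (default 29).
#' @return A symmetric numeric matrix of class `similarity_matrix` with
#'   method names as dimnames.
#' @export
similarity_matrix <- function(rankings, d = 29) {
  rankings <- split_rankings(rankings)
  if (d > nrow(rankings[[1]])) abort("`d` exceeds the feature count")
  tops <- purrr::map(rankings, ~ .x$feature[seq_len(d)])
  m <- length(tops)
  S <- matrix(1, m, m, dimnames = list(names(tops), names(tops)))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i < j) S[i, j] <- S[j, i] <- tanimoto(tops[[i]], tops[[j]])
  }
  structure(S, class = c("similarity_matrix", "matrix", "array"))
}

#' Balanced per-subject epoch sampling
#'
#' Draws the same number of epochs (`quota`) from every subject, with the
#' per-stage counts proportional to that subject's own stage frequencies
#' (largest-remainder rounding, ties to the earlier stage), sampled
#' without replacement.
#'
#' @param df A feature table with `subject` and `stage` columns.
#' @param quota Epochs per subject (must not exceed any subject's total).
#' @param seed Integer seed.
#' @return The sampled feature table (quota rows per subject).
#' @export
sample_balanced <- function(df, quota, seed = 1) {
  purrr::map_dfr(split(df, df$subject), function(sub) {
    if (quota > nrow(sub))
      abort(sprintf("quota %d exceeds subject %s's %d epochs",
                    quota, sub$subject[1], nrow(sub)))
    stages <- unique(as.character(sub$stage))
    freq <- table(factor(as.character(sub$stage), levels = stages)) /
      nrow(sub)
    alloc <- largest_remainder(as.numeric(freq) * quota)
    s <- mix_seed(seed, match(sub$subject[1], sort(unique(df$subject))))
    picked <- unlist(purrr::map(seq_along(stages), function(i) {
      rows <- which(as.character(sub$stage) == stages[i])
      with_seed(mix_seed(s, i), sample(rows, alloc[i]))
    }))
    sub[sort(picked), , drop = FALSE]
  })
}

# integer allocation of `target` (non-negative reals summing to an integer
# total) by largest remainder; ties broken by index
largest_remainder <- function(target) {
  base <- floor(target)
  left <- round(sum(target)) - sum(base)
  if (left > 0) {
    rem <- target - base
    extra <- order(-rem, seq_along(rem))[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Classification accuracy
#'
#' Fraction of correctly classified epochs.
#' @param predictions,labels Equal-length, non-empty label vectors.
#' @return Value in `[0, 1]`.
#' @export
classification_accuracy <- function(predictions, labels) {
  if (length(predictions) == 0 || length(predictions) != length(labels))
    abort("`predictions` and `labels` must be non-empty and equal length")
  mean(as.character(predictions) == as.character(labels))
}

# stratified train/test split; returns row indices. Every class with >= 2
# members appears in both folds, so a test class absent from training can
# only arise from singleton classes.
stratified_split <- function(y, train_frac, seed) {
  with_seed(seed, {
    train <- unlist(lapply(split(seq_along(y), y), function(rows) {
      if (length(rows) == 0) return(integer(0))
      n_tr <- max(1, min(length(rows) - 1, round(length(rows) * train_frac)))
      sample(rows, n_tr)
    }))
    sort(train)
  })
}

# one classification run; returns accuracy or NA when the run must be
# redrawn (test class absent from training / non-convergence)
run_classifier <- function(X, y, d_feats, classifier, train_frac, seed,
                           hidden = 12, maxit = 100, decay = 1e-4) {
  tr <- stratified_split(y, train_frac, seed)
  te <- setdiff(seq_along(y), tr)
  if (length(te) == 0) return(NA_real_)
  if (!all(unique(y[te]) %in% unique(y[tr]))) return(NA_real_)
  Xtr <- X[tr, d_feats, drop = FALSE]
  Xte <- X[te, d_feats, drop = FALSE]
  if (classifier == "knn") {
    pred <- with_seed(seed, class::knn(Xtr, Xte, y[tr], k = 1))
  } else {
    fit <- tryCatch(
      with_seed(seed, nnet::nnet(Xtr, nnet::class.ind(y[tr]), size = hidden,
                                 softmax = TRUE, maxit = maxit,
                                 decay = decay, trace = FALSE,
                                 MaxNWts = 5000)),
      error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    pr <- predict(fit, Xte)
    pred <- colnames(pr)[max.col(pr, ties.method = "first")]
  }
  classification_accuracy(pred, y[te])
}

#' Mean classification accuracy on the top-d features
#'
#' Repeated random sub-sampling validation: `n_runs` stratified
#' train/test splits, a classifier on the `d` best features of `ranking`,
#' and the mean test accuracy. The 1-NN classifier uses Euclidean
#' distance; the MLFN is a three-layer feed-forward net with 12 logistic
#' hidden units and softmax outputs. Runs whose test fold contains a class
#' unseen in training, or whose net fails to train, are redrawn (up to
#' `10 * n_runs` attempts).
#'
#' @param df A standardized feature table with a `stage` column.
#' @param ranking A single-method `ranked_list` (or its `feature` order).
#' @param d Number of top features to use.
#' @param classifier `"knn"` or `"mlfn"`.
#' @param n_runs Number of validation runs (default 200).
#' @param train_frac Training fraction per run (default 0.7).
#' @param seed Integer seed.
#' @param ... Passed to the MLFN (`hidden`, `maxit`, `decay`).
#' @return Mean accuracy over the runs.
#' @export
subsampling_accuracy <- function(df, ranking, d, classifier = c("knn", "mlfn"),
                                 n_runs = 200, train_frac = 0.7, seed = 1,
                                 ...) {
  classifier <- match.arg(classifier)
  feats <- if (is.data.frame(ranking)) ranking$feature else ranking
  if (d < 1 || d > length(feats)) abort("invalid `d`")
  X <- as.matrix(df[feature_cols(df)])
  y <- factor(as.character(df$stage))
  accs <- numeric(n_runs)
  attempt <- 0
  for (r in seq_len(n_runs)) {
    repeat {
      attempt <- attempt + 1
      if (attempt > 10 * n_runs) abort("too many redrawn validation runs")
      a <- run_classifier(X, y, feats[seq_len(d)], classifier, train_frac,
                          mix_seed(seed, attempt), ...)
      if (!is.na(a)) break
    }
    accs[r] <- a
  }
  mean(accs)
}

#' Accuracy curve over feature-count grid
#'
#' Evaluates [subsampling_accuracy()] on a grid of subset sizes `d`,
#' re-using the same validation splits across `d` (so curves are paired),
#' and attaches the Kneedle-selected optimum.
#'
#' @inheritParams subsampling_accuracy
#' @param d_values Feature counts (default odd sizes 1-15).
#' @param sensitivity Kneedle sensitivity (default 1).
#' @return A tibble of class `accuracy_curve` with columns `method`,
#'   `classifier`, `d`, `accuracy` and attribute `optimum_d`.
#' @export
accuracy_curve <- function(df, ranking, d_values = seq(1, 15, 2),
                           classifier = c("knn", "mlfn"), n_runs = 200,
                           train_frac = 0.7, seed = 1, sensitivity = 1,
                           ...) {
  classifier <- match.arg(classifier)
  method <- if (is.data.frame(ranking)) ranking$method[1] else "custom"
  curve <- purrr::map_dfr(d_values, function(d) {
    tibble(method = method, classifier = classifier, d = d,
           accuracy = subsampling_accuracy(df, ranking, d, classifier,
                                           n_runs, train_frac, seed, ...))
  })
  opt <- kneedle(curve$d, curve$accuracy, sensitivity = sensitivity)
  attr(curve, "optimum_d") <- opt
  class(curve) <- c("accuracy_curve", class(curve))
  curve
}

#' Kneedle knee-point selection
#'
#' Finds the knee of a saturating (concave increasing) performance curve:
#' both axes are min-max normalized, the difference curve
#' `y_norm - x_norm` is formed, and a local maximum is a knee when the
#' difference later drops below `max - sensitivity * mean(dx)` before the
#' next local maximum (or the end). Among several knees the smallest `x`
#' wins (favouring compact feature sets). Without any knee, the `x`
#' maximizing the difference curve is returned with a warning.
#'
#' @param x Increasing grid (feature counts).
#' @param y Performance values (same length, >= 3).
#' @param sensitivity Kneedle sensitivity S (default 1).
#' @return One element of `x`.
#' @examples
#' kneedle(c(1, 3, 5, 7, 9), c(0.50, 0.74, 0.76, 0.77, 0.77)) # 3
#' @export
kneedle <- function(x, y, sensitivity = 1) {
  if (length(x) < 3 || length(x) != length(y)) abort("need >= 3 points")
  if (is.unsorted(x, strictly = TRUE)) abort("`x` must be increasing")
  xn <- (x - min(x)) / (max(x) - min(x))
  if (diff(range(y)) == 0) {
    warn("flat curve: no knee; returning the first point")
    return(x[1])
  }
  yn <- (y - min(y)) / (max(y) - min(y))
  dif <- yn - xn
  n <- length(x)
  lmx <- which(vapply(seq_len(n), function(i) {
    i > 1 && i < n && dif[i] > dif[i - 1] && dif[i] >= dif[i + 1]
  }, logical(1)))
  knees <- integer(0)
  for (i in lmx) {
    thr <- dif[i] - sensitivity * mean(diff(xn))
    nxt <- lmx[lmx > i]
    stop_at <- if (length(nxt)) nxt[1] else n
    if (any(dif[(i + 1):stop_at] < thr)) knees <- c(knees, i)
  }
  if (length(knees) == 0) {
    warn("no knee passed the sensitivity threshold; returning the maximum of the difference curve")
    return(x[which.max(dif)])
  }
  x[min(knees)]
}
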