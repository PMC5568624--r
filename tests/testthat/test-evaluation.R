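# Tanimoto overlap, stability profiles, similarity, balanced sampling,
# classification accuracy and Kneedle.

test_that("Tanimoto index follows the set-overlap formula", {
  expect_equal(tanimoto(1:3, 1:3), 1)
  expect_equal(tanimoto(1:3, 4:6), 0)
  expect_equal(tanimoto(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_equal(tanimoto(integer(0), integer(0)), 1)
  expect_equal(tanimoto(integer(0), 1:3), 0)
  expect_equal(tanimoto(c(1, 1, 2), c(2, 2, 1)), 1)  # set semantics
})

test_that("a data-independent ranker has stability 1 at every d", {
  tab <- simulate_feature_table(n = 80, seed = 2)
  const_ranker <- function(df) {
    f <- grep("^X", names(df), value = TRUE)
    tibble::tibble(method = "const", rank = seq_along(f), feature = f,
                   score = 0)
  }
  sp <- stability_profile(tab, const_ranker, d_values = c(1, 3, 5, 9),
                          n_boot = 10, seed = 4)
  expect_true(all(sp$stability == 1))
})

test_that("n_boot = 2 gives a single-pair stability value", {
  tab <- simulate_feature_table(n = 80, seed = 3)
  sp <- stability_profile(tab, "fisher", d_values = 5, n_boot = 2, seed = 1)
  expect_equal(nrow(sp), 1)
  expect_gte(sp$stability, 0)
  expect_lte(sp$stability, 1)
  expect_error(stability_profile(tab, "fisher", d_values = 60, n_boot = 5),
               "exceeds")
})

test_that("batch stability profiles agree with the single-method path", {
  tab <- simulate_feature_table(n = 100, effect = 2, seed = 6)
  multi <- stability_profiles(tab, methods = c("fisher", "chi2"),
                              d_values = c(3, 7), n_boot = 6, seed = 11)
  single <- stability_profile(tab, "fisher", d_values = c(3, 7),
                              n_boot = 6, seed = 11)
  expect_equal(multi$stability[multi$method == "fisher"], single$stability)
  expect_true(all(multi$stability >= 0 & multi$stability <= 1))
})

test_that("similarity matrices are symmetric with unit diagonal", {
  tab <- make_std_table(n = 150, seed = 7)
  rl <- rank_features(tab, c("fisher", "chi2", "infogain"))
  S <- similarity_matrix(rl, d = 10)
  expect_equal(diag(S), c(chi2 = 1, fisher = 1, infogain = 1))
  expect_equal(S, t(S))
  expect_true(all(S >= 0 & S <= 1))
  # identical top-d sets give entry 1
  rl2 <- dplyr::bind_rows(rank_fisher(tab),
                          dplyr::mutate(rank_fisher(tab), method = "copy"))
  expect_equal(similarity_matrix(rl2, d = 10)["fisher", "copy"], 1)
  expect_error(similarity_matrix(rl, d = 100), "exceeds")
})

test_that("balanced sampling honours quotas and largest-remainder rounding", {
  df <- tibble::tibble(
    subject = rep(c("A", "B"), each = 300),
    stage = c(rep(c("W", "S1"), each = 150),          # A: 50/50 two stages
              rep(c("W", "S1", "S2"), each = 100)),   # B: thirds
    F1 = rnorm(600))
  out <- sample_balanced(df, 100, seed = 3)
  expect_equal(as.vector(table(out$subject)), c(100, 100))
  a <- table(out$stage[out$subject == "A"])
  expect_equal(as.vector(a[c("W", "S1")]), c(50, 50))
  b <- table(out$stage[out$subject == "B"])
  # (1/3, 1/3, 1/3) x 100 -> 34/33/33, first-come tie-break
  expect_equal(as.vector(b[c("W", "S1", "S2")]), c(34, 33, 33))
  expect_error(sample_balanced(df, 400, seed = 1), "exceeds")
  # determinism
  expect_identical(out, sample_balanced(df, 100, seed = 3))
})

test_that("classification accuracy is the fraction of true detections", {
  expect_equal(classification_accuracy(c(rep("a", 80), rep("b", 20)),
                                       rep("a", 100)), 0.8)
  expect_equal(classification_accuracy(letters[1:5], letters[1:5]), 1)
  expect_equal(classification_accuracy(rep("a", 5), rep("b", 5)), 0)
  expect_error(classification_accuracy(character(0), character(0)),
               "non-empty")
})

test_that("1-NN: memorization, separation, chance level", {
  # a test point identical to a training point takes its label
  tr <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
  pred <- class::knn(tr, matrix(c(1, 1), 1), factor(c("a", "b")), k = 1)
  expect_equal(as.character(pred), "b")
  # two well-separated classes: accuracy >= 0.95 on the top-2 features
  tab <- make_std_table(n = 300, effect = 4, seed = 8, n_classes = 2)
  rl <- rank_fisher(tab)
  expect_gte(subsampling_accuracy(tab, rl, 2, "knn", n_runs = 20, seed = 5),
             0.95)
  # shuffled labels, 5 classes: accuracy ~ 0.2
  tab5 <- make_std_table(n = 400, effect = 2, seed = 9)
  tab5$stage <- with_seed_test(7, sample(tab5$stage))
  acc <- subsampling_accuracy(tab5, rank_fisher(tab5), 5, "knn",
                              n_runs = 20, seed = 6)
  expect_lt(abs(acc - 0.2), 0.05)
})

test_that("MLFN: separable toy, constant features, determinism", {
  tab <- make_std_table(n = 240, effect = 4, seed = 10, n_classes = 2)
  rl <- rank_fisher(tab)
  a1 <- subsampling_accuracy(tab, rl, 2, "mlfn", n_runs = 5, seed = 2)
  expect_gte(a1, 0.95)
  a2 <- subsampling_accuracy(tab, rl, 2, "mlfn", n_runs = 5, seed = 2)
  expect_identical(a1, a2)
  # constant features: accuracy equals the majority-class frequency
  tabc <- tab
  for (f in grep("^X", names(tabc), value = TRUE)) tabc[[f]] <- 0
  acc <- subsampling_accuracy(tabc, rl, 3, "mlfn", n_runs = 4, seed = 3)
  maj <- max(table(tab$stage)) / nrow(tab)
  expect_lt(abs(acc - maj), 0.1)
})

test_that("accuracy curves are paired across d and carry a Kneedle optimum", {
  tab <- make_std_table(n = 250, effect = 2, seed = 11)
  rl <- rank_fisher(tab)
  cv <- accuracy_curve(tab, rl, d_values = c(1, 3, 5, 7), classifier = "knn",
                       n_runs = 8, seed = 4)
  expect_s3_class(cv, "accuracy_curve")
  expect_equal(cv$d, c(1, 3, 5, 7))
  expect_true(all(cv$accuracy >= 0 & cv$accuracy <= 1))
  expect_true(attr(cv, "optimum_d") %in% cv$d)
})

test_that("Kneedle finds the documented knees and degenerate fallbacks", {
  expect_equal(kneedle(c(1, 3, 5, 7, 9), c(0.50, 0.74, 0.76, 0.77, 0.77)), 3)
  # adding a constant leaves the knee unchanged
  expect_equal(kneedle(c(1, 3, 5, 7, 9), 0.1 + c(0.50, 0.74, 0.76, 0.77, 0.77)), 3)
  # perfectly linear: fallback with warning
  expect_warning(k <- kneedle(1:5, seq(0.2, 1, 0.2)), "no knee|flat")
  expect_true(k %in% 1:5)
  expect_error(kneedle(1:2, 1:2), "3 points")
  expect_error(kneedle(c(1, 3, 2), c(1, 2, 3)), "increasing")
})
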