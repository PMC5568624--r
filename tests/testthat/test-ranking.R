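# The seven filter rankers: micro examples, oracle cross-checks,
# determinism and invariance properties.

test_that("equal-width discretization follows the declared edge rule", {
  expect_equal(discretize(c(0, 0.5, 1), 2), c(0L, 1L, 1L))
  expect_equal(discretize(rep(4, 10), 5), rep(0L, 10))
  x <- rnorm(100)
  expect_equal(discretize(x, 10), discretize(3 * x - 7, 10))  # affine invariant
  expect_true(all(discretize(x, 10) %in% 0:9))
  expect_error(discretize(x, 1), "n_bins")
})

test_that("mutual information matches plug-in values", {
  a <- rep(c(0, 1), each = 50)
  expect_equal(mutual_information(a, a), log(2))
  b <- rep(c(0, 1, 0, 1), each = 25)  # product table: independent
  expect_equal(mutual_information(a, b), 0, tolerance = 1e-12)
  # joint counts [[2,1],[1,2]]
  aa <- c(0, 0, 0, 1, 1, 1)
  bb <- c(0, 0, 1, 0, 1, 1)
  p <- matrix(c(2, 1, 1, 2) / 6, 2)
  hand <- sum(p * log(p / outer(rowSums(p), colSums(p))))
  expect_equal(mutual_information(aa, bb), hand)
  expect_equal(mutual_information(aa, bb), oracle_mi(aa, bb))
  # conditional MI agrees with the oracle
  cc <- c(0, 1, 0, 1, 0, 1)
  expect_equal(conditional_mutual_information(aa, bb, cc),
               oracle_cmi(aa, bb, cc))
})

test_that("Fisher score: separation, ties, oracle agreement", {
  df <- tibble::tibble(stage = rep(c("W", "S2"), each = 20),
                       F1 = rep(c(1, -1), each = 20),
                       F2 = with_seed_test(1, rnorm(40)),
                       F3 = rep(c(1, -1), each = 20))
  r <- rank_fisher(df)
  expect_equal(r$feature[1:2], c("F1", "F3"))  # tie broken by index
  expect_equal(r$score[1], r$score[2])
  expect_gt(r$score[1], 1e6)  # bounded only by eps
  expect_equal(r$feature[3], "F2")
  tab <- make_std_table(n = 200, seed = 2)
  rf <- rank_fisher(tab)
  X <- as.matrix(tab[grep("^X", names(tab), value = TRUE)])
  sc <- oracle_fisher(X, tab$stage)
  expect_equal(rf$score, sort(sc, decreasing = TRUE), tolerance = 1e-9)
  expect_error(rank_fisher(dplyr::filter(df, stage == "W")), "2 classes")
})

test_that("chi-square: perfect predictor, null mean, permutation invariance", {
  y <- rep(c("W", "S1", "S2"), each = 30)
  df <- tibble::tibble(stage = y, F1 = rep(c(0, 5, 10), each = 30))
  r <- rank_chi2(df, n_bins = 3)
  expect_equal(r$score[1], 90 * (3 - 1))  # n (K - 1) for a diagonal table
  # independent feature: E[chi2] ~ degrees of freedom, mean over 200 draws
  df_dof <- (10 - 1) * (3 - 1)
  sims <- sapply(1:200, function(s) {
    d2 <- tibble::tibble(stage = y, F1 = with_seed_test(s, rnorm(90)))
    rank_chi2(d2, n_bins = 10)$score[1]
  })
  expect_lt(abs(mean(sims) - df_dof), 3)
  tab <- make_std_table(n = 150, seed = 4)
  perm <- with_seed_test(2, sample(nrow(tab)))
  expect_equal(rank_chi2(tab)$score, rank_chi2(tab[perm, ])$score)
})

test_that("information gain equals MI with the class and caps at H(Y)", {
  y <- rep(c("W", "S2"), each = 40)
  df <- tibble::tibble(stage = y, F1 = rep(c(0, 10), each = 40),
                       F2 = with_seed_test(3, rnorm(80)))
  r <- rank_infogain(df, n_bins = 4)
  expect_equal(r$score[r$feature == "F1"], log(2))  # = H(Y), perfect predictor
  expect_gte(r$score[r$feature == "F2"], 0)
  # exact agreement with the MI operation on the same bins
  b2 <- discretize(df$F2, 4)
  expect_equal(r$score[r$feature == "F2"],
               mutual_information(b2, factor(y)))
})

test_that("ReliefF: sign-flip feature wins, noise near zero, guards", {
  # 6-point, 2-class set with one discriminating and one constant feature
  df6 <- tibble::tibble(stage = rep(c("A", "B"), each = 3),
                        F1 = c(1, 1.1, 0.9, -1, -1.1, -0.9),
                        F2 = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5))
  r6 <- rank_relieff(df6, k = 2)
  expect_equal(r6$feature[1], "F1")
  expect_gt(r6$score[r6$feature == "F1"], 0.5)
  expect_equal(r6$score[r6$feature == "F2"], 0)
  # pure-noise weights are small at n = 500
  tab <- make_std_table(n = 500, seed = 6)
  rr <- rank_relieff(tab, k = 10)
  noise <- feature_roles(simulate_feature_table(n = 500, seed = 6))
  noise <- noise$feature[noise$role == "noise"]
  expect_lt(max(abs(rr$score[rr$feature %in% noise])), 0.05)
  expect_error(rank_relieff(df6, k = 5), "reduce")
})

test_that("CMIM: duplicate collapse and exhaustive-oracle agreement", {
  tab <- make_std_table(n = 250, seed = 7, k_informative = 3,
                        k_redundant = 0, k_noise = 2)
  tab$Xdup <- tab$X1  # exact duplicate of an informative feature
  r <- rank_cmim(tab)
  pos <- function(f) r$rank[r$feature == f]
  # whichever twin is picked later collapses below every distinct
  # informative feature
  expect_gt(max(pos("X1"), pos("Xdup")), max(pos("X2"), pos("X3")))
  expect_lte(min(pos("X1"), pos("Xdup")), 4)
  # ordering equals the brute-force implementation (8 features x 200 rows)
  for (s in 1:3) {
    t8 <- make_std_table(n = 200, seed = s, k_informative = 3,
                         k_redundant = 2, k_noise = 3)
    B <- apply(as.matrix(t8[grep("^X", names(t8))]), 2, discretize, n_bins = 10)
    expect_equal(rank_cmim(t8)$feature,
                 colnames(B)[oracle_cmim_order(B, t8$stage)])
  }
})

test_that("MRMR: duplicate penalty, MID/MIQ agreement on first pick, oracle", {
  tab <- make_std_table(n = 250, seed = 8, k_informative = 3,
                        k_redundant = 0, k_noise = 2)
  tab$Xdup <- tab$X1
  rmid <- rank_mrmr(tab, "MID")
  pos <- function(f) rmid$rank[rmid$feature == f]
  expect_gt(max(pos("X1"), pos("Xdup")), max(pos("X2"), pos("X3")))
  rmiq <- rank_mrmr(tab, "MIQ")
  expect_equal(rmid$feature[1], rmiq$feature[1])  # both start at max relevance
  for (s in 4:6) {
    t8 <- make_std_table(n = 200, seed = s, k_informative = 3,
                         k_redundant = 2, k_noise = 3)
    B <- apply(as.matrix(t8[grep("^X", names(t8))]), 2, discretize, n_bins = 10)
    expect_equal(rank_mrmr(t8, "MID")$feature,
                 colnames(B)[oracle_mrmr_order(B, t8$stage, "MID")])
    expect_equal(rank_mrmr(t8, "MIQ")$feature,
                 colnames(B)[oracle_mrmr_order(B, t8$stage, "MIQ")])
  }
})

test_that("rankers recover informative features (reduced sweep)", {
  hits <- sapply(1:6, function(s) {
    tab <- simulate_feature_table(n = 400, k_informative = 5,
                                  k_redundant = 0, k_noise = 44,
                                  effect = 2, seed = 100 + s)
    inf <- feature_roles(tab)$feature[feature_roles(tab)$role == "informative"]
    tab <- standardize_features(tab)
    rl <- rank_features(tab)
    sapply(ranking_methods(), function(m)
      sum(inf %in% rl$feature[rl$method == m & rl$rank <= 10]))
  })
  expect_true(all(hits >= 4))
})

test_that("rankers are deterministic and scale-invariant after standardization", {
  raw <- simulate_feature_table(n = 150, effect = 1.5, seed = 11)
  raw2 <- raw
  raw2$X3 <- raw2$X3 * 100  # rescale a raw feature
  r1 <- rank_features(standardize_features(raw))
  r2 <- rank_features(standardize_features(raw2))
  expect_equal(r1$feature, r2$feature)
  r3 <- rank_features(standardize_features(raw))
  expect_identical(r1, r3)
})
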