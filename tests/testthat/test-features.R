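# Per-epoch features: conventions on degenerate inputs, closed-form
# behaviour on constructed signals, scaling laws, and oracle agreement on
# random epochs (the large-scale oracle battery lives in the acceptance
# suite).

cfg <- feature_config()

test_that("statistical features: conventions and arithmetic", {
  expect_equal(unname(statistical_features(c(1, 2, 3, 4))[c("mean", "median", "min", "max")]),
               c(2.5, 2.5, 1, 4))
  const <- statistical_features(rep(3, 100))
  expect_equal(unname(const), c(3, 3, 3, 0, 0, 0, 0, 3))
  expect_error(statistical_features(numeric(0)), "empty")
  s <- statistical_features(rnorm(3000))
  expect_equal(s[["sd"]]^2, s[["var"]], tolerance = 1e-9)
  expect_lt(abs(s[["skewness"]]), 0.2)
  expect_lt(abs(s[["kurtosis"]] - 3), 0.5)  # raw kurtosis convention
})

test_that("zero-crossing rate counts sign changes", {
  expect_equal(zero_crossing_rate(rep(2, 50)), 0)
  expect_equal(zero_crossing_rate(c(1, -1, 1, -1)), 3)
  s10 <- sin(2 * pi * 10 * (0:2999) / 100)
  expect_lte(abs(zero_crossing_rate(s10) - 600), 1)
})

test_that("Hjorth parameters satisfy the sine and noise laws", {
  w <- 0.3
  s <- sin(w * (0:49999))
  h <- hjorth(s)
  expect_equal(h[["mobility"]], w, tolerance = 1e-2)
  expect_equal(h[["complexity"]], 1, tolerance = 1e-2)
  hw <- hjorth(rnorm(5000))
  expect_gt(hw[["complexity"]], 1)
  expect_equal(unname(hjorth(rep(1, 100))), c(0, 0, 0))
})

test_that("wavelet-packet features: Parseval, zero input, band dominance", {
  x <- simulate_stage_epoch(dplyr::filter(stage_specs(), stage == "SWS"),
                            seed = 3)$eeg
  wf <- wavelet_packet_features(x, 100, cfg)
  leaves <- wavelet_packet(x, cfg$wp_level, cfg$wp_wavelet)
  expect_length(leaves, 128)
  expect_equal(wf[["E_total"]], sum(sapply(leaves, function(v) sum(v^2))),
               tolerance = 1e-6)
  expect_equal(wf[["E_total"]], sum(x^2), tolerance = 1e-6)
  expect_equal(unname(wavelet_packet_features(numeric(3000), 100, cfg)),
               rep(0, 14))
  # delta-only epoch: delta dominates and delta/theta is the largest ratio
  spd <- list(stage = "SWS", delta = 1, theta = 0, alpha = 0, beta = 0,
              spindle_rate = 0, emg_tone = 1, eog_activity = 0)
  xd <- simulate_stage_epoch(spd, seed = 5)$eeg
  wfd <- wavelet_packet_features(xd, 100, cfg)
  expect_gte(wfd[["E_delta"]] / wfd[["E_total"]], 0.8)
  ratios <- wfd[c("r_alpha_deltatheta", "r_delta_alphatheta",
                  "r_theta_alphadelta", "r_delta_theta", "r_alpha_theta")]
  expect_equal(names(which.max(ratios)), "r_delta_theta")
})

test_that("wavelet-packet leaves are frequency ordered", {
  for (f0 in c(2.1, 11.5, 27.3)) {
    x <- sin(2 * pi * f0 * (0:3071) / 100)
    en <- sapply(wavelet_packet(x, 7), function(v) sum(v^2))
    expect_equal(which.max(en), floor(f0 / (50 / 128)) + 1)
  }
})

test_that("spectral entropy: flat and degenerate spectra, white noise", {
  expect_equal(spectral_entropy_psd(rep(0.25, 8)), 1)
  expect_equal(spectral_entropy_psd(c(0, 1, 0, 0)), 0)
  expect_equal(spectral_entropy(numeric(3000), 100, cfg), 0)
  expect_gte(spectral_entropy(rnorm(3000), 100, cfg), 0.9)
})

test_that("Renyi entropy: uniform, degenerate, hand-computed cases", {
  # uniform over K bins -> log K
  K <- 16
  x <- rep(seq(0, 1, length.out = K), each = 10) + 1e-6
  expect_equal(renyi_entropy(x, feature_config(n_hist_bins = K)), log(K),
               tolerance = 1e-6)
  expect_equal(renyi_entropy(rep(1, 50), cfg), 0)
  # p = (1/2, 1/2), alpha = 2 -> log 2
  expect_equal(renyi_entropy(c(0, 0, 1, 1), feature_config(n_hist_bins = 2)),
               log(2))
})

test_that("approximate entropy: constant, periodic vs random, printed variant", {
  expect_equal(approximate_entropy(rep(2, 100), cfg), 0)
  per <- rep(c(1, 0), 150)
  rnd <- with_seed_test(4, runif(300))
  expect_lt(approximate_entropy(per, cfg), approximate_entropy(rnd, cfg))
  # literal published form: both averages over length-m correlations
  x <- rnorm(200)
  v <- approximate_entropy(x, feature_config(apen_as_printed = TRUE))
  expect_lt(abs(v), 0.05)  # near-zero by construction of the printed form
})

test_that("permutation entropy: monotone, hand case, uniform limit", {
  expect_equal(permutation_entropy(1:100, cfg), 0)
  expect_equal(permutation_entropy(c(1, 3, 2, 4), feature_config(perm_m = 2)),
               -(2 / 3) * log(2 / 3) - (1 / 3) * log(1 / 3))
  u <- with_seed_test(9, runif(3000))
  expect_equal(permutation_entropy(u, cfg), log(6), tolerance = 0.02 * log(6))
})

test_that("Petrosian fractal dimension follows the sign-change formula", {
  expect_equal(petrosian_fd(1:100), 1)
  n <- 64
  alt <- rep(c(0, 1), n / 2)
  expect_equal(petrosian_fd(alt),
               log10(n) / (log10(n) + log10(n / (n + 0.4 * (n - 2)))))
})

test_that("Teager energy: cancellation, hand value, cosine law", {
  expect_equal(teager_energy(rep(3, 10)), 0)
  expect_equal(teager_energy(c(1, 2, 3)), 1)
  w <- 2 * pi * 7 / 100
  x <- 2 * cos(w * (0:9999))
  expect_equal(teager_energy(x), 4 * sin(w)^2, tolerance = 1e-3)
})

test_that("energy and boundary ratio conventions", {
  expect_equal(signal_energy(c(1, -1, 1, -1)), 1)
  expect_equal(signal_energy(numeric(10)), 0)
  expect_equal(energy_ratio(4, 2), 2)
  expect_equal(energy_ratio(4, 0), 1)
  expect_equal(energy_ratio(4, NA), 1)
})

test_that("curve length: constant, hand value, homogeneity", {
  expect_equal(mean_curve_length(rep(1, 10)), 0)
  expect_equal(mean_curve_length(c(0, 1, 0, 1)), 3)
  x <- rnorm(500)
  expect_equal(mean_curve_length(3 * x), 3 * mean_curve_length(x))
})

test_that("Hurst exponent: white noise near 0.5, integration raises it", {
  hs <- sapply(1:50, function(s) hurst_exponent(with_seed_test(s, rnorm(3000)), cfg))
  expect_gt(mean(hs), 0.4)
  expect_lt(mean(hs), 0.65)
  x <- with_seed_test(2, rnorm(3000))
  expect_gt(hurst_exponent(cumsum(x), cfg), hurst_exponent(x, cfg))
  expect_equal(hurst_exponent(rep(1, 100), cfg), 0)
})

test_that("wake AR model: recovery, selection size, determinism", {
  eps <- lapply(1:10, function(i)
    with_seed_test(i, as.numeric(stats::arima.sim(list(ar = c(0.5, -0.3)), 3000))))
  m <- fit_wake_ar_model(eps, feature_config(ar_order = 2), seed = 6)
  expect_length(m$selected, 5)  # floor(10 / 2)
  expect_lt(max(abs(m$coefficients - c(0.5, -0.3))), 0.1)
  m2 <- fit_wake_ar_model(eps, feature_config(ar_order = 2), seed = 6)
  expect_identical(m$selected, m2$selected)
  expect_error(fit_wake_ar_model(eps[1], feature_config()), "at least 2")
})

test_that("Itakura spectral distance separates processes and is stateless", {
  cfg2 <- feature_config(ar_order = 2)
  eps <- lapply(1:6, function(i)
    with_seed_test(i, as.numeric(stats::arima.sim(list(ar = c(0.6, -0.2)), 3000))))
  m <- fit_wake_ar_model(eps, cfg2, seed = 1)
  self_ep <- with_seed_test(99, as.numeric(stats::arima.sim(list(ar = c(0.6, -0.2)), 10000)))
  other_ep <- with_seed_test(98, as.numeric(stats::arima.sim(list(ar = -0.6), 3000)))
  expect_lte(itakura_spectral_distance(m, self_ep, cfg2), 0.05)
  expect_gt(itakura_spectral_distance(m, other_ep, cfg2),
            itakura_spectral_distance(m, self_ep, cfg2))
  # elementwise independence: permuting an epoch list permutes outputs
  eplist <- eps[1:3]
  d1 <- sapply(eplist, function(e) itakura_spectral_distance(m, e, cfg2))
  d2 <- sapply(rev(eplist), function(e) itakura_spectral_distance(m, e, cfg2))
  expect_equal(d1, rev(d2))
  expect_error(itakura_spectral_distance(m, rep(1, 3000), cfg2), "degenerate")
})

test_that("EMG spectral features scale quadratically and handle zero", {
  expect_equal(unname(emg_spectral_features(numeric(3000), 100)), rep(0, 4))
  x <- with_seed_test(5, rnorm(3000))
  f1 <- emg_spectral_features(x, 100)
  f2 <- emg_spectral_features(2 * x, 100)
  expect_equal(unname(f2), unname(4 * f1), tolerance = 1e-9)
  expect_gte(f1[["psd_max"]], f1[["psd_mean"]])
})

test_that("the 49-vector is complete, ordered, and stateless", {
  rec <- simulate_psg_cohort(cohort_config(n_subjects = 1,
    stage_counts = rbind(c(4, 2, 3, 2, 2)), seed = 13))
  model <- fit_wake_ar_model(rec$eeg[rec$stage == "W"], cfg, seed = 1)
  v <- extract_epoch_features(rec$eeg[[1]], rec$eog[[1]], rec$emg[[1]],
                              100, model, emg_prev = 1, emg_next = 1,
                              cfg = cfg)
  expect_length(v, 49)
  expect_named(v, paste0("F", 1:49))
  expect_true(all(is.finite(v)))
  v2 <- extract_epoch_features(rec$eeg[[1]], rec$eog[[1]], rec$emg[[1]],
                               100, model, emg_prev = 1, emg_next = 1,
                               cfg = cfg)
  expect_identical(v, v2)
  expect_error(extract_epoch_features(NULL, rec$eog[[1]], rec$emg[[1]],
                                      100, model), "eeg")
  expect_error(extract_epoch_features(rec$eeg[[1]], rec$eog[[1]], NULL,
                                      100, model), "emg")
})

test_that("extracted tables are complete and wake/SWS separate on EMG power and delta", {
  rec <- simulate_psg_cohort(cohort_config(n_subjects = 1,
    stage_counts = rbind(c(12, 4, 6, 12, 4)), seed = 17))
  ft <- extract_features(rec, cfg, seed = 2)
  expect_equal(nrow(ft), nrow(rec))
  expect_false(anyNA(ft))
  # F43 (EMG total power) larger in wake than SWS; F14 (delta energy)
  # larger in SWS than wake, on average
  expect_gt(mean(ft$F43[ft$stage == "W"]), mean(ft$F43[ft$stage == "SWS"]))
  expect_gt(mean(ft$F14[ft$stage == "SWS"] / ft$F19[ft$stage == "SWS"]),
            mean(ft$F14[ft$stage == "W"] / ft$F19[ft$stage == "W"]))
})

test_that("standardization: hand case, idempotence, constant columns", {
  df <- tibble::tibble(stage = c("W", "S1", "S2"), F1 = c(1, 2, 3),
                       F2 = c(5, 5, 5))
  s <- standardize_features(df)
  expect_equal(s$F1, c(-1, 0, 1) / sqrt(2 / 3))  # population-SD convention
  expect_equal(s$F1, oracle_standardize(c(1, 2, 3)))
  expect_equal(s$F2, c(0, 0, 0))
  s2 <- standardize_features(s)
  expect_equal(s2$F1, s$F1, tolerance = 1e-10)
  expect_lt(abs(mean(s$F1)), 1e-10)
  expect_equal(sqrt(mean((s$F1 - mean(s$F1))^2)), 1, tolerance = 1e-10)
})

test_that("scaling laws: quadratic, linear and scale-invariant features", {
  x <- with_seed_test(3, rnorm(512))
  c0 <- 2.7
  expect_equal(signal_energy(c0 * x), c0^2 * signal_energy(x))
  expect_equal(mean_curve_length(c0 * x), c0 * mean_curve_length(x))
  expect_equal(zero_crossing_rate(c0 * x), zero_crossing_rate(x))
  expect_equal(permutation_entropy(c0 * x, cfg), permutation_entropy(x, cfg))
  expect_equal(petrosian_fd(c0 * x), petrosian_fd(x))
  expect_equal(spectral_entropy(c0 * x, 100, cfg), spectral_entropy(x, 100, cfg),
               tolerance = 1e-9)
})
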