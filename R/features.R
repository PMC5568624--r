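# The 49-feature catalogue: per-epoch time-domain statistics, Hjorth
# parameters, wavelet-packet band energies, spectral/amplitude entropies,
# nonlinear complexity measures and the Itakura spectral distance to a
# subject's wake AR model, for EEG; statistics and energy for EOG; spectral
# features, energy and neighbour energy ratios for EMG.

#' Feature-extraction configuration
#'
#' Collects every tunable parameter of the feature extractor with the
#' defaults used throughout: approximate entropy with pattern length
#' `m = 2` and tolerance `0.2 * SD` (the field-standard choice),
#' collision-order Renyi entropy (`alpha = 2`) on a 16-bin amplitude
#' histogram, permutation entropy with 3-sample ordinal patterns,
#' a depth-7 db20 wavelet-packet tree whose 0.39 Hz leaves are pooled into
#' the clinical rhythm bands, spectral entropy on the 0.3-35 Hz band, and
#' order-8 Yule-Walker AR models for the Itakura distance.
#'
#' @param apen_m Approximate-entropy pattern length (samples).
#' @param apen_r Approximate-entropy tolerance as a multiple of the epoch SD.
#' @param apen_as_printed Use the literal published form of the ApEn
#'   difference (both averages over patterns of length `m`) instead of the
#'   standard `Phi^m - Phi^(m+1)`; default `FALSE`.
#' @param renyi_alpha Renyi entropy order (> 0, != 1).
#' @param n_hist_bins Equal-width amplitude-histogram bins for the Renyi
#'   entropy.
#' @param perm_m Permutation-entropy ordinal pattern length (>= 2).
#' @param wp_level Wavelet-packet tree depth.
#' @param wp_wavelet Daubechies order of the packet tree (and pre-filter).
#' @param band_edges Named list of `c(low, high)` Hz edges for the pooled
#'   bands `delta`, `theta`, `alpha`, `spindle`, `beta1`, `beta2`.
#' @param spectral_entropy_band `c(f1, f2)` Hz band of the spectral entropy.
#' @param ar_order AR model order for the Itakura spectral distance.
#' @param hurst_rs_scales Use the regression-over-scales R/S estimator
#'   instead of the single-window ratio; default `FALSE`.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(apen_m = 2, apen_r = 0.2, apen_as_printed = FALSE,
                           renyi_alpha = 2, n_hist_bins = 16, perm_m = 3,
                           wp_level = 7, wp_wavelet = 20,
                           band_edges = list(
                             delta   = c(0.39, 3.91),
                             theta   = c(3.91, 8.20),
                             alpha   = c(8.20, 12.89),
                             spindle = c(11.72, 14.06),
                             beta1   = c(12.89, 21.88),
                             beta2   = c(21.88, 35.16)),
                           spectral_entropy_band = c(0.3, 35),
                           ar_order = 8, hurst_rs_scales = FALSE) {
  stopifnot(apen_m >= 1, apen_r > 0, renyi_alpha > 0, renyi_alpha != 1,
            perm_m >= 2, n_hist_bins >= 2, ar_order >= 1)
  structure(as.list(environment()), class = "feature_config")
}

#' Descriptive catalogue of the 49 features
#'
#' @return Tibble with `feature` (F1-F49), `signal` (EEG/EOG/EMG) and a
#'   short `description` per feature.
#' @export
feature_catalog <- function() {
  tibble(
    feature = paste0("F", 1:49),
    signal = c(rep("EEG", 36), rep("EOG", 6), rep("EMG", 7)),
    description = c(
      "minimum", "maximum", "mean", "standard deviation", "variance",
      "skewness", "kurtosis", "median", "zero-crossing rate",
      "Hjorth activity", "Hjorth mobility", "Hjorth complexity",
      "WP alpha-band energy", "WP delta-band energy", "WP beta1-band energy",
      "WP beta2-band energy", "WP theta-band energy",
      "WP spindle-band energy", "WP total energy",
      "WP ratio alpha/(delta+theta)", "WP ratio delta/(alpha+theta)",
      "WP ratio theta/(alpha+delta)", "WP ratio delta/theta",
      "WP ratio alpha/theta", "WP in-band coefficient mean",
      "WP in-band coefficient SD", "spectral entropy", "Renyi entropy",
      "approximate entropy", "permutation entropy",
      "Petrosian fractal dimension", "Teager energy", "energy",
      "mean curve length", "Hurst exponent", "Itakura spectral distance",
      "mean", "maximum", "standard deviation", "skewness", "kurtosis",
      "energy", "total spectral power", "spectrum maximum", "spectrum mean",
      "spectrum SD", "energy", "energy ratio vs previous epoch",
      "energy ratio vs next epoch"
    )
  )
}

# ---- elementary per-epoch features ---------------------------------------

#' Statistical features of an epoch
#'
#' Minimum, maximum, mean, standard deviation (sample), variance, skewness,
#' kurtosis and median. Skewness and kurtosis are the bias-uncorrected
#' moment ratios (kurtosis is raw, i.e. 3 for a Gaussian); a zero-variance
#' epoch yields 0 for both.
#'
#' @param x Numeric epoch (non-empty).
#' @return Named numeric vector of length 8.
#' @export
statistical_features <- function(x) {
  if (length(x) == 0) abort("empty epoch")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  skew <- if (m2 > 0) mean((x - m)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - m)^4) / m2^2 else 0
  c(min = min(x), max = max(x), mean = m, sd = sd(x), var = var(x),
    skewness = skew, kurtosis = kurt, median = median(x))
}

#' Zero-crossing rate
#'
#' Number of sign-change points over the epoch (adjacent samples with a
#' strictly negative product).
#' @param x Numeric epoch.
#' @return Integer count in `[0, length(x) - 1]`.
#' @export
zero_crossing_rate <- function(x) {
  if (length(x) == 0) abort("empty epoch")
  sum(x[-length(x)] * x[-1] < 0)
}

#' Hjorth parameters
#'
#' Activity (variance), mobility (`sqrt(var(dx)/var(x))`) and complexity
#' (mobility of the first difference divided by mobility of the signal).
#' A zero-variance epoch maps all three to 0.
#' @param x Numeric epoch of at least 3 samples.
#' @return Named vector `activity`, `mobility`, `complexity`.
#' @export
hjorth <- function(x) {
  if (length(x) < 3) abort("need at least 3 samples")
  pvar <- function(v) mean((v - mean(v))^2)
  s0 <- pvar(x)
  if (s0 == 0) return(c(activity = 0, mobility = 0, complexity = 0))
  d1 <- diff(x); d2 <- diff(d1)
  s1 <- pvar(d1); s2 <- pvar(d2)
  mob <- sqrt(s1 / s0)
  cpx <- if (s1 == 0) 0 else sqrt(s2 / s1) / mob
  c(activity = s0, mobility = mob, complexity = cpx)
}

# one-sided Hann periodogram: tibble(freq, power)
periodogram <- function(x, fs) {
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  X <- fft(x * w)
  half <- floor(n / 2) + 1
  tibble(freq = (seq_len(half) - 1) * fs / n,
         power = Mod(X[seq_len(half)])^2 / n)
}

#' Spectral entropy
#'
#' Shannon entropy of the normalized Hann periodogram restricted to the
#' configured band, divided by `log` of the number of retained bins, so a
#' flat spectrum gives 1 and a single-line spectrum gives 0.
#' @param x Numeric epoch.
#' @param fs Sampling rate (Hz).
#' @param cfg A [feature_config()].
#' @return Value in `[0, 1]` (0 for an all-zero spectrum).
#' @export
spectral_entropy <- function(x, fs, cfg = feature_config()) {
  pg <- periodogram(x, fs)
  band <- cfg$spectral_entropy_band
  p <- pg$power[pg$freq >= band[1] & pg$freq <= band[2]]
  if (length(p) < 2 || sum(p) == 0) return(0)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p)) / log(sum(pg$freq >= band[1] & pg$freq <= band[2]))
}

#' @rdname spectral_entropy
#' @param p Numeric vector of (unnormalized) spectral power values, one per
#'   frequency bin; used directly instead of a periodogram.
#' @export
spectral_entropy_psd <- function(p) {
  if (length(p) < 2 || sum(p) == 0) return(0)
  q <- p / sum(p)
  q <- q[q > 0]
  -sum(q * log(q)) / log(length(p))
}

#' Renyi entropy of the amplitude distribution
#'
#' Order-`alpha` Renyi entropy of the epoch's amplitude histogram
#' (equal-width bins over the epoch range).
#' @inheritParams spectral_entropy
#' @return Non-negative value, at most `log(n_hist_bins)`.
#' @export
renyi_entropy <- function(x, cfg = feature_config()) {
  a <- cfg$renyi_alpha
  if (diff(range(x)) == 0) return(0)
  h <- tabulate(discretize(x, cfg$n_hist_bins) + 1, nbins = cfg$n_hist_bins)
  p <- h / sum(h)
  p <- p[p > 0]
  log(sum(p^a)) / (1 - a)
}

#' Approximate entropy
#'
#' Regularity statistic of the epoch: with tolerance `apen_r * SD(x)`
#' and pattern length `m`, computes `Phi^m(r) - Phi^(m+1)(r)` where
#' `Phi^m` is the average log fraction of length-`m` patterns within
#' Chebyshev distance `r` of each template (self-matches included). With
#' `apen_as_printed = TRUE` both averages use the length-`m` correlation
#' (the literal published difference, which is 0 up to the truncated last
#' template).
#' @inheritParams spectral_entropy
#' @return Non-negative value (up to floating error); 0 for a constant
#'   epoch.
#' @export
approximate_entropy <- function(x, cfg = feature_config()) {
  m <- cfg$apen_m
  n <- length(x)
  if (n <= m + 1) abort("epoch too short for `apen_m`")
  r <- cfg$apen_r * sd(x)
  cnt <- apen_counts(x, m, r)
  lc_m <- log(cnt$cm / (n - m + 1))
  if (cfg$apen_as_printed) {
    return(mean(lc_m) - mean(lc_m[seq_len(n - m)]))
  }
  lc_m1 <- log(cnt$cm1 / (n - m))
  mean(lc_m) - mean(lc_m1)
}

#' Permutation entropy
#'
#' Shannon entropy of the distribution of ordinal patterns of `perm_m`
#' consecutive samples (delay 1); ties are broken by order of appearance.
#' @inheritParams spectral_entropy
#' @return Value in `[0, log(perm_m!)]`.
#' @export
permutation_entropy <- function(x, cfg = feature_config()) {
  m <- cfg$perm_m
  if (length(x) < m) abort("epoch shorter than `perm_m`")
  E <- stats::embed(x, m)[, m:1, drop = FALSE]
  nr <- nrow(E)
  # stable ranks: r_i = 1 + #{j: x_j < x_i} + #{j < i: x_j == x_i}
  rk <- matrix(1L, nr, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    lt <- E[, j] < E[, i]
    if (j < i) lt <- lt | (E[, j] == E[, i])
    rk[, i] <- rk[, i] + lt
  }
  id <- as.vector((rk - 1) %*% m^(seq_len(m) - 1))
  f <- tabulate(id + 1)
  p <- f[f > 0] / nr
  -sum(p * log(p))
}

#' Petrosian fractal dimension
#'
#' `log10(N) / (log10(N) + log10(N / (N + 0.4 * Nd)))` where `Nd` counts
#' sign changes in the first difference of the signal.
#' @param x Numeric epoch of at least 3 samples.
#' @return Value >= 1 (exactly 1 for a strictly monotone signal).
#' @export
petrosian_fd <- function(x) {
  if (length(x) < 3) abort("need at least 3 samples")
  n <- length(x)
  d <- diff(x)
  nd <- sum(d[-length(d)] * d[-1] < 0)
  log10(n) / (log10(n) + log10(n / (n + 0.4 * nd)))
}

#' Mean Teager energy
#'
#' Average of the discrete Teager energy operator
#' `x[n]^2 - x[n-1] * x[n+1]` over the interior samples.
#' @param x Numeric epoch of at least 3 samples.
#' @export
teager_energy <- function(x) {
  if (length(x) < 3) abort("need at least 3 samples")
  n <- length(x)
  mean(x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n])
}

#' Epoch energy and neighbour energy ratio
#'
#' `signal_energy()` is the mean of squared samples; `energy_ratio()` is
#' the current/neighbour energy quotient with the boundary convention that
#' a missing or zero-energy neighbour gives 1.
#' @param x Numeric epoch.
#' @export
signal_energy <- function(x) {
  if (length(x) == 0) abort("empty epoch")
  mean(x^2)
}

#' @rdname signal_energy
#' @param current,neighbour Epoch energies.
#' @export
energy_ratio <- function(current, neighbour) {
  if (is.null(neighbour) || is.na(neighbour) || neighbour == 0) return(1)
  current / neighbour
}

#' Curve length
#'
#' Sum of absolute first differences over the epoch.
#' @param x Numeric epoch of at least 2 samples.
#' @export
mean_curve_length <- function(x) {
  if (length(x) < 2) abort("need at least 2 samples")
  sum(abs(diff(x)))
}

#' Hurst exponent by rescaled range
#'
#' Single-window R/S estimate: `H = log(R/S) / log(N)` with `R` the range
#' of the cumulative sum of the mean-centred epoch and `S` its population
#' SD. With `hurst_rs_scales = TRUE`, `log(R/S)` is instead regressed on
#' `log(window)` over dyadic window sizes.
#' @inheritParams spectral_entropy
#' @return Finite value, typically in (0, 1); 0 for a constant epoch.
#' @export
hurst_exponent <- function(x, cfg = feature_config()) {
  if (length(x) < 20) abort("need at least 20 samples")
  rs <- function(v) {
    s <- sqrt(mean((v - mean(v))^2))
    if (s == 0) return(NA_real_)
    y <- cumsum(v - mean(v))
    (max(y) - min(y)) / s
  }
  if (!cfg$hurst_rs_scales) {
    r <- rs(x)
    if (is.na(r)) return(0)
    return(log(r) / log(length(x)))
  }
  n <- length(x)
  sizes <- unique(floor(n / 2^(0:floor(log2(n / 16)))))
  pts <- purrr::map_dfr(sizes, function(w) {
    k <- floor(n / w)
    vals <- vapply(seq_len(k),
                   function(i) rs(x[((i - 1) * w + 1):(i * w)]), numeric(1))
    tibble(lw = log(w), lrs = log(mean(vals, na.rm = TRUE)))
  })
  pts <- pts[is.finite(pts$lrs), ]
  if (nrow(pts) < 2) return(0)
  unname(stats::coef(stats::lm(lrs ~ lw, data = pts))[2])
}

# ---- wavelet-packet features ---------------------------------------------

# indices (1-based) of the WP leaves pooled into a band
wp_band_leaves <- function(edges, fs, depth) {
  width <- fs / 2 / 2^depth
  lo <- max(0, floor(edges[1] / width + 1e-9))
  hi <- min(2^depth, ceiling(edges[2] / width - 1e-9))
  if (hi <= lo) abort("empty wavelet-packet band")
  (lo + 1):hi
}

#' Wavelet-packet band features (F13-F26)
#'
#' Energies of the alpha, delta, beta1, beta2, theta and spindle bands
#' (pooled depth-7 leaf energies), the total energy over all leaves, the
#' five band-energy ratios alpha/(delta+theta), delta/(alpha+theta),
#' theta/(alpha+delta), delta/theta and alpha/theta (a zero denominator
#' yields 0 with a warning), and the mean and SD of the coefficients pooled
#' over all six bands.
#' @inheritParams spectral_entropy
#' @return Named numeric vector of 14 values.
#' @export
wavelet_packet_features <- function(x, fs, cfg = feature_config()) {
  leaves <- wavelet_packet(x, depth = cfg$wp_level, wavelet = cfg$wp_wavelet)
  energies <- vapply(leaves, function(v) sum(v^2), numeric(1))
  bandE <- vapply(cfg$band_edges, function(e)
    sum(energies[wp_band_leaves(e, fs, cfg$wp_level)]), numeric(1))
  total <- sum(energies)
  ratio <- function(num, den) {
    if (den == 0) {
      if (num > 0) warn("zero-energy denominator band; ratio set to 0")
      return(0)
    }
    num / den
  }
  a <- bandE[["alpha"]]; d <- bandE[["delta"]]; th <- bandE[["theta"]]
  in_band <- unlist(purrr::map(cfg$band_edges, function(e)
    unlist(leaves[wp_band_leaves(e, fs, cfg$wp_level)])), use.names = FALSE)
  c(E_alpha = a, E_delta = d, E_beta1 = bandE[["beta1"]],
    E_beta2 = bandE[["beta2"]], E_theta = th,
    E_spindle = bandE[["spindle"]], E_total = total,
    r_alpha_deltatheta = ratio(a, d + th),
    r_delta_alphatheta = ratio(d, a + th),
    r_theta_alphadelta = ratio(th, a + d),
    r_delta_theta = ratio(d, th),
    r_alpha_theta = ratio(a, th),
    wp_mean = if (length(in_band)) mean(in_band) else 0,
    wp_sd = if (length(in_band) > 1 && sd(in_band) > 0) sd(in_band) else 0)
}

# ---- EMG spectral features ------------------------------------------------

#' EMG spectral features (F43-F46)
#'
#' Total power of the Hann periodogram (integrated over the full one-sided
#' frequency range) and the maximum, mean and SD of the PSD values.
#' @inheritParams spectral_entropy
#' @return Named numeric vector of 4 values.
#' @export
emg_spectral_features <- function(x, fs) {
  pg <- periodogram(x, fs)
  df <- fs / length(x)
  c(total_power = sum(pg$power) * df, psd_max = max(pg$power),
    psd_mean = mean(pg$power), psd_sd = if (sum(pg$power) == 0) 0 else
      sd(pg$power))
}

# ---- wake AR model and Itakura spectral distance --------------------------

#' Fit a subject's representative wake AR model
#'
#' Selects a seeded random 50% subset (`floor(n/2)`) of the subject's wake
#' EEG epochs, fits an AR model of order `ar_order` to each by Yule-Walker,
#' and averages the coefficient vectors elementwise. The selected epoch
#' indices are returned so downstream code can distinguish the model-fitting
#' half from the evaluation half.
#'
#' @param wake_epochs List of numeric EEG epochs scored as wake (>= 2).
#' @param cfg A [feature_config()] (supplies `ar_order`).
#' @param seed Integer seed for the subset selection.
#' @return List of class `wake_ar_model` with `coefficients` (length
#'   `ar_order`, the AR polynomial being `1 - a_1 z^-1 - ...`), `order`,
#'   and `selected` (indices of the epochs used).
#' @export
fit_wake_ar_model <- function(wake_epochs, cfg = feature_config(), seed = 1) {
  n <- length(wake_epochs)
  if (n < 2) abort("need at least 2 wake epochs to fit the wake model")
  sel <- with_seed(seed, sort(sample.int(n, floor(n / 2))))
  coefs <- vapply(wake_epochs[sel], function(ep) {
    fit <- ar(ep, aic = FALSE, order.max = cfg$ar_order,
              method = "yule-walker", demean = TRUE)
    fit$ar
  }, numeric(cfg$ar_order))
  structure(list(coefficients = rowMeans(matrix(coefs, nrow = cfg$ar_order)),
                 order = cfg$ar_order, selected = sel),
            class = "wake_ar_model")
}

#' Itakura spectral distance to a reference AR model
#'
#' Classical (asymmetric) Itakura distance between the reference AR process
#' and the AR model fitted to an epoch:
#' `log((a' R a) / (a_ref' R a_ref))` where `R` is the Toeplitz
#' autocorrelation matrix implied by the reference model and
#' `a = (1, -a_1, ..., -a_p)` are the prediction-error filter taps. The
#' self-distance of an epoch drawn from the reference process tends to 0.
#'
#' @param model A [fit_wake_ar_model()] result.
#' @param x Numeric epoch (long enough for an AR fit of equal order; not
#'   constant).
#' @param cfg A [feature_config()].
#' @return Non-negative value (up to floating error).
#' @export
itakura_spectral_distance <- function(model, x, cfg = feature_config()) {
  if (sd(x) == 0) abort("degenerate (constant) epoch")
  p <- model$order
  acf_ref <- ARMAacf(ar = model$coefficients, lag.max = p)
  R <- toeplitz(acf_ref)
  a_ref <- c(1, -model$coefficients)
  fit <- ar(x, aic = FALSE, order.max = p, method = "yule-walker",
            demean = TRUE)
  a_test <- c(1, -fit$ar)
  log(drop(a_test %*% R %*% a_test) / drop(a_ref %*% R %*% a_ref))
}

# ---- full epoch vector and table extraction -------------------------------

#' Extract the 49-feature vector of one epoch
#'
#' @param eeg,eog,emg Aligned numeric channel epochs.
#' @param fs Sampling rate (Hz).
#' @param wake_model The subject's [fit_wake_ar_model()] result (for F36).
#' @param emg_prev,emg_next Energies of the neighbouring EMG epochs, or
#'   `NA` at recording boundaries (ratio convention: 1).
#' @param cfg A [feature_config()].
#' @return Named numeric vector `F1...F49`.
#' @export
extract_epoch_features <- function(eeg, eog, emg, fs, wake_model,
                                   emg_prev = NA, emg_next = NA,
                                   cfg = feature_config()) {
  for (ch in c("eeg", "eog", "emg")) {
    v <- get(ch)
    if (is.null(v) || length(v) == 0)
      abort(sprintf("channel `%s` is missing", ch))
  }
  emg_en <- signal_energy(emg)
  out <- c(
    statistical_features(eeg),                      # F1-F8
    zcr = zero_crossing_rate(eeg),                  # F9
    hjorth(eeg),                                    # F10-F12
    wavelet_packet_features(eeg, fs, cfg),          # F13-F26
    spen = spectral_entropy(eeg, fs, cfg),          # F27
    renyi = renyi_entropy(eeg, cfg),                # F28
    apen = approximate_entropy(eeg, cfg),           # F29
    pe = permutation_entropy(eeg, cfg),             # F30
    pfd = petrosian_fd(eeg),                        # F31
    teager = teager_energy(eeg),                    # F32
    energy = signal_energy(eeg),                    # F33
    cl = mean_curve_length(eeg),                    # F34
    hurst = hurst_exponent(eeg, cfg),               # F35
    isd = itakura_spectral_distance(wake_model, eeg, cfg),  # F36
    statistical_features(eog)[c("mean", "max", "sd",
                                "skewness", "kurtosis")],   # F37-F41
    eog_energy = signal_energy(eog),                # F42
    emg_spectral_features(emg, fs),                 # F43-F46
    emg_energy = emg_en,                            # F47
    er_prev = energy_ratio(emg_en, emg_prev),       # F48
    er_next = energy_ratio(emg_en, emg_next)        # F49
  )
  stats::setNames(unname(out), paste0("F", 1:49))
}

#' Extract the feature table of a cohort recording
#'
#' Computes the 49-feature vector for every epoch of every subject. The
#' per-subject wake AR model needed by F36 is fitted on a seeded 50% subset
#' of that subject's wake epochs; EMG energy ratios (F48/F49) use the
#' declared previous/next epochs within each subject.
#'
#' @param rec A recording tibble (ideally pre-processed with
#'   [preprocess_recording()]).
#' @param cfg A [feature_config()].
#' @param seed Seed for the wake-epoch subset selection.
#' @return A feature table: tibble with `subject`, `epoch`, `stage` and
#'   numeric columns `F1...F49` (no missing values).
#' @export
extract_features <- function(rec, cfg = feature_config(), seed = 1) {
  rec |>
    dplyr::group_by(.data$subject) |>
    dplyr::group_modify(function(df, key) {
      wake <- df$eeg[df$stage == "W"]
      model <- fit_wake_ar_model(wake, cfg,
                                 seed = mix_seed(seed, match(key$subject[1],
                                   sort(unique(rec$subject)))))
      emg_en <- vapply(df$emg, signal_energy, numeric(1))
      n <- nrow(df)
      rows <- purrr::map(seq_len(n), function(i) {
        extract_epoch_features(
          df$eeg[[i]], df$eog[[i]], df$emg[[i]], df$fs[i], model,
          emg_prev = if (i > 1) emg_en[i - 1] else NA,
          emg_next = if (i < n) emg_en[i + 1] else NA,
          cfg = cfg)
      })
      vals <- as_tibble(do.call(rbind, rows))
      dplyr::bind_cols(df[, c("epoch", "stage")], vals)
    }) |>
    dplyr::ungroup()
}

#' Standardize feature columns to zero mean and unit variance
#'
#' Column-wise z-scoring with the population SD (divide by n); constant
#' columns map to all zeros. Idempotent up to floating error.
#'
#' @param df A feature table (any tibble; every `F`-numbered / numeric
#'   feature column is scaled, label columns are left alone).
#' @return The table with scaled feature columns.
#' @export
standardize_features <- function(df) {
  if (nrow(df) < 2) abort("need at least 2 rows to standardize")
  cols <- feature_cols(df)
  df[cols] <- lapply(df[cols], function(v) {
    m <- mean(v)
    s <- sqrt(mean((v - m)^2))
    if (s == 0) rep(0, length(v)) else (v - m) / s
  })
  df
}
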