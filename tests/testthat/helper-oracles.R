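# Independent brute-force transcriptions of the closed-form features and
# ranking criteria, used as oracles. These deliberately take different code
# paths from the package (naive loops, outer products, direct formula
# evaluation) while sharing the declared conventions.

oracle_stats <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  c(min = sort(x)[1], max = sort(x)[n], mean = mu,
    sd = sqrt(sum((x - mu)^2) / (n - 1)), var = sum((x - mu)^2) / (n - 1),
    skewness = if (m2 > 0) m3 / m2^(3 / 2) else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    median = unname(quantile(x, 0.5, type = 7)))
}

oracle_zcr <- function(x) {
  cnt <- 0
  for (i in seq_len(length(x) - 1)) if (x[i] * x[i + 1] < 0) cnt <- cnt + 1
  cnt
}

# Hjorth from variances of the differenced sequences
oracle_hjorth <- function(x) {
  v <- function(u) mean((u - mean(u))^2)
  s0 <- v(x)
  if (s0 == 0) return(c(activity = 0, mobility = 0, complexity = 0))
  s1 <- v(x[-1] - x[-length(x)])
  d1 <- x[-1] - x[-length(x)]
  s2 <- v(d1[-1] - d1[-length(d1)])
  mob <- sqrt(s1 / s0)
  c(activity = s0, mobility = mob,
    complexity = if (s1 == 0) 0 else sqrt(s2 / s1) / mob)
}

# Hann periodogram written independently of the package helper
oracle_pgram <- function(x, fs) {
  n <- length(x)
  h <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  sp <- abs(fft(x * h))^2 / n
  k <- 0:floor(n / 2)
  list(freq = k * fs / n, power = sp[k + 1])
}

oracle_spen <- function(x, fs, band = c(0.3, 35)) {
  pg <- oracle_pgram(x, fs)
  sel <- pg$freq >= band[1] & pg$freq <= band[2]
  p <- pg$power[sel]
  if (sum(p) == 0) return(0)
  p <- p / sum(p)
  p <- p[p > 0]
  (-sum(p * log(p))) / log(sum(sel))
}

oracle_renyi <- function(x, alpha = 2, bins = 16) {
  if (diff(range(x)) == 0) return(0)
  w <- diff(range(x)) / bins
  idx <- pmin(floor((x - min(x)) / w), bins - 1)
  p <- as.numeric(table(idx)) / length(x)
  log(sum(p^alpha)) / (1 - alpha)
}

# vectorized transcription of the approximate-entropy correlation sums
oracle_apen <- function(x, m = 2, rfrac = 0.2) {
  r <- rfrac * sd(x)
  phi <- function(mm) {
    M <- length(x) - mm + 1
    E <- sapply(seq_len(mm), function(k) x[k:(k + M - 1)])
    D <- matrix(0, M, M)
    for (k in seq_len(mm)) D <- pmax(D, abs(outer(E[, k], E[, k], "-")))
    mean(log(rowSums(D <= r) / M))
  }
  phi(m) - phi(m + 1)
}

oracle_permen <- function(x, m = 3) {
  pats <- character(0)
  for (t in seq_len(length(x) - m + 1)) {
    w <- x[t:(t + m - 1)]
    pats <- c(pats, paste(order(w), collapse = "-"))
  }
  p <- as.numeric(table(pats)) / length(pats)
  -sum(p * log(p))
}

oracle_petrosian <- function(x) {
  n <- length(x)
  d <- x[-1] - x[-n]
  nd <- 0
  for (i in seq_len(length(d) - 1)) if (d[i] * d[i + 1] < 0) nd <- nd + 1
  log10(n) / (log10(n) + log10(n / (n + 0.4 * nd)))
}

oracle_teager <- function(x) {
  n <- length(x)
  v <- numeric(n - 2)
  for (i in 2:(n - 1)) v[i - 1] <- x[i]^2 - x[i - 1] * x[i + 1]
  mean(v)
}

oracle_cl <- function(x) {
  s <- 0
  for (i in 2:length(x)) s <- s + abs(x[i] - x[i - 1])
  s
}

oracle_hurst <- function(x) {
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) return(0)
  y <- cumsum(x - mean(x))
  r <- max(y) - min(y)
  log(r / s) / log(length(x))
}

oracle_standardize <- function(col) {
  mu <- sum(col) / length(col)
  sig <- sqrt(sum((col - mu)^2) / length(col))
  if (sig == 0) rep(0, length(col)) else (col - mu) / sig
}

# fraction of periodogram power below `cut` Hz (spectral oracle)
power_frac_below <- function(x, fs, cut) {
  pg <- stats::spec.pgram(x, plot = FALSE, taper = 0, detrend = FALSE)
  sum(pg$spec[pg$freq * fs < cut]) / sum(pg$spec)
}

# relative power of [f1,f2] among a set of bands (spectral oracle)
band_power <- function(x, fs, f1, f2) {
  pg <- stats::spec.pgram(x, plot = FALSE, taper = 0, detrend = FALSE)
  f <- pg$freq * fs
  sum(pg$spec[f >= f1 & f < f2])
}

oracle_fisher <- function(X, y, eps = 1e-12) {
  sapply(seq_len(ncol(X)), function(j) {
    mu <- mean(X[, j])
    num <- den <- 0
    for (cl in unique(y)) {
      v <- X[y == cl, j]
      num <- num + length(v) * (mean(v) - mu)^2
      den <- den + length(v) * mean((v - mean(v))^2)
    }
    num / (den + eps)
  })
}

oracle_mi <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  s <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    if (tab[i, j] > 0) {
      pij <- tab[i, j] / n
      s <- s + pij * log(pij / (sum(tab[i, ]) / n * sum(tab[, j]) / n))
    }
  }
  s
}

oracle_cmi <- function(a, b, cc) {
  s <- 0
  for (lev in unique(cc)) {
    sel <- cc == lev
    s <- s + mean(sel) * oracle_mi(a[sel], b[sel])
  }
  s
}

# brute-force CMIM ordering on a discretized matrix
oracle_cmim_order <- function(B, y) {
  k <- ncol(B)
  rel <- sapply(seq_len(k), function(j) oracle_mi(B[, j], y))
  sel <- integer(0)
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(k), sel)
    crit <- sapply(cand, function(f) {
      if (length(sel) == 0) rel[f]
      else min(sapply(sel, function(g) oracle_cmi(B[, f], y, B[, g])))
    })
    sel <- c(sel, cand[order(-crit, cand)][1])
  }
  sel
}

# brute-force MRMR ordering on a discretized matrix
oracle_mrmr_order <- function(B, y, variant = "MID", eps = 1e-12) {
  k <- ncol(B)
  rel <- sapply(seq_len(k), function(j) oracle_mi(B[, j], y))
  sel <- integer(0)
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(k), sel)
    crit <- sapply(cand, function(f) {
      if (length(sel) == 0) return(rel[f])
      R <- mean(sapply(sel, function(g) oracle_mi(B[, f], B[, g])))
      if (variant == "MID") rel[f] - R else rel[f] / max(R, eps)
    })
    sel <- c(sel, cand[order(-crit, cand)][1])
  }
  sel
}

# small standardized feature table for ranker tests
make_std_table <- function(n = 200, effect = 2, seed = 1, ...) {
  standardize_features(simulate_feature_table(n = n, effect = effect,
                                              seed = seed, ...))
}

# run expr under a local seed without touching the suite's RNG state
with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
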