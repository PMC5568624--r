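# Daubechies filters and the periodized wavelet machinery used by both the
# band-pass pre-filter and the wavelet-packet features.

.filter_cache <- new.env(parent = emptyenv())

#' Daubechies orthonormal filter pair
#'
#' Generates the length-`2p` Daubechies scaling (low-pass) and wavelet
#' (high-pass) filters by spectral factorization of the maximally-flat
#' half-band polynomial: the binomial polynomial
#' \eqn{P(y) = \sum_k \binom{p-1+k}{k} y^k} is rooted, the minimum-phase
#' spectral factor is kept, and `p` zeros at z = -1 are appended. The result
#' is normalized so the low-pass coefficients sum to \eqn{\sqrt 2}.
#'
#' @param p Number of vanishing moments ("db20" is `p = 20`, 40 taps).
#' @return List with numeric vectors `lo` and `hi` of length `2p`.
#' @examples
#' f <- daubechies_filter(4)
#' sum(f$lo^2) # 1: orthonormal
#' @export
daubechies_filter <- function(p) {
  if (!is.numeric(p) || length(p) != 1 || p < 1 || p != round(p))
    abort("`p` must be a positive integer number of vanishing moments")
  key <- as.character(p)
  if (!is.null(.filter_cache[[key]])) return(.filter_cache[[key]])
  if (p == 1) {
    lo <- c(1, 1) / sqrt(2)
  } else {
    co <- choose(p - 1 + 0:(p - 1), 0:(p - 1))
    ry <- polyroot(co)
    zroots <- vapply(ry, function(y) {
      b <- 2 - 4 * y
      disc <- sqrt(b^2 - 4)
      z1 <- (b + disc) / 2
      z2 <- (b - disc) / 2
      if (Mod(z1) < 1) z1 else z2
    }, complex(1))
    h <- 1
    for (i in seq_len(p)) h <- convolve(h, rev(c(1, 1) / 2), type = "open")
    for (z in zroots) h <- convolve(h, rev(c(1, -z) / (1 - z)), type = "open")
    lo <- Re(h)
    lo <- lo * sqrt(2) / sum(lo)
  }
  hi <- (-1)^(seq_along(lo) - 1) * rev(lo)
  out <- list(lo = lo, hi = hi)
  .filter_cache[[key]] <- out
  out
}

# Reflect-pad x at the tail to the next multiple of 2^depth; returns the
# padded vector plus the original length.
pad_pow2 <- function(x, depth) {
  blk <- 2^depth
  n <- length(x)
  target <- ceiling(n / blk) * blk
  if (target > n) {
    extra <- target - n
    refl <- rev(x)[seq_len(min(extra, n))]
    while (length(refl) < extra) refl <- c(refl, rev(refl))[seq_len(extra)]
    x <- c(x, refl[seq_len(extra)])
  }
  list(x = x, n = n)
}

#' Wavelet multi-level band-pass filter
#'
#' Band-pass filters a signal by multi-level wavelet decomposition and
#' reconstruction: the signal is decomposed with the db`p` filter bank to the
#' depth whose approximation band falls below `low`, the approximation and
#' every detail level whose dyadic band lies outside `[low, high]` are
#' zeroed, and the signal is reconstructed. Dyadic splits cannot place a cut
#' exactly at an arbitrary `high`; by default a detail level is dropped as
#' soon as its band extends above `high` (so a Nyquist tone is fully
#' rejected), while `keep_partial_high = TRUE` retains levels that only
#' partially exceed `high`.
#'
#' @param x Numeric signal (a full-night channel, any length >= 2).
#' @param fs Sampling rate in Hz.
#' @param low,high Pass-band edges in Hz; `0 < low < high < fs/2`.
#' @param wavelet Daubechies order (vanishing moments); default 20 ("db20").
#' @param keep_partial_high Keep detail levels whose band only partially
#'   exceeds `high`? Default `FALSE`.
#' @return Filtered signal, same length as `x`.
#' @examples
#' fs <- 100
#' t <- seq(0, 10, by = 1 / fs)[-1]
#' x <- sin(2 * pi * 10 * t) + sin(2 * pi * 49 * t)
#' y <- wavelet_bandpass(x, fs, 0.3, 35)
#' @export
wavelet_bandpass <- function(x, fs, low = 0.3, high = 35, wavelet = 20,
                             keep_partial_high = FALSE) {
  stopifnot_scalar_pos(fs, "fs")
  if (!is.numeric(low) || !is.numeric(high) || low <= 0 || high <= low ||
      high >= fs / 2)
    abort("need 0 < low < high < fs/2")
  f <- daubechies_filter(wavelet)
  # depth: approximation band [0, fs/2^(depth+1)] must fall below `low`
  depth <- 1
  while (fs / 2^(depth + 1) > low) depth <- depth + 1
  pad <- pad_pow2(x, depth)
  a <- pad$x
  details <- vector("list", depth)
  for (l in seq_len(depth)) {
    details[[l]] <- wt_analysis_step(a, f$hi)
    a <- wt_analysis_step(a, f$lo)
  }
  a <- numeric(length(a))  # approximation: below `low`
  for (l in seq_len(depth)) {
    band <- c(fs / 2^(l + 1), fs / 2^l)
    drop_high <- if (keep_partial_high) band[1] >= high else band[2] > high
    drop_low <- band[2] <= low
    if (drop_high || drop_low) details[[l]] <- numeric(length(details[[l]]))
  }
  for (l in rev(seq_len(depth))) {
    a <- wt_synthesis_step(a, details[[l]], f$lo, f$hi)
  }
  a[seq_len(pad$n)]
}

#' Wavelet-packet leaf coefficients in frequency order
#'
#' Expands an epoch into the full wavelet-packet tree of the given depth and
#' returns the `2^depth` leaf coefficient vectors ordered by increasing
#' frequency (natural filter-path order is permuted by the inverse Gray
#' code, which corrects the spectral inversions introduced by decimated
#' high-pass branches). The epoch is reflect-padded to a multiple of
#' `2^depth`, so leaf `i` covers `[i, i + 1) * fs / 2^(depth+1)` Hz.
#'
#' @param x Numeric epoch.
#' @param depth Tree depth (default 7: 128 leaves of fs/256 Hz each).
#' @param wavelet Daubechies order; default 20.
#' @return List of `2^depth` numeric vectors, lowest band first.
#' @export
wavelet_packet <- function(x, depth = 7, wavelet = 20) {
  f <- daubechies_filter(wavelet)
  pad <- pad_pow2(x, depth)
  if (pad$n < length(pad$x)) {
    # zero-pad instead of reflecting: keeps leaf energies those of the
    # original samples (Parseval on the padded signal)
    pad$x[(pad$n + 1):length(pad$x)] <- 0
  }
  leaves <- wpt_leaves(pad$x, f$lo, f$hi, depth)
  leaves[gray_code(seq_len(2^depth) - 1) + 1]
}

# binary-reflected Gray code; natural index gray_code(i) holds the i-th
# frequency band
gray_code <- function(n) bitwXor(n, bitwShiftR(n, 1))
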