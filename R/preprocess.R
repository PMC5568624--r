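# Pre-processing: zero-energy epoch rejection, wavelet band-pass filtering
# of EEG/EOG, and epoch segmentation.

#' Remove zero-energy epochs from a recording
#'
#' Drops every epoch whose energy (sum of squares) is zero, or below
#' `tol`, in *any* channel — such epochs arise from recording-device
#' dropouts — keeping all channels and the hypnogram aligned. The operation
#' is idempotent and preserves the order of surviving epochs.
#'
#' @param rec A recording tibble (`subject`, `epoch`, `stage`, `fs`, plus
#'   `eeg`/`eog`/`emg` list columns).
#' @param tol Energy threshold; the default 0 means exact equality, a small
#'   positive value accommodates quantized data.
#' @return A list with `recording` (the filtered tibble) and `removed`
#'   (integer row indices of the dropped epochs, possibly empty).
#' @examples
#' cfg <- cohort_config(n_subjects = 1,
#'                      stage_counts = rbind(c(2, 1, 1, 1, 1)), seed = 1)
#' rec <- simulate_psg_cohort(cfg)
#' rec$eeg[[3]] <- rep(0, length(rec$eeg[[3]]))
#' remove_zero_energy_epochs(rec)$removed
#' @export
remove_zero_energy_epochs <- function(rec, tol = 0) {
  chans <- intersect(c("eeg", "eog", "emg"), names(rec))
  if (length(chans) == 0) abort("`rec` has no channel list columns")
  dead <- rep(FALSE, nrow(rec))
  for (ch in chans) {
    en <- vapply(rec[[ch]], function(x) sum(x^2), numeric(1))
    dead <- dead | en <= tol
  }
  removed <- which(dead)
  list(recording = rec[!dead, , drop = FALSE], removed = removed)
}

#' Segment a continuous signal into fixed-length epochs
#'
#' Splits a signal into consecutive non-overlapping windows of
#' `epoch_len` seconds; a trailing partial window is discarded.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param epoch_len Window length in seconds (default 30).
#' @return A list of numeric vectors, each of `fs * epoch_len` samples.
#' @examples
#' length(segment_signal(rnorm(9000), 100)) # 3
#' @export
segment_signal <- function(x, fs, epoch_len = 30) {
  stopifnot_scalar_pos(fs, "fs")
  stopifnot_scalar_pos(epoch_len, "epoch_len")
  n <- round(fs * epoch_len)
  if (length(x) < n) abort("signal shorter than one epoch")
  k <- floor(length(x) / n)
  purrr::map(seq_len(k), function(i) x[((i - 1) * n + 1):(i * n)])
}

#' Pre-process a PSG recording
#'
#' Applies the full pre-processing chain per subject: zero-energy epochs are
#' removed, the EEG and EOG channels are concatenated into full-night
#' signals, band-pass filtered to `[low, high]` Hz by wavelet multi-level
#' decomposition/reconstruction (db20), and re-segmented into epochs. The
#' EMG channel is left unfiltered (the band follows scoring-manual
#' recommendations for EEG/EOG).
#'
#' @param rec A recording tibble.
#' @param low,high Pass band in Hz (defaults 0.3 and 35).
#' @param wavelet Daubechies order for the filter bank (default 20).
#' @param tol Zero-energy tolerance passed to
#'   [remove_zero_energy_epochs()].
#' @return A recording tibble of the surviving, filtered epochs, with the
#'   removed row indices in attribute `"removed"`.
#' @export
preprocess_recording <- function(rec, low = 0.3, high = 35, wavelet = 20,
                                 tol = 0) {
  z <- remove_zero_energy_epochs(rec, tol = tol)
  rec <- z$recording
  out <- rec |>
    dplyr::group_by(.data$subject) |>
    dplyr::group_modify(function(df, key) {
      n_ep <- vapply(df$eeg, length, integer(1))
      fs <- df$fs[1]
      for (ch in c("eeg", "eog")) {
        full <- unlist(df[[ch]], use.names = FALSE)
        filt <- wavelet_bandpass(full, fs, low, high, wavelet)
        idx <- c(0, cumsum(n_ep))
        df[[ch]] <- purrr::map(seq_len(nrow(df)),
                               function(i) filt[(idx[i] + 1):idx[i + 1]])
      }
      df
    }) |>
    dplyr::ungroup()
  attr(out, "removed") <- z$removed
  out
}
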