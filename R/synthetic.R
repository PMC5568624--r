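# Synthetic PSG cohort generator. The signals are controllable stand-ins for
# real polysomnography, not physiological simulations: EEG epochs are sums of
# band-limited Gaussian noise with stage-dependent band weights (plus
# spindle bursts in S2), EOG is low-frequency drift with step-like
# deflections, EMG is white noise scaled by stage-dependent muscle tone.

#' Stage synthesis profiles
#'
#' One row per sleep stage giving the relative EEG rhythm-band powers
#' (delta/theta/alpha/beta, summing to 1), the number of 13 Hz spindle
#' bursts per epoch, the EMG amplitude scale and the EOG activity scale used
#' by the epoch generator. The defaults encode the textbook picture:
#' alpha-rich wake with high muscle tone, delta-dominant slow-wave sleep,
#' spindle-bearing stage 2, and REM that is spectrally close to S1 but
#' atonic with strong eye-movement activity.
#'
#' @return A tibble with columns `stage`, `delta`, `theta`, `alpha`, `beta`,
#'   `spindle_rate`, `emg_tone`, `eog_activity`.
#' @examples
#' stage_specs()
#' @export
stage_specs <- function() {
  tibble(
    stage        = stage_levels(),
    delta        = c(0.20, 0.30, 0.45, 0.75, 0.35),
    theta        = c(0.15, 0.40, 0.30, 0.15, 0.40),
    alpha        = c(0.45, 0.15, 0.10, 0.05, 0.10),
    beta         = c(0.20, 0.15, 0.15, 0.05, 0.15),
    spindle_rate = c(0, 0, 3, 0, 0),
    emg_tone     = c(1.6, 0.7, 0.5, 0.35, 0.15),
    eog_activity = c(1.0, 0.7, 0.15, 0.05, 1.8)
  )
}

#' Per-epoch variability settings for the synthetic generator
#'
#' Lognormal jitter SDs applied independently to every generated epoch:
#' `band` on the rhythm-band weights (renormalized), `scale` on EMG tone
#' and EOG activity, `amp` on the overall EEG amplitude. The defaults
#' (0.4/0.5/0.3) give the stage-conditional feature distributions the
#' overlapping, heavy-tailed spread seen in real PSG, so no single feature
#' separates the stages perfectly.
#'
#' @param band,scale,amp Non-negative SDs on the log scale.
#' @return A list with components `band`, `scale`, `amp`.
#' @export
epoch_jitter <- function(band = 0.4, scale = 0.5, amp = 0.3) {
  if (band < 0 || scale < 0 || amp < 0) abort("jitter SDs must be >= 0")
  list(band = band, scale = scale, amp = amp)
}

check_stage_spec <- function(spec) {
  bp <- c(spec$delta, spec$theta, spec$alpha, spec$beta)
  if (any(bp < 0) || abs(sum(bp) - 1) > 1e-9)
    abort("band powers must be non-negative and sum to 1")
  if (spec$spindle_rate < 0 || spec$emg_tone <= 0 || spec$eog_activity < 0)
    abort("spindle_rate / emg_tone / eog_activity must be non-negative")
  invisible(spec)
}

# unit-variance Gaussian noise restricted to [f1, f2] Hz by FFT masking
band_noise <- function(n, fs, f1, f2) {
  z <- fft(rnorm(n))
  freq <- (seq_len(n) - 1) * fs / n
  freq <- pmin(freq, fs - freq)  # two-sided
  z[freq < f1 | freq > f2] <- 0
  y <- Re(fft(z, inverse = TRUE)) / n
  s <- sd(y)
  if (s == 0) numeric(n) else y / s
}

#' Generate one synthetic PSG epoch
#'
#' Produces aligned EEG, EOG and EMG sample vectors for a single 30-second
#' epoch of the given stage. The EEG is a sum of independent band-limited
#' Gaussian processes, one per rhythm band (delta 0.5-4, theta 4-8, alpha
#' 8-13, beta 13-30 Hz), weighted so the relative band powers match the
#' stage profile, plus broadband noise 20 dB below the signal; S2 epochs add
#' `spindle_rate` Hann-windowed 13 Hz tone bursts of 1 s.
#'
#' @param spec A one-row stage profile as returned by [stage_specs()] (or a
#'   list with the same fields).
#' @param fs Sampling rate in Hz (default 100).
#' @param epoch_len Epoch length in seconds (default 30).
#' @param seed Integer seed; identical seeds give bitwise-identical epochs.
#' @param jitter Per-epoch lognormal variability (SDs on the log scale):
#'   `band` multiplies each rhythm-band weight before renormalization,
#'   `scale` multiplies the EMG tone and EOG activity, `amp` the overall
#'   EEG amplitude. Real epochs of one stage vary substantially, so the
#'   defaults make the stage-conditional feature distributions overlap;
#'   set all three to 0 to recover the nominal profile exactly.
#' @return A list with numeric vectors `eeg`, `eog`, `emg`, each of
#'   `fs * epoch_len` samples.
#' @examples
#' sp <- dplyr::filter(stage_specs(), stage == "SWS")
#' ep <- simulate_stage_epoch(sp, seed = 7)
#' length(ep$eeg)
#' @export
simulate_stage_epoch <- function(spec, fs = 100, epoch_len = 30, seed = 1,
                                 jitter = epoch_jitter()) {
  stopifnot_scalar_pos(fs, "fs")
  stopifnot_scalar_pos(epoch_len, "epoch_len")
  spec <- as.list(spec)
  check_stage_spec(spec)
  n <- round(fs * epoch_len)
  bands <- list(delta = c(0.5, 4), theta = c(4, 8),
                alpha = c(8, 13), beta = c(13, 30))
  with_seed(seed, {
    w <- vapply(names(bands), function(b) spec[[b]], numeric(1))
    w <- w * exp(rnorm(4, 0, jitter$band))
    w <- w / sum(w)
    amp <- exp(rnorm(1, 0, jitter$amp))
    spec$emg_tone <- spec$emg_tone * exp(rnorm(1, 0, jitter$scale))
    spec$eog_activity <- spec$eog_activity * exp(rnorm(1, 0, jitter$scale))
    eeg <- numeric(n)
    for (b in names(bands)) {
      if (w[[b]] > 0) eeg <- eeg + sqrt(w[[b]]) * band_noise(n, fs,
                                         bands[[b]][1], bands[[b]][2])
    }
    eeg <- amp * (eeg + 0.1 * rnorm(n))  # broadband floor at -20 dB
    n_sp <- round(spec$spindle_rate)
    if (n_sp > 0) {
      sp_len <- round(fs)  # 1-s bursts
      win <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = sp_len)))
      for (s in seq_len(n_sp)) {
        at <- sample.int(n - sp_len, 1)
        ph <- runif(1, 0, 2 * pi)
        tone <- sin(2 * pi * 13 * (seq_len(sp_len) - 1) / fs + ph)
        eeg[at:(at + sp_len - 1)] <- eeg[at:(at + sp_len - 1)] +
          1.5 * win * tone
      }
    }
    eog <- spec$eog_activity * band_noise(n, fs, 0.1, 1)
    n_step <- round(2 * spec$eog_activity)
    if (n_step > 0) {
      for (s in seq_len(n_step)) {
        len <- round(runif(1, 0.5, 1.5) * fs)
        at <- sample.int(max(n - len, 1), 1)
        amp <- sample(c(-2, 2), 1) * spec$eog_activity
        edge <- tanh(seq(-3, 3, length.out = len))
        eog[at:(at + len - 1)] <- eog[at:(at + len - 1)] + amp * (edge + 1) / 2
      }
    }
    emg <- spec$emg_tone * rnorm(n)
    list(eeg = eeg, eog = eog, emg = emg)
  })
}

#' Synthetic cohort configuration
#'
#' Assembles the configuration of a synthetic PSG cohort. The default stage
#' counts are those of the six-subject clinical cohort the pipeline is
#' benchmarked against (per-subject wake/REM/S1/S2/SWS epoch counts of
#' magnitude 40-530, roughly 650-1030 epochs per subject).
#'
#' @param n_subjects Number of subjects (default 6).
#' @param stage_counts Integer matrix `n_subjects x 5` with columns
#'   W, S1, S2, SWS, REM; rows are recycled/truncated to `n_subjects`.
#' @param fs Sampling rate (Hz), default 100.
#' @param epoch_len Epoch length (s), default 30.
#' @param specs Stage profile tibble, default [stage_specs()].
#' @param jitter Per-epoch variability, see [epoch_jitter()].
#' @param seed Integer master seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 6, stage_counts = NULL, fs = 100,
                          epoch_len = 30, specs = stage_specs(),
                          jitter = epoch_jitter(), seed = 1) {
  if (is.null(stage_counts)) {
    stage_counts <- cbind(
      W   = c(146, 41, 85, 40, 149, 131),
      S1  = c(101, 71, 120, 47, 102, 135),
      S2  = c(527, 351, 392, 266, 428, 378),
      SWS = c(136, 284, 180, 152, 218, 198),
      REM = c(122, 159, 226, 143, 80, 142)
    )
  }
  stage_counts <- as.matrix(stage_counts)
  if (is.null(colnames(stage_counts))) colnames(stage_counts) <- stage_levels()
  stage_counts <- stage_counts[rep_len(seq_len(nrow(stage_counts)),
                                       n_subjects), , drop = FALSE]
  if (any(stage_counts < 0)) abort("stage counts must be non-negative")
  structure(list(n_subjects = n_subjects, stage_counts = stage_counts,
                 fs = fs, epoch_len = epoch_len, specs = specs,
                 jitter = jitter, seed = seed),
            class = "cohort_config")
}

# Hypnogram with exact per-stage counts whose run structure mimics sleep
# cycles: sampling without replacement from the stage multiset with a
# first-order Markov weighting (self-transition 0.9). Cosmetic, not
# physiological.
simulate_hypnogram <- function(counts, seed, p_self = 0.9) {
  counts <- counts[stage_levels()]
  total <- sum(counts)
  if (total == 0) abort("total epoch count must be positive")
  with_seed(seed, {
    remaining <- counts
    out <- character(total)
    cur <- sample(names(remaining)[remaining > 0], 1,
                  prob = remaining[remaining > 0])
    for (i in seq_len(total)) {
      w <- ifelse(names(remaining) == cur, p_self,
                  (1 - p_self) / (length(remaining) - 1))
      w <- w * (remaining > 0)
      if (sum(w) == 0) w <- as.numeric(remaining > 0)
      cur <- sample(names(remaining), 1, prob = w)
      out[i] <- cur
      remaining[cur] <- remaining[cur] - 1
    }
    out
  })
}

#' Simulate a synthetic PSG cohort
#'
#' Generates one `psg recording` tibble for a whole cohort: each row is one
#' 30-s epoch of one subject, with aligned EEG/EOG/EMG sample vectors as
#' list columns, the stage label, and the sampling rate. Per-subject
#' hypnograms realize the configured stage counts exactly with a
#' sleep-cycle-like run structure. The output is a pure function of the
#' config (including its seed).
#'
#' @param config A [cohort_config()].
#' @return A tibble with columns `subject`, `epoch`, `stage`, `fs`, `eeg`,
#'   `eog`, `emg` (the last three are list columns of numeric vectors).
#' @examples
#' cfg <- cohort_config(n_subjects = 1,
#'                      stage_counts = rbind(c(5, 3, 6, 4, 3)), seed = 2)
#' rec <- simulate_psg_cohort(cfg)
#' nrow(rec)
#' @export
simulate_psg_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  specs <- config$specs
  purrr::map_dfr(seq_len(config$n_subjects), function(s) {
    counts <- config$stage_counts[s, ]
    hyp <- simulate_hypnogram(counts, mix_seed(config$seed, s, 0))
    eps <- purrr::map(seq_along(hyp), function(i) {
      sp <- specs[specs$stage == hyp[i], ]
      simulate_stage_epoch(sp, config$fs, config$epoch_len,
                           seed = mix_seed(config$seed, s, i),
                           jitter = config$jitter)
    })
    tibble(subject = sprintf("S%02d", s), epoch = seq_along(hyp),
           stage = hyp, fs = config$fs,
           eeg = purrr::map(eps, "eeg"),
           eog = purrr::map(eps, "eog"),
           emg = purrr::map(eps, "emg"))
  })
}

#' Simulate a feature table with known ground truth
#'
#' Direct generator of an epochs-by-features table for exercising the
#' rankers: `k_informative` columns carry class-conditional mean shifts of
#' `effect` standard deviations between adjacent classes (each informative
#' column gets its own random assignment of class means), `k_redundant`
#' columns are noisy copies of informative ones (additive Gaussian noise of
#' SD `noise_scale`), and `k_noise` columns are class-independent N(0,1).
#'
#' @param n Number of rows (epochs); must be at least `n_classes`.
#' @param k_informative,k_redundant,k_noise Column counts per role.
#' @param effect Between-adjacent-class mean separation in SD units
#'   (must be >= 0; 0 makes every column class-independent).
#' @param n_classes Number of classes (default 5, labelled with the sleep
#'   stages when `n_classes == 5`).
#' @param noise_scale SD of the noise added to redundant copies.
#' @param seed Integer seed.
#' @return A tibble with columns `stage` (factor) and `X1...Xk`; the
#'   column roles are attached as attribute `"roles"` (a tibble with
#'   `feature`, `role`, `parent`), retrievable with [feature_roles()].
#' @examples
#' tab <- simulate_feature_table(n = 100, effect = 2, seed = 1)
#' feature_roles(tab)
#' @export
simulate_feature_table <- function(n = 500, k_informative = 5,
                                   k_redundant = 5, k_noise = 39,
                                   effect = 1, n_classes = 5,
                                   noise_scale = 0.1, seed = 1) {
  if (effect < 0) abort("`effect` must be non-negative")
  if (n < n_classes) abort("`n` must be at least `n_classes`")
  k <- k_informative + k_redundant + k_noise
  with_seed(seed, {
    cls <- sort(rep_len(seq_len(n_classes), n))
    X <- matrix(rnorm(n * k), n, k)
    mu <- effect * (seq_len(n_classes) - (n_classes + 1) / 2)
    for (j in seq_len(k_informative)) {
      X[, j] <- X[, j] + sample(mu)[cls]
    }
    for (j in seq_len(k_redundant)) {
      parent <- (j - 1) %% max(k_informative, 1) + 1
      X[, k_informative + j] <- X[, parent] + noise_scale * rnorm(n)
    }
    colnames(X) <- paste0("X", seq_len(k))
    labels <- if (n_classes == 5) stage_levels()[cls] else
      paste0("C", cls)
    out <- as_tibble(as.data.frame(X))
    out <- dplyr::bind_cols(tibble(stage = factor(labels,
      levels = unique(labels[order(cls)]))), out)
    roles <- tibble(
      feature = colnames(X),
      role = rep(c("informative", "redundant", "noise"),
                 c(k_informative, k_redundant, k_noise)),
      parent = c(rep(NA_character_, k_informative),
                 if (k_redundant > 0)
                   paste0("X", ((seq_len(k_redundant) - 1) %%
                                  max(k_informative, 1)) + 1)
                 else character(0),
                 rep(NA_character_, k_noise))
    )
    attr(out, "roles") <- roles
    out
  })
}

#' Ground-truth column roles of a simulated feature table
#' @param tab A table from [simulate_feature_table()].
#' @return The roles tibble stored alongside the table.
#' @export
feature_roles <- function(tab) {
  r <- attr(tab, "roles")
  if (is.null(r)) abort("`tab` carries no ground-truth roles")
  r
}
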