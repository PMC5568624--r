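# Orchestration: stage-label utilities, CSV I/O for recordings and feature
# tables, benchmark configuration, the full pipeline, and manifest replay.

#' Map R&K hypnogram labels to AASM stages
#'
#' Stages 3 and 4 merge into slow-wave sleep (SWS); W, S1, S2 and REM are
#' unchanged; movement-time (MT) epochs map to `NA` as an exclusion
#' marker. Unknown labels are an error.
#'
#' @param stage Character vector of R&K labels
#'   (`W, S1, S2, S3, S4, REM, MT`).
#' @return Character vector of AASM labels (`NA` for MT).
#' @examples
#' map_rk_to_aasm(c("S4", "REM", "MT"))
#' @export
map_rk_to_aasm <- function(stage) {
  mapping <- c(W = "W", S1 = "S1", S2 = "S2", S3 = "SWS", S4 = "SWS",
               REM = "REM", MT = NA_character_)
  stage <- as.character(stage)
  bad <- setdiff(unique(stage), names(mapping))
  if (length(bad)) abort(sprintf("unknown R&K label(s): %s",
                                 paste(bad, collapse = ", ")))
  unname(mapping[stage])
}

#' Read a PSG recording from per-channel CSV files
#'
#' Real-data entry point: one single-column CSV of samples per channel
#' (role names matched case-insensitively to EEG/EOG/EMG) plus a hypnogram
#' CSV with columns `epoch_index,stage`. Each channel is segmented into
#' epochs; a hypnogram whose length disagrees with the epoch count is an
#' alignment error.
#'
#' @param channel_files Named character vector of CSV paths; names are the
#'   channel roles.
#' @param hypnogram_file CSV path with columns `epoch_index,stage`.
#' @param subject Subject label.
#' @param fs Sampling rate (Hz), default 100.
#' @param epoch_len Epoch length (s), default 30.
#' @return A recording tibble.
#' @export
read_psg <- function(channel_files, hypnogram_file, subject = "S01",
                     fs = 100, epoch_len = 30) {
  roles <- tolower(names(channel_files))
  if (!setequal(roles, c("eeg", "eog", "emg")))
    abort("`channel_files` must name EEG, EOG and EMG files")
  chans <- lapply(stats::setNames(channel_files, roles), function(p)
    readr::read_csv(p, col_types = "d", progress = FALSE)[[1]])
  segs <- lapply(chans, segment_signal, fs = fs, epoch_len = epoch_len)
  n_ep <- unique(vapply(segs, length, integer(1)))
  if (length(n_ep) != 1) abort("channels disagree on epoch count")
  hyp <- readr::read_csv(hypnogram_file, col_types = "ic", progress = FALSE)
  if (nrow(hyp) != n_ep)
    abort(sprintf("hypnogram has %d epochs but channels have %d",
                  nrow(hyp), n_ep))
  tibble(subject = subject, epoch = seq_len(n_ep),
         stage = as.character(hyp$stage), fs = fs,
         eeg = segs$eeg, eog = segs$eog, emg = segs$emg)
}

#' Write / read a feature table as CSV
#'
#' Round-trips losslessly (doubles are written with full precision).
#' @param df A feature table.
#' @param path CSV path.
#' @export
write_feature_table <- function(df, path) {
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_tibble(df)
}

#' Write a synthetic recording to per-channel CSV files
#'
#' One samples CSV per channel plus `hypnogram.csv`
#' (`epoch_index,stage`) per subject, mirroring the [read_psg()] layout.
#' @param rec A recording tibble (single subject).
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_recording <- function(rec, dir) {
  if (length(unique(rec$subject)) != 1)
    abort("`write_recording()` expects a single subject")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in c("eeg", "eog", "emg")) {
    readr::write_csv(tibble(sample = unlist(rec[[ch]], use.names = FALSE)),
                     file.path(dir, paste0(ch, ".csv")), progress = FALSE)
  }
  readr::write_csv(tibble(epoch_index = rec$epoch,
                          stage = as.character(rec$stage)),
                   file.path(dir, "hypnogram.csv"), progress = FALSE)
  invisible(dir)
}

#' Benchmark configuration
#'
#' Collects every knob of the full comparison pipeline. Defaults follow
#' the study protocol: the six-subject cohort, all seven filter rankers
#' plus Borda and RRA, 50 bootstrap replicates on the odd subset sizes
#' 1-29 for stability, similarity at d = 29, 200 validation runs on the
#' odd sizes 1-15 for the accuracy curves of both classifiers, 70/30
#' stratified splits, and a per-subject quota of 200 epochs.
#'
#' @param cohort A [cohort_config()] for the synthetic data source.
#' @param feature_cfg A [feature_config()].
#' @param methods Ranking methods, see [ranking_methods()].
#' @param quota Balanced epochs per subject.
#' @param n_boot Stability bootstrap replicates.
#' @param stability_d,accuracy_d Subset-size grids.
#' @param similarity_d Subset size for the similarity matrix.
#' @param n_runs Validation runs per accuracy point.
#' @param train_frac Training fraction.
#' @param classifiers Subset of `c("knn", "mlfn")`.
#' @param relieff_k,n_bins Ranker parameters.
#' @param seed Master seed for every stochastic stage.
#' @return A list of class `benchmark_config`.
#' @export
benchmark_config <- function(cohort = cohort_config(),
                             feature_cfg = feature_config(),
                             methods = ranking_methods(aggregates = TRUE),
                             quota = 200, n_boot = 50,
                             stability_d = seq(1, 29, 2),
                             accuracy_d = seq(1, 15, 2),
                             similarity_d = 29, n_runs = 200,
                             train_frac = 0.7,
                             classifiers = c("knn", "mlfn"),
                             relieff_k = 10, n_bins = 10, seed = 1) {
  if (length(methods) == 0) abort("at least one ranking method is required")
  structure(as.list(environment()), class = "benchmark_config")
}

#' Run the full feature-ranking comparison benchmark
#'
#' Executes the whole pipeline on a synthetic cohort: simulation,
#' pre-processing (zero-energy removal, 0.3-35 Hz wavelet band-pass of
#' EEG/EOG), 49-feature extraction, balanced per-subject sampling,
#' standardization, the seven filter rankings plus Borda and RRA
#' aggregation, bootstrap stability profiles, the between-method
#' similarity matrix, repeated random sub-sampling accuracy curves for
#' 1-NN and the MLFN, and Kneedle selection of the optimal feature count.
#' Fully reproducible from the returned manifest.
#'
#' @param config A [benchmark_config()].
#' @param out_dir Optional directory; when given, every result table is
#'   written as CSV together with a JSON run manifest.
#' @param verbose Print stage progress? Default `FALSE`.
#' @return A list of class `sleep_benchmark` with elements `features`
#'   (raw feature table), `analysis` (balanced, standardized table),
#'   `rankings`, `stability`, `similarity`, `accuracy`, `optima`,
#'   `manifest`.
#' @export
run_benchmark <- function(config = benchmark_config(), out_dir = NULL,
                          verbose = FALSE) {
  stopifnot(inherits(config, "benchmark_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  say("simulating %d-subject cohort", config$cohort$n_subjects)
  rec <- simulate_psg_cohort(config$cohort)
  say("pre-processing %d epochs", nrow(rec))
  rec <- preprocess_recording(rec)
  say("extracting features")
  feats <- extract_features(rec, config$feature_cfg,
                            seed = mix_seed(config$seed, 101))
  say("balanced sampling (quota %d) and ranking", config$quota)
  analysis_raw <- sample_balanced(feats, config$quota,
                                  seed = mix_seed(config$seed, 102))
  analysis <- standardize_features(analysis_raw)
  rankings <- rank_features(analysis, methods = config$methods,
                            relieff_k = config$relieff_k,
                            n_bins = config$n_bins)
  say("stability (%d bootstraps)", config$n_boot)
  stability <- stability_profiles(analysis_raw, methods = config$methods,
                                  d_values = config$stability_d,
                                  n_boot = config$n_boot,
                                  seed = mix_seed(config$seed, 103),
                                  relieff_k = config$relieff_k,
                                  n_bins = config$n_bins)
  similarity <- similarity_matrix(rankings, d = config$similarity_d)
  say("accuracy curves")
  acc <- purrr::map_dfr(config$classifiers, function(cl) {
    purrr::map_dfr(config$methods, function(m) {
      rl <- rankings |> dplyr::filter(.data$method == m)
      accuracy_curve(analysis, rl, d_values = config$accuracy_d,
                     classifier = cl, n_runs = config$n_runs,
                     train_frac = config$train_frac,
                     seed = mix_seed(config$seed, 104))
    })
  })
  class(acc) <- c("accuracy_curve", class(acc))
  optima <- acc |>
    dplyr::group_by(.data$method, .data$classifier) |>
    dplyr::summarise(optimum_d = kneedle(.data$d, .data$accuracy),
                     accuracy_at_optimum =
                       .data$accuracy[match(kneedle(.data$d, .data$accuracy),
                                            .data$d)],
                     .groups = "drop")
  manifest <- benchmark_manifest(config)
  out <- structure(list(features = feats, analysis = analysis,
                        rankings = rankings, stability = stability,
                        similarity = similarity, accuracy = acc,
                        optima = optima, manifest = manifest),
                   class = "sleep_benchmark")
  if (!is.null(out_dir)) write_benchmark(out, out_dir)
  out
}

# serializable manifest of a benchmark config
benchmark_manifest <- function(config) {
  list(
    package = "sleeprank",
    cohort = list(n_subjects = config$cohort$n_subjects,
                  stage_counts = unclass(config$cohort$stage_counts),
                  stage_names = colnames(config$cohort$stage_counts),
                  fs = config$cohort$fs,
                  epoch_len = config$cohort$epoch_len,
                  specs = as.data.frame(config$cohort$specs),
                  jitter = config$cohort$jitter,
                  seed = config$cohort$seed),
    feature_cfg = config$feature_cfg[setdiff(names(config$feature_cfg),
                                             "band_edges")],
    band_edges = config$feature_cfg$band_edges,
    methods = config$methods, quota = config$quota, n_boot = config$n_boot,
    stability_d = config$stability_d, accuracy_d = config$accuracy_d,
    similarity_d = config$similarity_d, n_runs = config$n_runs,
    train_frac = config$train_frac, classifiers = config$classifiers,
    relieff_k = config$relieff_k, n_bins = config$n_bins,
    seed = config$seed
  )
}

# rebuild a benchmark_config from a parsed manifest
config_from_manifest <- function(m) {
  sc <- matrix(unlist(m$cohort$stage_counts), nrow = m$cohort$n_subjects)
  colnames(sc) <- unlist(m$cohort$stage_names)
  fc <- do.call(feature_config,
                c(m$feature_cfg[setdiff(names(m$feature_cfg), "ar_order")],
                  list(ar_order = m$feature_cfg$ar_order,
                       band_edges = lapply(m$band_edges, unlist))))
  benchmark_config(
    cohort = cohort_config(n_subjects = m$cohort$n_subjects,
                           stage_counts = sc, fs = m$cohort$fs,
                           epoch_len = m$cohort$epoch_len,
                           specs = as_tibble(m$cohort$specs),
                           jitter = do.call(epoch_jitter, m$cohort$jitter),
                           seed = m$cohort$seed),
    feature_cfg = fc, methods = unlist(m$methods), quota = m$quota,
    n_boot = m$n_boot, stability_d = unlist(m$stability_d),
    accuracy_d = unlist(m$accuracy_d), similarity_d = m$similarity_d,
    n_runs = m$n_runs, train_frac = m$train_frac,
    classifiers = unlist(m$classifiers), relieff_k = m$relieff_k,
    n_bins = m$n_bins, seed = m$seed)
}

# write every result table + the manifest
write_benchmark <- function(bench, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) readr::write_csv(df, file.path(out_dir, name),
                                            progress = FALSE)
  wr(bench$rankings, "ranked_lists.csv")
  wr(bench$stability, "stability.csv")
  sim <- as_tibble(as.data.frame(unclass(bench$similarity)),
                   rownames = "method")
  wr(sim, "similarity_matrix.csv")
  wr(bench$accuracy, "accuracy_curves.csv")
  wr(bench$optima, "optima.csv")
  wr(stability_summary(bench$stability), "stability_summary.csv")
  wr(top_features_table(bench$rankings, n = 10), "top_features.csv")
  jsonlite::write_json(bench$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Replay a benchmark run from its manifest
#'
#' Re-executes [run_benchmark()] with exactly the configuration stored in
#' a `manifest.json`; with the same package version the outputs are
#' byte-identical to the original run's.
#'
#' @param manifest_path Path to a `manifest.json`.
#' @param out_dir Optional output directory for the replayed tables.
#' @return The replayed `sleep_benchmark`.
#' @export
replay_manifest <- function(manifest_path, out_dir = NULL) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  run_benchmark(config_from_manifest(m), out_dir = out_dir)
}

#' Mean stability up to selected subset sizes
#'
#' Summarises a stability profile as the mean stability over all grid
#' sizes `d <= 5`, `d <= 13` and `d <= 29` per method.
#'
#' @param stability A `stability_profile` tibble.
#' @return A tibble with one row per method.
#' @export
stability_summary <- function(stability) {
  purrr::map_dfr(c(5, 13, 29), function(dmax) {
    stability |>
      dplyr::filter(.data$d <= dmax) |>
      dplyr::group_by(.data$method) |>
      dplyr::summarise(mean_stability = mean(.data$stability),
                       .groups = "drop") |>
      dplyr::mutate(up_to_d = dmax)
  }) |>
    tidyr::pivot_wider(names_from = "up_to_d", values_from = "mean_stability",
                       names_prefix = "mean_stability_d")
}

#' Top-n features per method
#'
#' @param rankings A bound `ranked_list` tibble.
#' @param n Number of leading features (default 10).
#' @return A wide tibble: one column per method, one row per rank.
#' @export
top_features_table <- function(rankings, n = 10) {
  rankings |>
    dplyr::filter(.data$rank <= n) |>
    dplyr::select("method", "rank", "feature") |>
    tidyr::pivot_wider(names_from = "method", values_from = "feature")
}
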