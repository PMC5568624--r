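# Seed plumbing and small shared helpers.
#
# Every stochastic operation in the package draws from a sub-seed derived
# from one integer master seed, so a whole benchmark is a pure function of
# its config. Sub-seeds are produced by chaining the MINSTD multiplicative
# congruential map, which keeps all arithmetic exactly representable in
# doubles (48271 * 2^31 < 2^53).

MINSTD_M <- 2147483647

#' Derive a child seed from a master seed and a stream index
#'
#' @param seed Integer master seed.
#' @param ... One or more non-negative integer stream indices; different
#'   index tuples give decorrelated child seeds.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @keywords internal
mix_seed <- function(seed, ...) {
  s <- (abs(as.double(seed)) %% MINSTD_M)
  for (i in c(...)) {
    s <- (s * 48271 + as.double(i) + 1) %% MINSTD_M
    s <- (s * 48271 + 11) %% MINSTD_M
  }
  as.integer(if (s == 0) 1 else s)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Names of the per-epoch feature columns of a feature table, in catalogue
# order (F1, F2, ..., not lexicographic).
feature_cols <- function(df) {
  nm <- grep("^F[0-9]+$", names(df), value = TRUE)
  if (length(nm) == 0) {
    nm <- setdiff(names(df)[vapply(df, is.numeric, logical(1))],
                  c("epoch", "fs"))
  }
  nm[order(feature_index(nm))]
}

# Deterministic ordering index for feature labels: numeric suffix where the
# labels look like F7/X12, otherwise position in alphabetical order.
feature_index <- function(features) {
  if (all(grepl("^[A-Za-z]*[0-9]+$", features))) {
    as.numeric(sub("^[A-Za-z]*", "", features))
  } else {
    match(features, sort(unique(features)))
  }
}

stage_levels <- function() c("W", "S1", "S2", "SWS", "REM")

as_stage_factor <- function(x) {
  f <- factor(as.character(x), levels = stage_levels())
  if (anyNA(f)) abort("unknown sleep-stage label in `stage`")
  f
}

stopifnot_scalar_pos <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
    abort(sprintf("`%s` must be a positive number", what))
}
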