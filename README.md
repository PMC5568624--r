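# sleeprank

Feature ranking and rank aggregation for automatic sleep-stage
classification from polysomnography (PSG).

Automatic sleep staging labels every 30-second epoch of an overnight
recording as wake, S1, S2, slow-wave sleep or REM, and its accuracy is
driven almost entirely by the features fed to the classifier. `sleeprank`
is for researchers who need to decide *which* features to keep: it
implements a complete comparative protocol — a 49-feature catalogue per
epoch, seven filter rankers, two rank-aggregation schemes, and a
three-axis evaluation (accuracy, stability, similarity) with knee-point
selection of the optimal feature count. A seeded synthetic PSG generator
makes every stage of the pipeline runnable and testable without clinical
recordings.

## What it computes

**Features (per 30-s epoch, EEG + horizontal EOG + submental EMG at
100 Hz).** Time-domain statistics and Hjorth parameters; depth-7 db20
wavelet-packet band energies and ratios (delta/theta/alpha/spindle/beta);
spectral, Rényi (α = 2), approximate (m = 2, r = 0.2·SD) and permutation
(m = 3) entropies; Petrosian fractal dimension, Teager energy, energy,
curve length, Hurst exponent (single-window R/S); and the Itakura
spectral distance between each epoch's order-8 AR fit and a per-subject
wake AR model,

d(ref, x) = log[(aₓᵀ R_ref aₓ) / (a_refᵀ R_ref a_ref)],

with a = (1, −a₁, …, −a₈) and R_ref the autocorrelation matrix implied by
the wake model. Features are z-scored column-wise (population SD) before
ranking.

**Rankers.** ReliefF (k = 10, all anchors), Fisher score, chi-square,
information gain, CMIM and MRMR-MID/MIQ (plug-in mutual information on 10
equal-width bins), fused by Borda count (points N − rank + 1) and robust
rank aggregation (beta order statistics,
ρ = min_k P(Beta(k, m−k+1) ≤ r₍ₖ₎), Bonferroni-corrected).

**Evaluation.** Selection stability = mean pairwise Tanimoto overlap
|A∩B|/|A∪B| of top-d sets across 50 bootstrap re-rankings, d = 1, 3, …,
29; between-method similarity of top-29 sets; classification accuracy of
1-NN and a 12-hidden-unit feed-forward net under repeated random
sub-sampling validation (stratified 70/30 splits), with the Kneedle
algorithm picking the knee of each accuracy curve.

## A worked example

```r
library(sleeprank)

cfg <- benchmark_config(n_runs = 20, n_boot = 20, seed = 1)
bench <- run_benchmark(cfg, verbose = TRUE)
bench
#> <sleep_benchmark>
#>   5550 epochs, 6 subjects, 9 ranking methods
#>   analysis table: 1200 balanced epochs
#>   optima:
#> # A tibble: 18 x 4
#>    method   classifier optimum_d accuracy_at_optimum
#>    <chr>    <chr>          <dbl>               <dbl>
#>  1 borda    knn                3               0.892
#>  2 borda    mlfn               3               0.899
#>  3 chi2     knn                7               0.886
#>  ...
#> 16 mrmr_miq mlfn               3               0.895
#> 17 relieff  knn                3               0.892
#> 18 rra      mlfn               3               0.907
```

The bundle holds tidy tibbles throughout. For the run above,
`stability_summary(bench$stability)` reports, e.g., mean stability up to
the 5th feature of 0.94 for chi-square and 0.78 for CMIM (the least
stable method), and `bench$similarity` shows the two MRMR variants as the
most similar pair (Tanimoto 0.93 on their top-29 sets). Accuracy climbs
from 0.58–0.70 with one feature to 0.87–0.93 at d = 11 — each
additional feature typically increments accuracy until the curve
plateaus, and Kneedle places every method's optimum at 3–7 features.

Every piece is usable on its own and pipes naturally:

```r
rec   <- simulate_psg_cohort(cohort_config(seed = 1)) |> preprocess_recording()
feats <- extract_features(rec) |> standardize_features()
feats |> rank_features(c("fisher", "mrmr_mid")) |> aggregate_borda()
feats |> stability_profile("fisher", n_boot = 50) |> autoplot()
```

`tidy()`, `glance()` and `autoplot()` methods cover ranked lists,
stability profiles, accuracy curves and similarity matrices. Real
recordings enter through `read_psg()` (per-channel CSV sample files plus
a `epoch_index,stage` hypnogram); R&K-scored hypnograms convert with
`map_rk_to_aasm()`.

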