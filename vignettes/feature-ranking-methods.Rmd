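---
title: "Comparing feature rankers for sleep-stage classification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing feature rankers for sleep-stage classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sleeprank)
```

## The problem

Sleep staging assigns one of five labels — wake (W), light sleep (S1, S2),
slow-wave sleep (SWS) and REM — to every 30-second epoch of an overnight
polysomnography (PSG) recording. Automatic staging pipelines extract a
feature vector per epoch and feed it to a classifier, and their accuracy is
dominated by the quality of that feature vector. `sleeprank` implements a
comparative protocol for deciding *which* features matter: it computes a
49-dimensional catalogue of widely used EEG/EOG/EMG features, ranks them
with seven filter methods, fuses the rankings with two rank-aggregation
schemes, and scores every method on three axes — classification accuracy,
selection *stability* under resampling, and between-method *similarity*.

The package operates on one EEG, one horizontal EOG and one submental EMG
channel, all sampled at 100 Hz and cut into 30-s epochs. Real recordings
enter through per-channel CSV sample files plus a hypnogram
(`read_psg()`); the shipped synthetic cohort generator makes the whole
pipeline runnable and testable without clinical data.

## Pre-processing

Epochs with zero energy in any channel (recorder dropouts) are removed
with the hypnogram kept aligned (`remove_zero_energy_epochs()`; exact
zero by default, a tolerance is available for quantized data). EEG and EOG
are band-pass filtered to 0.3–35 Hz by wavelet multi-level
decomposition/reconstruction with the Daubechies db20 wavelet; EMG is left
unfiltered, since the band follows scoring-manual recommendations for
EEG/EOG.

Because no wavelet package is available on this stack, the package builds
its own filters: db20 coefficients are generated by spectral factorization
of the maximally-flat half-band polynomial and the transform is a
periodized orthogonal filter bank whose synthesis operator is exactly the
transpose of analysis, so perfect reconstruction and Parseval hold to
machine precision (both are property-tested). At 100 Hz the decomposition
depth is 8, making the discarded approximation band 0–0.195 Hz. Dyadic
splits cannot cut exactly at 35 Hz: the first detail level spans 25–50 Hz.
We zero it — so a Nyquist-rate artifact tone is attenuated by more than
20 dB, at the cost of also removing 25–35 Hz content — because the filter's
contract (suppress out-of-band power) outweighs fidelity in a band that
carries little sleep-relevant EEG. `keep_partial_high = TRUE` restores the
fidelity-first alternative.

## The 49 features

Per epoch the extractor computes (`feature_catalog()` lists all):

* **EEG, time domain (F1–F12)**: eight order/moment statistics,
  zero-crossing count, and the Hjorth parameters. Hjorth activity is the
  variance, mobility `sqrt(var(dx)/var(x))`, complexity the mobility of
  the first difference divided by the mobility of the signal. Printed
  versions of the Hjorth table in the applied literature often carry
  typographic slips (activity as a squared variance, mobility as a
  self-quotient); the classical definitions are the ones consistent with
  the parameters' defining properties (a pure sine gives mobility ≈ its
  angular frequency and complexity ≈ 1), so those are implemented.
* **EEG, time–frequency (F13–F26)**: a depth-7 db20 wavelet-packet tree
  (128 leaves of 0.39 Hz at 100 Hz sampling) pooled into delta
  (0.39–3.91), theta (3.91–8.20), alpha (8.20–12.89), spindle
  (11.72–14.06), beta1 (12.89–21.88) and beta2 (21.88–35.16 Hz) bands —
  band energies, total energy, five energy ratios, and the mean/SD of the
  pooled in-band coefficients. Leaves are mapped to frequencies through the
  inverse Gray code (decimated high-pass branches invert the spectrum),
  verified against pure-tone inputs. A zero-energy ratio denominator
  yields 0 with a warning. The leaf-to-band edges are config-exposed
  because half-band trees cannot reproduce the clinical 0/4/8/13 Hz edges
  exactly.
* **EEG, entropies (F27–F30)**: spectral entropy of the Hann periodogram
  on 0.3–35 Hz normalized by `log` of the bin count; Rényi entropy of
  order α = 2 (collision entropy, common in EEG work) on a 16-bin
  equal-width amplitude histogram; approximate entropy with the
  field-standard m = 2, r = 0.2·SD (a commonly reprinted form of the
  defining difference subtracts two averages of the *same* correlation
  sum — a slip for the standard `Φ^m − Φ^{m+1}`, which we implement; the
  literal reprinted form is selectable via `apen_as_printed`); permutation entropy with 3-sample
  ordinal patterns, delay 1, ties by order of appearance.
* **EEG, nonlinear (F31–F36)**: Petrosian fractal dimension, mean Teager
  energy, mean-square energy, curve length, Hurst exponent, and the
  Itakura spectral distance (ISD). The Hurst estimate is the
  single-window rescaled-range ratio `log(R/S)/log(N)` — the direct
  reading of the defining ratio — with a regression-over-scales variant
  behind `hurst_rs_scales`. The ISD compares each epoch's order-8 Yule–Walker AR
  fit against a subject-level *wake model*: AR coefficients averaged over
  a seeded random half of the subject's wake epochs
  (`fit_wake_ar_model()`), with
  `d = log((a' R a)/(a_ref' R a_ref))` and `R` the Toeplitz
  autocorrelation matrix implied by the wake model — the classical
  (asymmetric) Itakura distance from speech processing. The scale of `R`
  cancels in the quotient, so the normalized autocorrelation suffices.
* **EOG (F37–F42)**: mean, maximum, SD, skewness, kurtosis, energy.
* **EMG (F43–F49)**: total periodogram power, spectrum maximum/mean/SD,
  energy, and the energy ratios against the declared previous and next
  epoch (boundary epochs get ratio 1; so does a zero-energy neighbour).

Skewness and kurtosis are bias-uncorrected moment ratios with raw (not
excess) kurtosis; constant epochs map both to 0. Feature standardization
(`standardize_features()`) is column-wise z-scoring with the *population*
SD (no sample-size correction), constant columns mapped to zero; it is
idempotent to 1e-10.

## The seven rankers and two aggregates

All rankers consume the standardized table and emit a full ordering of the
49 features with deterministic index-based tie-breaking:

* **Fisher score** — between-/within-class scatter ratio with an ε = 1e-12
  denominator guard.
* **Chi-square**, **information gain**, **CMIM**, **MRMR** — computed on
  10 equal-width bins of the standardized values (top bin right-closed).
  Equal-width binning was chosen over quantile binning for transparency;
  the count is config-exposed. Mutual information is the plug-in estimate
  in natural log.
* **ReliefF** — every instance is an anchor (no sampling, keeping the
  ranker deterministic), k = 10 nearest hits/misses under Manhattan
  distance, miss contributions weighted by class priors renormalized over
  non-target classes. ReliefF weights are not scale-invariant, which is
  why the pipeline standardizes first.
* **CMIM** — first pick maximizes `I(f;Y)`; every later pick maximizes
  `min over selected g of I(f;Y|g)`. An exact duplicate of a selected
  feature collapses to the bottom of the list — this is the method's
  defining behaviour, and it means CMIM keeps exactly one representative
  of a group of mutually redundant features. Evaluations of CMIM's
  recovery on data with built-in redundant copies must therefore count
  recovered *groups*, not individual columns; the test suite does.
* **MRMR** — greedy maximization of relevance minus (MID) or divided by
  (MIQ) the mean MI with already-selected features, with an ε guard for
  the zero-redundancy quotient.

**Borda** assigns each feature `N − position + 1` points per ranking and
sorts by descending total. Borda is often written as a raw rank-sum while
calling the *highest* Borda value best; the points convention reconciles
the two readings and induces the identical ordering. **RRA** (robust rank
aggregation) compares each feature's vector of normalized positions with
uniform order statistics: `rho = min_k P(Beta(k, m−k+1) ≤ r_(k))`,
Bonferroni-corrected by the number of rankings. Features are ordered by
the raw rho — the correction clamps clearly non-significant features at 1
and would otherwise erase their relative order — while the reported score
is the corrected value.

## Evaluation protocol

* **Stability** (`stability_profile()`): 50 bootstrap replicates of the
  analysis table, re-standardized and re-ranked per replicate (re-standardizing is a
  genuine design choice; we do it because a ranker deployed on a
  resampled cohort would see that cohort's own scaling), and the mean
  pairwise Tanimoto overlap `|A∩B| / |A∪B|` of the top-d sets over all
  1225 pairs, on the odd grid d = 1, 3, …, 29. Two empty sets count as
  identical, one empty as disjoint.
* **Similarity** (`similarity_matrix()`): the same overlap between the
  top-29 sets of different methods on the full table.
* **Accuracy** (`accuracy_curve()`): repeated random sub-sampling
  validation — stratified 70/30 train/test splits (the split fraction is a free
  parameter; 70/30 is the field default), 200 runs by
  default, 1-NN with Euclidean distance and a feed-forward net with 12
  logistic hidden units and softmax outputs. The classical small-MLFN recipe
  is Levenberg–Marquardt training with early stopping; no available
  package trains nets by LM, and a hand-written LM Jacobian would be
  prohibitive inside a 200-run loop, so the net is `nnet`'s BFGS with
  weight decay — the classifier is evaluation scaffolding here, not the
  object of study.
  Splits are shared across the d grid so curves are paired. A test class
  absent from training causes the run to be redrawn (structurally rare:
  stratified splits keep every class with ≥ 2 members in both folds).
* **Optimal feature count** (`kneedle()`): both axes min-max normalized,
  knee = local maximum of the difference curve `y − x` that later falls
  below `max − S·mean(Δx)` (S = 1, no smoothing since curves are already
  run-averaged). With several knees the smallest d wins, favouring compact
  feature sets; with none, the maximum of the difference curve is returned
  with a warning.
* **Balanced sampling** (`sample_balanced()`): the same number of epochs
  per subject (quota 200 by default, chosen so the analysis table keeps
  every stage of every subject represented while the 200-run validation
  stays tractable), per-stage counts
  proportional to the subject's own stage frequencies by largest-remainder
  rounding with first-come tie-breaks.

## The synthetic cohort

The generator (`simulate_psg_cohort()`) emulates the benchmark's study
conditions: six subjects with per-stage epoch counts matching the
magnitudes of the clinical cohort (about 650–1030 epochs each, S2
dominant), 100 Hz, 30-s epochs. Per stage, EEG is a sum of independent
band-limited Gaussian processes (delta 0.5–4, theta 4–8, alpha 8–13, beta
13–30 Hz) weighted by the stage profile of `stage_specs()` — alpha-rich
wake, delta-dominant SWS, spindle-bearing S2 (three 1-s Hann-windowed
13 Hz bursts per epoch), REM spectrally close to S1 — plus broadband noise
20 dB down. EOG is sub-1 Hz drift plus step-like deflections scaled by a
stage-dependent activity level (largest in REM); EMG is white noise scaled
by a stage-dependent tone (largest in wake, near-atonic in REM).

Every epoch additionally draws lognormal variability (`epoch_jitter()`:
SD 0.4 on band weights, 0.5 on EMG/EOG scales, 0.3 on EEG amplitude).
This matters: with fixed per-stage scales a single EMG feature separates
all five stages perfectly, which real PSG never does; the jitter gives the
stage-conditional feature distributions realistic overlap so accuracy
rises gradually with d and knee selection is meaningful. The hypnogram
realizes the configured stage counts exactly, ordered by a first-order
Markov scheme (self-transition 0.9) that mimics sleep-cycle runs — a
cosmetic choice, not a physiological model. All randomness flows from one
integer master seed through a splittable mixing function; no global RNG
state survives a call.

What the generator does **not** emulate: 1/f background spectra, artifacts
other than zero-energy epochs, inter-subject covariance structure, stage
transitions' physiology, or any quantitative property of the clinical
recordings beyond stage counts and sampling rate (none are published).
Passing tests on synthetic data therefore demonstrate correctness and
calibration of the *methods*, not expected field performance on real
recordings: the published benchmark numbers for the clinical cohort are
not reproducible without those recordings, and the package makes no
attempt to imitate them.

`simulate_feature_table()` skips signal synthesis entirely and emits a
table with known ground truth (informative columns with class-conditional
mean shifts, noisy redundant copies, pure noise) for calibrating the
rankers.

## Numerical choices and degenerate inputs

* Constant epochs: statistics/Hjorth/entropies/Hurst all return 0 by the
  documented conventions; ApEn of a constant epoch is 0 by cancellation.
* Zero signals: all 14 wavelet-packet features are 0; spectral entropy 0.
* Seeds: every stochastic stage derives child seeds via a chained MINSTD
  map, keeping all arithmetic exact in doubles and every derived seed
  below 2^31.
* Problem sizes in the shipped tests: the oracle battery uses 50
  3000-sample epochs (the approximate-entropy oracle, which is O(N²) in
  plain R, runs on 10 of them plus 40 shorter epochs); the end-to-end
  benchmark runs the full six-subject cohort with 20 validation runs and
  a reduced stability grid. The acceptance script runs 20 validation runs
  and the full 50-replicate stability protocol.

## Known limitations

* The MLFN optimizer is BFGS with weight decay rather than
  Levenberg–Marquardt with early stopping (see above); accuracies are
  comparable but not numerically identical to an LM-trained net.
* The discretization scheme, MI estimator and ReliefF k all admit
  reasonable alternatives; orderings on real data can differ under other
  choices (all three are config-exposed).
* RRA's exact beta order-statistic bound is computed feature-wise, which
  is fine at N = 49 but quadratic-ish for very large feature sets.
* EDF files are not read directly; recordings enter as per-channel CSV.

## A worked example

```{r example}
library(sleeprank)
cfg <- benchmark_config(n_runs = 20, n_boot = 20, seed = 1)
bench <- run_benchmark(cfg, out_dir = "bench_out", verbose = TRUE)
glance(bench$rankings)      # best feature per method
stability_summary(bench$stability)
bench$optima                # Kneedle-selected d and accuracy per method
autoplot(bench$accuracy)
autoplot(bench$similarity)
```
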