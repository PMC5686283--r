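---
title: "Methods: pH-based FHR classification benchmarking with fhrbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pH-based FHR classification benchmarking with fhrbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhrbench)
```

## The problem

Cardiotocography records the fetal heart rate (FHR, beats per minute)
during labor. Its visual interpretation is notoriously variable between
clinicians, which motivates data-driven classifiers that predict an
objective outcome — the umbilical-artery pH measured after delivery.
`fhrbench` implements a complete benchmark pipeline for that task on
uniformly sampled FHR traces (4 Hz in the open clinical archives):
artifact rejection, a 54-variant multi-domain feature bank, exact-AUC
feature ranking, a cost-weighted least-squares SVM evaluated under a
nested, imbalance-aware cross-validation protocol, and a
PCA + SMOTE + minimum-Mahalanobis-distance comparator. A synthetic FHR
generator makes every stage testable without access to clinical data.

The class boundary is fixed throughout: a record is *abnormal*
(acidotic) iff pH ≤ 7.05, boundary included (`label_from_ph()`). On the
open 552-record intrapartum archive this rule yields a 44 : 508
imbalance, which shapes every design decision downstream.

## Preprocessing

Clinical FHR is contaminated by impulsive spikes (Doppler artifacts) and
zeroed dropout. `preprocess_record()` applies the standard two-step
rejection scheme:

1. **Extreme-value removal** — samples above 200 bpm or below 50 bpm
   (zeros included) are marked missing. The thresholds are strict
   inequalities; 50 and 200 themselves survive.
2. **Gap handling** — missing runs of at most 15 s are filled by
   *monotone* (shape-preserving) piecewise-cubic Hermite interpolation
   through the flanking samples. The monotone variant is chosen over a
   free cubic because it cannot overshoot the anchor values, which
   matters for bounded physiological data; the interpolant is
   `stats::splinefun(method = "monoH.FC")`. Runs longer than 15 s, and
   leading/trailing runs of any length (one-sided extrapolation is never
   attempted), are masked out of all feature extraction.

The *noise fraction* of a record counts extreme-removed and
short-gap-missing samples — the artifacts that were repaired — as a
fraction of the record; masked long-gap samples are tracked separately
(`long_gap_fraction`). A sample inside a long run is counted once, under
the long-gap share, even if its value was also non-physiological.

Gap lengths are measured on the missing run *before* interpolation, in
seconds at the record's sampling rate. Config surface:
`max_gap_s = 15`, `bpm_min = 50`, `bpm_max = 200`, and a 60 s minimum
segment length for extraction.

## The 54-variant feature bank

`feature_registry()` fixes the canonical enumeration — 21 base measures
across four domains, expanded to 54 named variants by internal
parameters. The enumeration itself is a package design choice: the
benchmark literature states the base measures and the entropy parameter
grid but not the complete expansion, so the registry is data-driven
(YAML-serializable, logged with every run) and the canonical set is:

* **FIGO-based (5)** — baseline mean and SD, acceleration and
  deceleration counts, and `delta_total`, the summed per-minute range of
  the detrended signal. The baseline is a slowly varying trend robust to
  accel/decel excursions: a wide rolling-median initialization followed
  by iterated {low-pass at 0.006 Hz → trim samples > 15 bpm from the
  trend → refit} until the trend moves < 0.5 bpm (≤ 10 passes). The
  published baseline algorithms are cited but not restated in the
  benchmark literature, so this is a documented surrogate with the same
  contract (50–200 bpm bounds, robustness to minute-long events).
  Events follow the clinical guideline thresholds: ≥ ±15 bpm sustained
  ≥ 15 s, same-direction excursions separated by < 5 s merged, events
  never bridging masked gaps. Thresholds are configurable.
* **Time domain (10)** — computed on RR intervals in ms
  (`RR = 60000 / bpm`): STV (2.5 s epoch means), Haan-style STV (IQR of
  successive differences), Yeh's differential index, Dawes–Redman style
  Sonicaid STV (3.75 s epochs per minute), SDNN, Δ (mean per-minute
  range), Haan LTI (IQR of successive-pair modulus), RMSSD, MAD and IQR
  of RR.
* **Frequency domain (18)** — Welch PSD on the bpm signal with a
  Gaussian window of 1024 samples (σ_w = 0.4·(N−1)/2) and 80% overlap,
  averaged over every valid segment long enough to hold a window;
  band powers by trapezoid integration under two band conventions:
  `sig` (VLF 0–0.03, LF 0.03–0.15, MF 0.15–0.5, HF 0.5–1 Hz) and `alt`
  (LF 0.03–0.07, MF 0.07–0.13, HF 0.13–1 Hz), with totals, the LF/HF
  and LF/(MF+HF) ratios, and relative powers.
* **Nonlinear (21)** — fractal dimensions (variance-of-increments,
  box-counting, Sevcik, Higuchi at k_max 8 and 16) and DFA (overall,
  short-scale α1 on 4–16-sample boxes, α2 on 16–64) on the bpm signal;
  approximate and sample entropy on RR over the grid
  r ∈ {0.15, 0.2}·SD, m ∈ {2, 3} (Chebyshev distance; ApEn includes
  self-matches, SampEn excludes them); Lempel–Ziv complexity of the
  median-binarized and tertile-ternarized signal, normalized by
  `c(n)·log_a(n)/n`; Poincaré SD1/SD2 and their ratio.

HRV-tradition features (time domain, entropies, Poincaré) run on RR in
ms; FIGO and spectral/fractal features run on bpm — the representation
is recorded per registry entry. Valid segments are concatenated for the
global statistics; spectral windows are always placed within a single
segment, so a masked gap is exactly equivalent to excising the masked
samples.

Numerical conventions worth noting: SD of the series is the sample SD;
SD1 comes from the successive-difference SD and SD2 from the identity
SD2² = 2·SDNN² − SD1² (floored at 0), making the SDNN identity exact by
construction while the direct rotated-coordinate SDs agree to O(1/n);
sample entropy with no template matches is undefined and returns a
flagged `NA` — the record is then excluded from ranking for that feature
rather than imputed; a zero-variance series scores 0 entropy and unit
fractal dimension by convention, flagged.

## Feature ranking

Features are scored by the exact Mann–Whitney AUC from pooled midranks:
`U = R₁ − n₁(n₁+1)/2`, `AUC = U/(n₁n₂)` — the probability that a
positive-class value exceeds a negative-class one, with half credit for
ties, equal to normalized Wilcoxon rank-sum and immune to class
imbalance. Ranking uses the direction-agnostic score
`max(AUC, 1 − AUC)`. Robustness to the small abnormal class is obtained
by leave-out resampling: per repeat, one random abnormal and twelve
random normals are set aside and the AUC computed on the remainder;
the final score is the mean over repeats (default 100). Ties break by
registry order, making the ranking fully reproducible from the seed.

The benchmark's pinned input sets (`paper_subset()`) are the trio
{VLF energy (alt system), LF energy, Poincaré SD2} and the nine-set
adding {ApEn r=0.2 m=2, ApEn r=0.15 m=2, LF/HF, SampEn r=0.2 m=2,
Haan STV, LF energy (alt system)}. Pinning bypasses data-driven ranking
when benchmark parity matters; fully nested per-fold ranking is
available by flag.

## The weighted LS-SVM

The classifier is a least-squares SVM with RBF kernel
`K(x, z) = exp(−‖x−z‖²/σ²)` (note σ², not 2σ², in the denominator —
the convention used in this benchmark's lineage). Training solves the
dual KKT linear system of

  min ½‖w‖² + ½γ Σᵢ vᵢ eᵢ²  s.t.  yᵢ(wᵀφ(xᵢ) + b) = 1 − eᵢ,

namely `[[0, yᵀ], [y, Ω + diag(1/(γv))]] [b; a] = [0; 1]` with
`Ω = yyᵀ ∘ K` — one dense solve; every training point is a support
vector. Class imbalance enters through the error costs
`vᵢ = N/(2N₊)` for abnormals and `N/(2N₋)` for normals (unit costs when
balanced), with the abnormal cost additionally scaled by a tuned
imbalance multiplier. The solver falls back to a least-squares solve
when the system's reciprocal condition number underflows; the estimate
is kept on the model. Decision scores follow
`Σᵢ aᵢyᵢK(xᵢ, x) + b`; an exact zero score maps to the normal class
(conservative toward the majority). Inputs are z-scored with a
transform learned on training data only and stored on the model.

The kernel spread is parameterized relative to the median pairwise
training distance (`sigma_rel`), the usual scale-free heuristic; the
default grid spans `sigma_rel = 2^−3…2^6`, `γ = 2^−6…2^10`, imbalance
multipliers 0.25–4. The benchmark literature does not state its grids,
so numeric parity with any particular tuned model is not claimed.

## Evaluation protocol

Performance estimation uses a nested stratified cross-validation built
around the abnormal class: one outer fold per abnormal record, each
test fold holding that abnormal plus an equal share of normals (12 or
11 with 508 normals over 44 folds). Per fold, the z-score transform,
any feature ranking, and all tuning see only the training rows. Inner
tuning repeats a one-fold-per-abnormal CV (43-fold at benchmark scale)
`n_inner_repeats = 5` times; normals are shuffled once and *rotated* by
the maximal fold share between repeats, which guarantees — by
construction, whenever feasible — that no abnormal case is ever paired
with the same normal companions twice. The tuning criterion (g-mean,
F-measure, MCC, or BER) is computed on the confusion matrix aggregated
over inner folds and averaged over inner repeats; grid ties resolve to
the first row. The outer procedure is repeated (15 times at benchmark
scale) with reshuffled folds; metrics are reported per repetition with
means across repetitions. All seeds derive deterministically from one
master seed.

Metrics are the imbalance-robust suite: sensitivity, specificity,
precision, accuracy, g-mean, F-measure, MCC, and the balanced error
rate. Two BER variants are reported side by side: the conventional
`1 − (sensitivity + specificity)/2` (key `ber`, used for tuning) and a
variant circulating in the benchmark literature that pairs FP with
(FN+TP) and FN with (FP+TN) (key `ber_printed`); the two coincide only
for balanced confusion margins, so both appear in every report. Any
metric with a zero denominator is a flagged `NA`, never silently
dropped. A useful calibration point: the trivial all-negative
classifier on a 44/508 split scores an accuracy of exactly
508/552 ≈ 0.9203 while being clinically useless — the reason accuracy
never drives tuning here.

## The baseline comparator

The reference scheme replaces each stage with its conventional
counterpart: PCA (fit on the normalized training fold) for
dimensionality reduction, SMOTE in PC space for imbalance compensation
(each minority point emits `amount/100` interpolates toward one of its
k = 5 nearest minority neighbors, `u ~ U(0,1)`), and a
minimum-Mahalanobis-distance classifier under a pooled within-class
covariance with ridge `1e-6·trace/dim`. The classifier itself is
parameter-free; the tuned grid is {retained PCs, SMOTE amount}. SMOTE
only ever sees training rows. PCA is fit on the original training data
and SMOTE applied in PC space — the order is not stated in the
benchmark literature; fitting PCA first keeps the projection free of
synthetic points and is the documented choice here.

## The synthetic generator

`generate_record()` builds FHR-like traces as
baseline + broadband variability + narrowband oscillations + events +
artifacts:

* baseline level drawn from 110–160 bpm with a slow (< 0.003 Hz)
  wander, clipped to the band;
* AR(2) broadband variability (poles from `ar = (1.2, −0.45)`), scaled
  to 6 bpm SD in the normal class;
* VLF/LF/MF sinusoids (2, 3, 1.5 bpm; 0.01–0.025, 0.04–0.1,
  0.18–0.3 Hz) with random phase;
* trapezoidal accelerations/decelerations (amplitude 20–30 / 20–35 bpm,
  duration 25–60 s, 5 s ramps, Poisson counts at 0.3 and 0.1 per
  minute, ≥ 10 s separation when it fits);
* spike artifacts (3.6/min, 1–3 samples, values outside the 50–200 bpm
  physiological range so preprocessing provably removes them) and
  zeroed dropout gaps (1.1/min; 90% uniform 2–15 s, 10% uniform
  16–40 s, exercising both the interpolation and the masking paths).

Every rate and amplitude additionally carries a per-record lognormal
multiplier with log-SD 0.3 — the between-subject heterogeneity
(≈ 30% coefficient of variation) without which any deterministic class
ratio would be perfectly separable from a long record. The artifact
rates are calibrated so the measured short-artifact load averages
≈ 14% of a 30-minute record (observed 14.3%, individual records
roughly 8–18%), matching the documented clinical conditions. The
abnormal class multiplies variability by 0.75, LF amplitude by 0.65,
VLF amplitude by 1.5, the acceleration rate by 0.5 and the
deceleration rate by 2.5, each ratio exponentiated by an `effect_size`
knob (0 = identical classes). With the heterogeneity above, these
ratios put the best synthetic features near AUC 0.75–0.9 — the
difficulty regime of the clinical benchmark — and they are frozen at
these values. Attached pH values are drawn from class-consistent
ranges (abnormal 6.85–7.05, normal 7.06–7.35), so the labeling rule
can be exercised end-to-end.

What the generator does *not* emulate: true beat detection (it
synthesizes the 4 Hz resampled trace directly), uterine-contraction
coupling, autocorrelated artifact bursts, and the heavy-tailed
inter-record variability of clinical archives. Passing recovery tests
on synthetic data therefore demonstrates the pipeline's internal
correctness and sensitivity, not clinical performance.

## Problem sizes used by tests and the acceptance script

Unit and property tests run at the smallest sizes that expose each
property (n ≤ 7200 samples; brute-force oracles at n ≤ 1000). The
pipeline-level checks use 768 s records with a lightened gap model
(0.25 gaps/min, 5% long) so every record supports the 1024-sample
spectral window, a 127 : 11 dataset mirroring the benchmark's class
ratio, 5 outer × 3 inner repetitions, and compact tuning grids; these
sizes are the package's desk-scale defaults for synthetic work, and the
30-minute generator defaults remain the reference conditions. One
translation-invariance caveat: bpm-domain features are invariant under
a constant bpm offset, but RR-domain features are not (RR = 60000/bpm
is nonlinear), so the invariance test covers the bpm-domain set.

## Known limitations

* The FIGO baseline is a surrogate with the published contract but not
  the published code; absolute event counts on real data may differ
  from specific clinical implementations, which is why recovery tests
  assert ±1 agreement with generator truth rather than exact counts.
* The exact 54-variant expansion, the ranking repeat count, and the
  tuning grids are package choices where the benchmark literature is
  silent; all are logged and configurable, and none affect the module
  contracts.
* The O(N³) dense LS-SVM solve is accepted at benchmark scale
  (N ≈ 550); no low-rank approximations are provided.
* `ber_printed` is reported for literature comparability but never
  drives tuning.
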