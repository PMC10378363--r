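---
title: "ramancell: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ramancell: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`ramancell` implements a complete chemometric workflow for classifying
single-cell Raman spectra into normal (`NFC`), precancerous (`NIH/3T3`)
and malignant (`MBM-T`) fibroblast categories. This vignette documents
the model, every consequential numerical choice, and what the synthetic
test world does and does not establish.

## 1. Data model

A spectrum is a strictly monotone wavenumber grid (cm⁻¹) with one
intensity per point. Spectra are stored **ascending** internally;
descending instrument exports are reversed on read. Each cell contributes
up to three site spectra (center, cytoplasm, membrane); a manifest groups
them into per-cell records on one common grid (grids differing by less
than a quarter of the median spacing are snapped; larger mismatches are
linearly interpolated and flagged).

Four analysis databases give one characteristic vector per cell:

| database | rule |
|---|---|
| I | pointwise mean of the *available* site spectra (1–3 sites) |
| II / III / IV | the center / cytoplasm / membrane spectrum; cells lacking that site are omitted |

Averaging over available sites (rather than requiring all three) is a
deliberate choice: the emulated design has fewer cytoplasm/membrane than
center measurements, so "always three sites" is impossible. Whether the
original workflow excluded incomplete cells from database I is unknown;
we average and flag.

## 2. Preprocessing

Per spectrum, in order (the order is part of the contract):

1. **Cut** to 600–1800 cm⁻¹ (closed interval).
2. **Savitzky–Golay smoothing**, window 5 points. Only the window length
   is inherited from the source procedure; the polynomial order is not
   stated anywhere, so we fix `sg_polyorder = 2` (the common default,
   which preserves quadratic peak shapes) and expose it in
   `preprocess_config()`. Edges are mirror-padded by `(window−1)/2`
   points so the output keeps the input length.
3. **Iterative anchored-minima baseline correction**
   (`baseline_config()`):
   * the range splits at 1200 cm⁻¹ into an upper sub-region
     (1200, 1800] and a lower sub-region [600, 1200];
   * in the upper sub-region an anchor is the intensity minimum within
     ±10 cm⁻¹ of each fixed wavenumber 1800, 1750, 1720, 1560, 1530,
     1490 cm⁻¹ (a literal single-point reading would not be a
     "minimum"; the window half-width is a documented, configurable
     choice);
   * the lower sub-region is tiled into 50 equal ranges (12 cm⁻¹ wide on
     the default grid, half-open `[a, b)` except the last); the minimum
     of each non-empty range is an anchor (empty ranges on coarse grids
     are skipped);
   * the baseline is the piecewise-linear interpolant through the
     anchors and is subtracted; this is repeated **5 times**, with
     anchors recomputed from the evolving spectrum each pass (whether
     the original recomputed anchors is unstated; recomputation is the
     natural reading of an iterated process). Negative residuals are not
     clipped — they are handled only by the final normalization shift.
   * **Extrapolation beyond the outermost anchors is linear**
     (continuing the adjacent segment), not flat. With flat
     extrapolation an exactly linear spectrum retains an edge bump of
     order (anchor window)/(span) that no number of iterations removes;
     with linear continuation a straight line is removed exactly in one
     pass and the zero spectrum is a fixed point. The extrapolated
     stretch is at most about one anchor window (~10 cm⁻¹), so there is
     no runaway.
4. **Vector normalization**: subtract the mean intensity, divide by the
   Euclidean norm of the mean-subtracted vector (unit norm), then shift
   so the minimum is exactly 0. The pre-shift vector is recoverable from
   the output `y` as `y − mean(y)`, which is how the unit-norm contract
   is tested. A constant spectrum has zero norm and raises a
   degenerate-input error.

The pipeline is deterministic, invariant to positive scaling and to
additive constants of its input, and idempotent in its cut stage.

## 3. Classification

**PCA.** The basis is the eigendecomposition of the sample covariance
(divisor `n − 1`) of mean-centred training spectra, computed by thin SVD.
Component signs are fixed (largest-magnitude element positive) for
reproducibility. PCA is refit **inside every training fold**; test
spectra are only ever projected.

**LDA.** Gaussian classes with a shared covariance: pooled within-class
scatter with divisor `n − 2`, plus a ridge `ε·I` with default
`ε = 1e−8 · trace/dim` (the source procedure states neither divisor nor
regularization; these are standard unbiased choices, and the ridge keeps
10–20-PC fits on ~230-cell training folds well conditioned — passing
`regularization = 0` restores the unregularised estimator and raises a
singularity error when appropriate). With uniform priors the decision is
the minimum of the squared Mahalanobis distance; an exact tie is assigned
to the **negative** class (deterministic and conservative toward
"normal").

**Tasks.** Four binary tasks with fixed positive-class conventions:
abnormal (NIH/3T3 + MBM-T pooled) positive vs NFC; MBM-T positive in both
pure pairings that contain it; NIH/3T3 positive vs NFC.

## 4. Evaluation

**Cross-validation** is stratified 5-fold, grouped by `cell_id`, with a
seeded shuffle; within every class stratum fold sizes differ by at most
one, and the stratum remainders are dealt to the currently smallest folds
so overall fold sizes also stay within one. Confusion counts are
**summed over folds** and the metrics computed once from the summed
counts ("average the folds' performance" is ambiguous; summed counts are
the standard pooling), while `acc_std` is the standard deviation of the
per-fold accuracies, reported for ACC only.

**Metrics** are ACC, SE, SP, PPV, NPV in percent; a zero denominator
yields `NA` rather than an error.

**PC-count selection.** `accuracy_vs_pcs()` sweeps `n_pcs = 1..25` with
*identical folds* across the sweep (per fold the basis is fitted once and
truncated — exactly equivalent to independent runs, which is tested).
`select_n_pcs()` returns the smallest dimension within `tolerance`
(default 0.5 percentage points; the notion of "plateau" is not quantified
anywhere, so the tolerance is configurable) of the curve maximum.

**Sub-range analysis** restricts the *already preprocessed* spectra to
each of the four biomolecular windows — carbohydrates 600–1195,
amide III + lipids 1196–1380, nucleic acids 1381–1520,
amide I + II 1521–1728 cm⁻¹ — then re-sweeps and re-selects the PC count
per (task, range). Preprocessing is not redone per range: re-baselining a
~200 cm⁻¹ window whose anchors lie outside it is ill-defined, and the
full-range degenerate window then reproduces the full-spectrum run
bit-for-bit (tested).

## 5. The synthetic world

The generator states a world once; its defaults are not tuned per test.

* **Grid**: 600–1800 cm⁻¹ at 1.2 cm⁻¹ dispersion (1001 points).
* **Bands**: the 35 catalogued fibroblast bands, Lorentzian with
  FWHM 12 cm⁻¹; strength grades map to amplitudes
  vs 1.0 / s 0.6 / m 0.35 / w 0.18 / vw 0.08 (the grades are
  qualitative; any numeric mapping is a simulation choice and is
  config-exposed, chosen to resemble the relative peak pattern of a
  fibroblast spectrum).
* **Design**: 169/136/152 cells with per-site counts 444/274/279
  (997 site spectra), reproduced exactly by deterministic presence
  masks.
* **Class effects** are multiplicative on band amplitudes (the
  between-class differences in the emulated study are intensity changes
  at fixed wavenumbers, not shifts). Both abnormal classes scale a
  shared difference pattern on the difference bands (the 700–800 cm⁻¹
  triplet, 1064, 1088/1096, 1128, 1250, 1311, 1337, 1443, 1578,
  1602/1618; the 1700 cm⁻¹ difference position has no catalogued band
  and is dropped), with NIH/3T3 at 0.45 and MBM-T at 0.60 of the
  pattern; MBM-T additionally carries a small secondary pattern
  (scale 0.30) on bands outside the difference set.
* **Within-class variability**: a per-cell global amplitude factor
  (log-sd 0.10; removed by normalization, present for realism), per-cell
  per-band jitter (log-sd 0.06), and — importantly — a per-cell scalar
  (sd 0.15) that scales the shared difference pattern itself. This
  correlated mode emulates the fact that real biological variability is
  structured along the same biochemical axes that separate the classes;
  it is what puts the easy pairs' discriminative direction among the top
  PCA modes (plateau at 1–2 PCs) while the malignant-specific secondary
  pattern, which has no correlated variability, stays in late PCs (the
  hard pair needs many more). The separations were calibrated once,
  before the acceptance thresholds were evaluated, to order as
  NFC↔MBM-T > NFC↔NIH/3T3 > NIH/3T3↔MBM-T.
* **Degradation**: a positive random polynomial background (degree 3,
  amplitude 2 — i.e. fluorescence of the order of twice the strongest
  Raman band, dominating the raw signal) and additive Gaussian noise
  (sd 0.01). The true background is stored per spectrum so
  baseline-recovery tests have a construction oracle.
* **Sites** differ by global intensity factors (1 / 0.92 / 0.85); since
  vector normalization is scale-invariant, site has essentially no
  effect on classification — mirroring the emulated study's finding.

What a green test therefore establishes: the *pipeline* (preprocessing
contracts, leakage-free per-fold PCA, the Mahalanobis rule, CV
bookkeeping, plateau selection, sub-range localisation) behaves correctly
on data with the right structure. What it does not establish: that the
generator reproduces real instrument data — there are no cosmic spikes,
no detector response, no wavenumber miscalibration, no cell-cycle or
culture-batch structure — so synthetic accuracies are properties of the
stated world, not reproductions of any measured percentage.

## 6. Numerical notes and degenerate inputs

* Plateau selection on a single 457-cell replicate is quantised at ~0.22
  points per cell and the curve wiggles by about ±0.6 points — larger
  than the 0.5-point tolerance — so the acceptance test measures
  selection on the curve averaged over its 20 replicates.
* The permutation-null check runs on the near-balanced
  NIH/3T3-vs-MBM-T task: a uniform-prior Mahalanobis rule on permuted
  labels predicts each class about half the time, so its null accuracy
  is ~50%, which only coincides with "within 5 points of the
  majority-class rate" when the majority rate is near 50% (152/288 ≈
  52.8% here). On the 63%-majority pooled task that check would fail for
  any uniform-prior classifier.
* Savitzky–Golay agreement with the sliding least-squares oracle is
  asserted at 1e−10, PCA against the dense eigensolver at 1e−8 (up to
  sign), LDA against explicit quadratic forms exactly (label identity).
* Degenerate inputs raise errors early: spectra shorter than 2 points or
  with non-monotone grids, constant spectra at normalization, fewer than
  2 resolvable baseline anchors, single-class LDA input, classes smaller
  than the fold count under stratification, empty databases (a site no
  cell has), and `n_pcs` beyond the available components.

## 7. Known limitations

* Binary tasks only (the workflow under study is strictly pairwise); no
  ROC/AUC, no nested CV, no probability calibration.
* The baseline corrector assumes the fixed-anchor wavenumbers are
  peak-free; spectra with genuine bands at those positions would have
  them attenuated.
* Sub-range analysis inherits whatever the full-range baseline did
  inside the window; windows narrower than the anchor spacing are not
  re-anchored.
* The manifest format is deliberately plain (CSV + two-column text);
  vendor binary formats and hyperspectral maps are out of scope.
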