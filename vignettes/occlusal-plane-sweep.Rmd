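---
title: "Quantifying the sensitivity of facial aesthetics to occlusal-plane rotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the sensitivity of facial aesthetics to occlusal-plane rotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cephsweep)
```

## The question

Orthodontic treatment can rotate the occlusal plane — measured as the
SN-OP angle between the sella–nasion line and the plane through the biting
surfaces — without surgery. Clinicians want to know how much facial
aesthetics respond per degree of that rotation, and whether the response
differs across skeletal types. Two cephalometric indices summarize the
aesthetics: the posterior–anterior face height ratio
(FHR = S-Go/N-Me, in percent; higher means a shorter, more hypodivergent
face) and the facial angle (FA = NPo-FH, in degrees; higher means a more
prognathic, concave profile).

Because SN-OP cannot be varied experimentally in a patient, the analysis
is a *model-based sensitivity study*: a regression surrogate is trained to
predict FHR (or FA) from ten skeletal measurements, and each patient's
SN-OP is then swept counterfactually over 9–25° with the other nine
measurements frozen. The per-patient prediction curve is summarized by an
ordinary-least-squares slope `k` (index units per degree) and intercept
`b`. Group statistics of `k` and `b` over a 3 × 3 grid of skeletal types
(sagittal Class I/II/III × vertical hypo/normo/hyperdivergent) are the end
product.

`cephsweep` implements this pipeline end to end, together with a
calibrated synthetic-cohort generator, because the underlying patient
measurements are not publicly available. Every stage is exercised by the
generator, so the whole analysis is reproducible from a seed.

## Pipeline stages

1. **Cohort** (`generate_cohort()`, or `read_cohort()` for real CSV data):
   one row per patient with sixteen indicators (units: mm, degrees,
   percent).
2. **Classification** (`classify_cohort()`): sagittal class from ANB
   (Class I for 1–5°, II above, III below) and vertical type by a 2-of-3
   quorum over SN-MP, FH-MP and FHR (hypodivergent: SN-MP < 24°,
   FH-MP < 22°, FHR > 65%; normodivergent: 24–36°, 22–30°, 62–65%;
   hyperdivergent: the complements). Hypodivergent (short-face) patients
   have the *higher* FHR, so the FHR bands run opposite to the two
   mandibular-plane angles.
3. **Surrogate** (`train_surrogate()`): a three-layer feedforward network —
   10 inputs, one hidden layer of 10 tanh units, linear output — fitted by
   full-batch BFGS on the mean squared error after min–max normalization
   of all variables to [-1, 1] (bounds from the training split only).
   Rows are split 70:15:15 into train/validation/test; training stops
   after 6 epochs (of 25 optimizer iterations each) without
   validation-MSE improvement and returns the best-validation weights.
4. **Sweep** (`run_sweep()`): per patient, predict the outcome on the
   absolute grid 9, 10, …, 25° of SN-OP with the other nine inputs frozen,
   then fit the OLS line; report `k`, `b` and the fit R².
5. **Statistics** (`compare_groups()`, `build_slope_table()`, `icc()`):
   Lilliefors-corrected Kolmogorov–Smirnov normality screening and
   median-centered Levene homogeneity select either one-way ANOVA with
   pooled-variance pairwise t tests or Kruskal–Wallis with Dunn's
   rank-based z tests; each triple of pairwise comparisons (across
   vertical types within a sagittal class, or across sagittal classes
   within a vertical type) is one Bonferroni family of size 3, at
   alpha = 0.05. Reliability of repeated measurements is summarized by
   single-rater intraclass correlations: two-way random effects with
   absolute agreement, ICC(2,1), between raters, and two-way mixed
   effects with consistency, ICC(3,1), between sessions.

`cmd_run_all()` chains the stages under one seed that expands
deterministically into per-stage seeds, and writes flat CSV/JSON artifacts
plus a manifest.

## What the generator emulates

The generator reproduces the published summary structure of a 903-patient
orthodontic cohort:

* the exact 9-cell × sex allocation (`allocate_cells(903, "published_exact")`;
  550 female, 353 male), with proportional and uniform modes for other
  sizes;
* per-cell truncated-normal feature distributions with the published
  means and SDs for all ten surrogate inputs plus SN-MP, FH-MP and ANB;
* outcomes that are linear in SN-OP within each cell,
  `FHR = b(cell) + k(cell)·SN-OP + 0.10(S-Go − mean) − 0.10(N-ANS − mean) + ε`,
  `FA = b(cell) + k(cell)·SN-OP + 0.05(Go-Po − mean) + ε′`, with the
  published per-cell `k` and `b` as generating truth and noise SDs
  σ(FHR) = 0.5 percent, σ(FA) = 0.8°. The small cross-feature couplings
  make the learning problem genuinely multivariate while leaving
  ∂outcome/∂SN-OP equal to `k(cell)` exactly, so the generating slope is a
  well-defined recovery target.

Truncation choices: ANB is truncated into its sagittal band, and SN-MP
and FH-MP into their vertical bands, which guarantees that the classifier
reproduces the intended cell for every generated record (the intended
vertical category meets its quorum through those two indicators alone).
All other features are truncated at mean ± 4 SD, which leaves their
moments essentially untouched. The band truncation *does* shift the
moments of the three classification indicators (e.g. the Class I
hypodivergent SN-MP mean sits above the printed 24° boundary), a
deliberate trade: label fidelity is load-bearing for every downstream
group statistic, while those three indicators feed nothing but the
classifier. The distribution-calibration tests therefore check the ten
surrogate inputs, not the band-truncated indicators.

Features are sampled independently within a cell apart from the enforced
identity SNB = SNA − ANB and the explicit outcome couplings; the
published tables report no covariances, so none are invented (a
correlation matrix can be supplied through `generator_config()` for
sensitivity studies). Sex affects allocation bookkeeping only.

For the simulated reliability study (`repeated_measures()`), the
measurement-error defaults are scaled to each field's dispersion in the
cohort being measured — noise SD 0.2×, per-rater bias SD 0.1× — sizes
chosen so that single-rater ICCs land in the low-to-mid 0.9s, the regime
reported for trained cephalometric raters. These magnitudes are artifact
choices: the source analysis reports ICC ranges, not error SDs.

## Numerical choices

* The published split ratio "75:15:15" sums to 105%; the conventional
  70:15:15 is used and is configurable. Largest-remainder rounding with
  earlier-category tie-break gives 632/136/135 at n = 903.
* Optimizer: full-batch BFGS (quasi-Newton) on a 121-parameter network.
  An "epoch" is 25 BFGS iterations; patience 6; at most 1000 epochs; one
  random initialization (uniform on [-0.5, 0.5]), seed-controlled, with
  optional restarts keeping the best validation MSE. Recovery results are
  insensitive to this schedule.
* Slope fitting is the exact closed form; a constant response gets
  `k = 0`, `r2 = 0` and a degenerate flag. Per-patient R² is reported and
  values below 0.95 are flagged in the run report, since the linearity of
  the prediction curve is an assumption, not a law.
* Boundary values in classification belong to the band whose printed
  inequality is inclusive; quorum ties (possible only on band boundaries)
  prefer the normodivergent category, then the category containing the
  SN-MP value.
* Normality verdicts use the Lilliefors correction (moments are estimated
  from the sample); the uncorrected KS p-value is reported alongside.
  Both raw and Bonferroni-adjusted pairwise p-values are retained in every
  report.

## Problem sizes

The shipped tests run the full pipeline at the published size (n = 903,
two surrogates) plus smaller structural checks (n = 45–300); the whole
suite takes well under a minute on one core. Statistical oracles use
1000 null simulations (family-wise error), 3000–4000 subjects
(ICC convergence) and 4000 pairs (Bland–Altman coverage).

## Known limitations

* **Slope-recovery ceiling.** The generator is a 9-cell mixture, and the
  surrogate sees only the ten inputs, in which the cells overlap — and
  SN-OP itself carries information about the cell (cell SN-OP means range
  from 11.2° to 21.9°). The best possible predictor of the outcome given
  the ten inputs is a posterior-weighted mixture over cells, so sweeping
  SN-OP also sweeps the implied cell membership: intercepts fall from the
  hypodivergent to the hyperdivergent cells, which steepens every
  per-patient slope toward a common value near the population gradient
  (about −0.40 for both outcomes, versus generating values of −0.23 to
  −0.47). This is a property of the data-generating design, not of the
  network: a Bayes-optimal predictor built from the exact generating
  densities shows the same compression. Consequently the pipeline
  reproduces the *sign, magnitude scale and linearity* of the published
  slopes but not their between-cell ordering, and per-cell recovery of
  `k` should not be expected to be sharper than roughly ±0.1 under these
  conditions. On real data, where the outcome is a geometric function of
  the measurements rather than a cell mixture, this ceiling does not
  apply — which is precisely what passing tests on synthetic data cannot
  show.
* The sweep is an absolute 9–25° grid, so it extrapolates beyond an
  individual's plausible occlusion by design; reports label the results
  as model-based sensitivity, not treatment effects.
* No landmark coordinates, images, growth or treatment mechanics are
  modelled; NA-FH is treated as an opaque degree-valued feature (its
  printed name and definition disagree in the source material).
* The generator draws features independently within cells; real
  cephalometric indicators are correlated, so surrogate fit statistics on
  synthetic data are not evidence about real-data fit quality.
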