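---
title: "Benchmarking taxonomy identification from single-cell Raman spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking taxonomy identification from single-cell Raman spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-cell Raman spectroscopy (SCRS) records, per cell, a vibrational
spectrum that acts as a phenotypic fingerprint of the cell's biochemical
composition. Because that composition is taxon-specific, a supervised model
trained on a reference library of labelled spectra can identify the taxonomy
of unknown cells — but the fingerprint also shifts with the cell's growth
stage, and environmental cells arrive with unknown stage and extra
fluorescence background. `scrstax` implements the full analysis chain this
problem calls for:

1. **Preprocessing** — background subtraction, smoothing, baseline
   correction, normalization.
2. **A DR × classifier benchmark** — six dimensionality-reduction (DR)
   methods crossed with nine classifiers (plus an optional MLP), evaluated
   by stratified 10-fold cross-validation with nested grid-search tuning.
3. **A two-step ensemble (G-T)** — predict growth stage first, then
   taxonomy with a stage-specific model.
4. **Bayesian accuracy comparison (BEST)** with FDR control over multiple
   model pairs.
5. **A genus-level reference-extension procedure** for classifying
   environmental cells against a pure-culture library.
6. **A synthetic SCRS generator** so that every stage of the pipeline is
   testable end to end without access to a proprietary reference library.

```{r setup}
library(scrstax)
```

## The data container

An `scrs_dataset` holds an intensity matrix (cells × wavenumber channels) on
one shared grid plus a label table (`cell_id`, `strain`, `genus`, `phylum`,
`stage`). Growth stages are `Exp` (exponential) and `S1`/`S2`/`S3`
(beginning, mid-point, end of the stationary phase); cells of unknown stage
(environmental samples) carry the sentinel `"unknown"`, never an empty
string. On disk the matrix is a CSV whose header row is the wavenumber grid
and the labels a TSV — a deliberately plain convention, since vendor formats
vary by instrument.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes, not
Raman physics. Each strain's mean spectrum is a sum of Gaussian bands in
three tiers: a common backbone every cell shares (placed at familiar
positions — 1003, 1095, 1250, 1450, 1660 cm⁻¹), genus-level bands shared by
strains of a genus, and strain-specific bands. Gaussian line shapes are the
simplest standard band approximation; nothing downstream depends on the
shape. Growth stage enters twice: a global multiplicative modulation of the
backbone bands and one stage-marker band each for S1/S2/S3 (the exponential
phase is the unmarked reference state). Each simulated cell is the
stage-modulated band sum times a log-normal amplitude jitter, plus a random
polynomial baseline (order ≤ 3) and i.i.d. Gaussian noise.

Tunable knobs, with defaults chosen once as the study conditions:

* 36 strains in 16 genera and 4 phyla, 120 spectra per strain per stage
  (17,280 cells), a 600–1800 cm⁻¹ grid of 900 channels — the scale of a
  full pure-culture reference library;
* `taxon_separation` and `stage_separation` (both 1) scale the taxon- and
  stage-specific band amplitudes; at 0 the corresponding signal vanishes
  exactly, which the tests use to verify chance-level behaviour;
* `amp_jitter_sd = 0.08` with per-stage multipliers `(Exp 1, S1 0.5, S2 1,
  S3 1.5)` — S1, the beginning of the stationary phase, is generated as the
  most internally consistent stage. This is a default, not a hard-coded
  rule: it gives the synthetic data a stage whose spectra are most
  homogeneous, the regime in which per-stage taxonomy models are expected
  to do best;
* `environmental_mode` adds a broad per-cell Gaussian fluorescence hump and
  extra amplitude jitter, emulating the signal degradation of
  FISH-processed environmental cells; at strength 0 it reproduces the clean
  dataset bit for bit.

No quantitative estimates of real per-stage spectral variability were
available to calibrate these effect sizes; they are free parameters. The
generator also ignores instrument response, cosmic-ray spikes and detector
saturation. Consequently, a pipeline that is accurate on synthetic data is
verified for *correctness of machinery* (no leakage, correct routing,
correct arithmetic), not certified to reach any particular accuracy on real
spectra.

The two strains designated as the "overlapping pair" (first two strains of
the first multi-strain genus) share all genus bands and all strain bands
except one faint discriminating band — a synthetic analogue of two closely
related strains that dominate each other's misclassifications.

Determinism: one master seed; every strain × stage block, every fold
shuffle, every sampler draws from a sub-stream derived deterministically
from it, so identical configurations give bit-identical datasets.

## Preprocessing choices

The conventional protocol is background → smooth → baseline → normalize,
exposed as `preprocess_pipeline()` with every step optional and ordered by
the caller.

* **Smoothing** is Savitzky–Golay (via the `signal` package), default
  window 11 channels, polynomial order 3 — a common spectroscopy default.
* **Baseline correction** is asymmetric least squares: the baseline
  minimizes a second-difference penalty (`lam`, default 1e5) with asymmetric
  weights (`p`, default 0.01) so peaks sit above it. ALS is the standard
  default where no protocol prescribes otherwise; both parameters are
  exposed. It is near-idempotent: correcting an already corrected spectrum
  changes it by less than the peak recovery tolerance.
* **Normalization** offers unit vector norm (default), unit area, and unit
  maximum. All-zero spectra are an error naming the offending cell.
* **Resampling** is linear interpolation and refuses to extrapolate;
  reading per-spectrum two-column files likewise refuses mixed grids rather
  than resampling silently.

Preprocessing is applied once, before cross-validation, as a fixed
label-free protocol; DR and classifier fitting happen strictly inside
training folds.

## Dimensionality reduction

Six methods behind one `fit_dr()` / `transform_dr()` interface: `NONE`
(identity — "no DR" is a first-class grid member so the benchmark treats it
uniformly), `PCA`, `KPCA` (RBF kernel), `LDA`, `SUP_PCA`, `ISM_SDR`.
Default output dimensionality is 35 for taxonomy tasks and 3 for the
4-class growth-stage task — the LDA maximum there is n_classes − 1 = 3, and
the bound is enforced with an informative error.

Design notes on the two less standard methods:

* **SUP_PCA** (supervised PCA) takes the leading eigenvectors of
  X_c′ L_c X_c, where L_c is the centered one-hot label kernel — the
  standard supervised-PCA construction. Its projections are checked in the
  tests against a dense brute-force eigendecomposition.
* **ISM_SDR** is an iterative spectral supervised DR: with Γ the centered
  label kernel and K_Z the RBF kernel of the currently projected data, the
  basis is refreshed as the top eigenvectors of the weighted scatter
  X_c′ (Γ∘K_Z − D) X_c, then the kernel scale is reset to the median
  pairwise projected distance; iteration stops when the projection
  subspace moves less than 1e-6 in Frobenius norm (projector difference) or
  after 100 iterations. Component signs are fixed so the largest-magnitude
  loading is positive. This is this package's documented variant of the
  iterative-spectral family of supervised kernel DR methods; numerical
  equality with other implementations is not claimed.
* **KPCA** scores are rescaled to the PCA convention (unit-norm
  feature-space loadings), so a linear-kernel KPCA reproduces PCA scores
  exactly — a convenient oracle for tests. The RBF scale defaults to the
  median pairwise distance heuristic.

`class_centroid_distance()` quantifies how far a DR places two classes
apart in its own reduced space. Reduced spaces have method-specific units
(LDA distances are in within-class-whitened units, PCA in raw intensity
units), so these distances are a descriptive comparison of
post-DR geometry, as is customary, not a scale-free statistic.

## Classifiers

Ten methods behind `fit_classifier()` / `predict()`: GNB, KNN (K = 10), LDA,
LR, RF (100 trees), SVM_LIN, SVM_LIN_CV, SVM_RBF, SVM_RBF_CV, NN. Defaults
where the method needed a concrete choice:

* **LR** is multinomial logistic regression with an L2 penalty at fixed
  C = 1 (fitted as a penalized multinomial log-linear model).
* **SVMs** use C = 1 untuned; the `*_CV` variants grid-search
  C ∈ {0.01, 0.1, 1, 10, 100} and, for the RBF kernel, a scale of
  {0.01, 0.1, 1, 10} × the median-distance heuristic. Multiclass handling
  follows libsvm's native pairwise (one-vs-one) coupling.
* **NN** is a single-hidden-layer MLP of 128 units trained for a fixed cap
  of 200 iterations (the `nnet` optimizer has no early-stopping path; a
  fixed iteration budget plays the same regularizing role and keeps runs
  deterministic). It is CPU-scale by design.
* **KNN** distance ties are broken under the spec seed, so predictions are
  reproducible.

Every stochastic method consumes a seed carried in its spec; two fits with
the same seed are parameter-identical, which the tests assert via
`fitted_params()` — an environment-free extraction of each model's
decision-defining parameters.

## Cross-validation design

`make_folds()` assigns stratified folds: within each stratum, fold labels
are cyclic after shuffling, so per-fold class counts are within ±1 of
proportional. Stratification fields default to strain for taxonomy tasks
and stage for the growth-stage task — with 36 balanced strains the smallest
class holds under 1% of the data, and stratification protects it from
vanishing out of test folds. Strata smaller than the fold count degrade
gracefully with a warning.

Hyperparameter tuning is a nested (optimization) CV: the nine training
splits of each evaluation fold are pooled and re-split into 3 inner folds
(a pragmatic default — 10 inner folds would multiply SVM fits with little
selection benefit at these sample sizes); candidates are scored by mean
inner accuracy and ties go to the first candidate in declared grid order.
The inner CV operates on the DR-reduced training features of that fold:
the tuned quantities are classifier hyperparameters, and re-fitting the DR
per inner fold would multiply cost without touching the evaluation split,
which is never seen by any fitting step. The evaluation metric is plain
accuracy — appropriate here because the class design is balanced; raw
per-fold predictions are retained in every result so other metrics can be
derived.

The benchmark grid is all six DR methods × the nine non-neural classifiers
= 54 models; the MLP joins only by explicit flag, mirroring its separate
treatment (it is costlier and not expected to outperform at these dataset
sizes). Per-model failures inside `run_grid()` are recorded in the result
table rather than aborting the run. `dim_sweep()` scans output
dimensionalities and selects the best mean accuracy, ties toward the
smaller dimension.

## The two-step G-T ensemble

`train_gt()` fits one growth-stage classifier (G-step; default NONE +
SVM_RBF_CV, the strongest stage classifier in this package's benchmarks)
and four taxonomy models (T-step; default LDA + LR), one per stage.
Prediction routes each cell through the T-step model of its *predicted*
stage; misrouted cells are classified by the wrong stage's model rather
than erroring, because that is exactly the failure mode worth measuring.

Whether T-step models should be trained on ground-truth stage partitions or
on the G-step's own predicted partitions is genuinely open; the default is
ground truth (cleaner per-stage models, and an oracle-routed prediction
then reproduces the taxonomy-given-true-stage path bitwise), with
`t_train_on = "predicted"` available. `evaluate_gt()` shares one set of
folds (stratified jointly by strain × stage) between both steps so that
per-fold joint accuracy is well defined, and reports G-step accuracy, joint
accuracy, oracle-routed accuracy, per-stage accuracy and the stage
confusion matrix. An arithmetic consequence worth knowing: joint accuracy
is bounded below by G-step accuracy × the minimum per-stage
correctly-routed accuracy.

## BEST accuracy comparison

`best_compare()` models each group of per-fold accuracies as Gaussian with
unknown mean and sd; means and sds carry normal priors (the sd prior
truncated positive), centered on the pooled sample statistics with sd 0.5 —
weakly informative on the accuracy scale. A component-wise random-walk
Metropolis–Hastings chain runs 11,000 iterations and discards the first
1,000 as burn-in (a fixed, automated burn-in; `chain_diagnostics()` flags
acceptance rates outside [0.1, 0.7] where manual inspection would be
warranted). Proposal scales default to 2.4 × pooled sd / √n, which lands
acceptance in that band across the fold-accuracy regimes the tests cover.

"The null is true" needs a number: it is defined as a region of practical
equivalence (ROPE) of half-width 0.005 on the difference of mean accuracies
— half a percentage point, below which two models are operationally
interchangeable. `p_null` is the posterior mass inside the ROPE. Note the
regime dependence: comparing a fold-accuracy vector against itself gives
`p_null` near its maximum, but that maximum only exceeds 0.5 when the
posterior spread of the mean difference is comparable to or smaller than
the ROPE — which holds in the 10-fold-CV regime (per-fold sds of a few
tenths of a percent) this tool targets. Both groups degenerate (zero
spread) is resolved analytically. Multiple comparisons go through
`fdr_adjust()`, Benjamini–Hochberg at level 0.05.

## Problem sizes used by the tests and acceptance script

Unit tests run on miniature libraries (typically 4–6 strains × 4 stages ×
8–20 spectra, 30–120 channels) where every property is still expressible.
The end-to-end acceptance checks use a 12-strain × 4-stage × 50-spectra
library at 300 channels (2,400 cells) for the recoverability and
separation checks, a 36-strain library at reduced depth for the
reference-extension check, and 200 simulated comparisons for BEST
calibration — sizes at which the full pipeline, including the 54-model
leakage audit, completes comfortably on a single CPU.

## Known limitations

* The synthetic generator's effect sizes are conventions, not estimates of
  real spectral variability; absolute synthetic accuracies say nothing
  about accuracies on real spectra.
* ALS baseline parameters and Savitzky–Golay defaults are community
  conventions; protocols tied to specific instruments should override them.
* `ISM_SDR` is this package's documented variant of an iterative supervised
  kernel DR; it is deterministic and oracle-free by construction, and its
  kernel memory cost is O(n²), so it is the slowest grid member on large
  libraries.
* The BEST model is Gaussian per group (means and sds with normal priors)
  rather than the heavier-tailed t likelihood sometimes used; with 10–100
  fold accuracies per group the practical difference is small, but extreme
  outlier folds would be better served by a t likelihood.
* The G-T ensemble uses hard routing; probability-weighted soft routing is
  a plausible extension, deliberately out of scope.
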