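---
title: "Methods: simultaneous GSH/H2O2 quantification from ratiometric SERS spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simultaneous GSH/H2O2 quantification from ratiometric SERS spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement problem

Gliomas carrying an IDH1 mutation differ metabolically from wild-type
tumors: mutant tumors run higher hydrogen peroxide (H2O2, tens to hundreds
of micromolar) and somewhat lower glutathione (GSH, millimolar) than
wild-type tumors, and both tumor types hold far more GSH than normal brain
(< 1 mM). A dual-reporter gold-nanostar SERS probe encodes the two
concentrations in its Raman spectrum: the band at 542 cm^-1 grows with GSH
(together with 806 and 1023 cm^-1), the band at 628 cm^-1 shrinks with
H2O2 (together with 801, 1164, 1426 and 1617 cm^-1), and the band at
928 cm^-1 is inert and serves as an internal reference. Quantification is
ratiometric: `r1 = I542/I928` tracks GSH, `r2 = I628/I928` tracks H2O2,
and dividing by the same reference cancels global intensity variation
(probe dose, focus, integration time).

`sersquant` implements the computational side of this workflow end to end:
a spectrum data model with the standard preprocessing, a synthetic SERS
simulator, the RPM spectrum-to-image transform, a dual-branch
batch-correlation regression network (DBCNet) with 1D/2D residual
baselines, peak-ratio calibration with inverse quantification and spatial
maps, and a two-stage logistic genotype classifier with ROC/AUC and
confusion-matrix reporting.

# The synthetic spectrum generator

No public spectra accompany this problem, so the simulator is a
first-class, tested module, and its defaults define the study conditions
used throughout the tests.

Each spectrum is a sum of Lorentzian lines on a 400-1800 cm^-1 axis
(default: 2 cm^-1 spacing, which puts the three analytically used peaks
542/628/928 exactly on grid), plus an optional random quadratic baseline
and additive white noise:

* **Line shape.** Lorentzian, the standard Raman line model. Default
  half-width at half-maximum 4 cm^-1 (FWHM 8 cm^-1), typical of sharp
  reporter bands. Width matters: much broader lines leak measurable
  Lorentzian tails from the strong 542 band into the 628 extraction
  window, producing exactly the kind of channel cross-talk the physical
  probe is designed not to have. At FWHM 8 the noiseless
  calibrate-then-invert round trip is self-consistent to better than 1%
  over the full calibration grid.
* **Response forms.** Affine in concentration for both channels:
  `amp = base * (1 + 0.4 * c_GSH)` for GSH-responsive peaks and
  `amp = base * max(0.05, 1 - 0.0045 * c_H2O2)` for H2O2-responsive peaks
  (relative units per mM and per uM). The GSH channel is reported as
  robustly linear by the probe's characterization; the functional form of
  the H2O2 decay is not published, so the affine-with-floor default is a
  modeling choice and the response table is pluggable. The slopes are
  simulator parameters chosen so the ratios move monotonically across the
  physiological working ranges (GSH 0.5-20 mM, H2O2 5-200 uM); they are
  not claims about the real probe's sensitivity.
* **Orthogonality.** GSH-responsive amplitudes do not depend on H2O2 and
  vice versa, and the 928 cm^-1 reference depends on neither - the
  simulator mirrors the probe's reported interference-free behavior, and
  the tests assert it.
* **Noise.** Additive Gaussian noise with sd = 1% of the reference peak
  amplitude plus a random quadratic baseline (coefficients up to 5% of
  the reference amplitude). This is deliberately mild but non-zero: it is
  enough to make baseline subtraction and ratiometric correction matter
  without burying the signal. The generator does not model spikes,
  detector saturation, wavenumber miscalibration, autofluorescence or
  probe-uptake variation, so passing tests say nothing about robustness
  to those failure modes on real instrument data.
* **Calibration design.** The default factorial database crosses 6 GSH
  levels {2, 4, 6, 8, 10, 16} mM with 8 H2O2 levels
  {1, 25, 50, 75, 100, 125, 150, 200} uM at 200 replicates per cell -
  9600 spectra.
* **Tissue cohorts.** Per-class concentrations are drawn from
  zero-truncated normals with the published in-vivo allograft statistics:
  GSH 12.08 +/- 0.53 mM (IDH1-WT), 9.20 +/- 0.83 mM (IDH1-MUT), and H2O2
  68.54 +/- 4.51 uM (WT), 109.3 +/- 9.44 uM (MUT). Normal brain GSH is
  published only as "below 1 mM", so the default is 0.7 +/- 0.15 mM;
  normal-brain H2O2 is not published for this probe and defaults to a low
  physiological 15 +/- 5 uM. Both choices were made once, on physiological
  grounds, before any classifier was run.

# Preprocessing and the RPM transform

Instrument-style preprocessing is an index-window crop (1-based inclusive;
the convention makes "the 50th to 336th points" a 287-point spectrum)
followed by division by the spectrum maximum. Normalized spectra are
encoded for the 2D networks as the Relative Position Matrix,
`RPM[i, j] = x_i - x_j`: an M x M antisymmetric image whose rows/columns
carry every pairwise intensity contrast. The transform cancels constant
offsets, is homogeneous of degree 1, and needs no further rescaling - the
values are already in the normalized intensity range. The package fixes
the order preprocess-then-RPM (the reverse is testable by calling `rpm()`
on raw intensities, but it is not the default path).

# DBCNet and the reference baselines

All three models are trained from scratch inside the package by a small
matrix-based network engine (im2col convolutions evaluated by BLAS,
explicit backpropagation, Nadam). Every layer's gradient is verified
against central finite differences in the test suite.

* **DBCNet**: RPM image -> shared residual 2D backbone -> global average
  pooling -> two branches (one per metabolite), each
  `dense -> ReLU -> batch correlation -> dense(1)`.
* **2D baseline**: same backbone, one shared `dense(2)` head, no batch
  correlation - i.e. DBCNet minus its contribution.
* **1D baseline**: residual 1D convolutions on the raw preprocessed
  spectra with a shared `dense(2)` head.

The desk-scale `"reduced"` backbone average-pools the RPM image (factor 2
by default - input resolution, not width, turned out to limit H2O2
accuracy), applies one stride-2 3x3 convolution per entry of `widths`
(default 8, 16, 24, 32 channels) and one residual block, and pools
globally to a 32-dimensional feature. The
full `"resnet18"` topology (7x7 stem, max-pool, four stages of two basic
blocks, 512-d features, ~11M parameters) is available and tested for its
I/O contract; the reduced backbone is what a single CPU trains in minutes,
and both baselines share its widths so model comparisons are
capacity-matched.

## Batch correlation

Given the N x D matrix of branch features in a batch, each feature is
replaced by a convex combination of all features, weighted by pairwise
cosine similarity:

F'_i = sum_k a_k F_k,  with a_k >= 0, sum_k a_k = 1.

The published form of the weights is not recoverable from the source
material, so two standard normalizations are implemented: softmax over
similarities (default, with a temperature) and positive-part similarities
normalized to sum to one (`"sumpos"`). `batch_correlation()` with the
default temperature 1 reproduces the textbook two-row example
(softmax of similarities (1, 0) gives weights e/(e+1) and 1/(e+1)).

Two practical findings shaped the training defaults, and both are worth
recording because they are consequences of the convex-combination form
itself:

1. **Mean collapse at initialization.** A freshly initialized backbone
   maps all inputs to almost-parallel feature vectors (pairwise cosines
   above 0.99, since post-ReLU features share one dominant direction).
   The update then returns nearly the batch mean for every sample,
   predictions lose their dependence on the input, and gradient descent
   stalls at chance-level regression accuracy. This happens for every
   normalization and temperature tried. The remedy is a warm-up schedule
   (`train_config(bc_warmup = 0.75)`): the first 75% of the epoch budget
   trains with the layer held at identity, then the joint phase switches
   it on with a fresh optimizer state. The operator itself is unchanged;
   only when it becomes active during optimization changes.
2. **Temperature.** After warm-up, features of same-concentration
   replicates have cosines around 0.9997 against roughly 0.992 for
   different concentrations. A temperature of 1 cannot convert a margin
   that small into selective weights, so the model default is 0.002,
   which turns the update into a soft average over the sample itself and
   its near-replicates in the batch - denoising within a concentration
   cell rather than indiscriminate mixing.

At inference the default is `mode = "per_sample"`: batch correlation
degenerates to the identity so a tissue point's prediction never depends
on unrelated co-batched points. `mode = "cohort"` applies the update
across inference batches - the regime the network is trained in, and the
one used to evaluate held-out calibration data (a held-out set is itself
a cohort of replicates, and evaluating in the training regime is how the
original protocol necessarily operated).

## Training protocol

Nadam with initial learning rate 0.001; loss is the unweighted sum of the
two per-metabolite MAEs after dividing H2O2 labels by `h2o2_scale` so
both tasks span comparable numeric ranges (GSH 2-16 mM against H2O2
1-200 uM; without rescaling the H2O2 term dominates the summed MAE ~10:1).
The multi-task weighting is not published; the scale is a package design
choice, set so the desk-scale network splits its capacity roughly evenly
between the metabolites. Up to 400 epochs with batch size 32,
learning-rate reduction on validation plateau (patience 25, factor 0.1,
so one reduction lands at 1e-4), early stopping (patience 30), and
restoration of the best-validation weights. One integer seed drives weight
initialization and batch order; splits take their own seed. Training is
deterministic for a given seed up to BLAS rounding.

The dataset split draws 20% for test, then 1/10 of the remainder for
validation (banker's rounding at each step: 9600 records split
6912/768/1920). When concentration labels are present the split is
stratified per concentration pair with largest-remainder apportionment, so
every grid cell appears in every part while the global sizes stay exactly
the unstratified ones; `strata = NULL` disables this.

## Problem sizes used in the tests

The test and acceptance runs use a reduced analogue of the full design:
128-point spectra, 6 x 8 grid, 25 replicates (1200 spectra,
864/96/240 split), reduced backbone, 60 epochs. On this scale the trained
DBCNet reaches held-out R^2 >= 0.99 for both metabolites in a few minutes
of single-CPU time, the desk-scale twin of the published
instrument-data accuracy. Model-comparison runs (DBCNet vs the 2D
baseline over five seeds) use a lighter reduced variant (pool factor 4,
widths 12/24, shared by both models) at 24 epochs per model; the
published enhancement percentages depend on undeposited instrument data
and are checked only as a direction, never as values.

# Ratiometric calibration and mapping

Peak intensities are extracted as the window maximum after subtracting
the straight line through the window's endpoint samples
(default +/- 15 cm^-1); the local linear baseline makes the extraction
robust to the simulator's quadratic background and to global offsets,
and a flat spectrum extracts exactly zero. Calibration is ordinary least
squares of ratio on concentration, with the response sign enforced
(GSH slope positive, H2O2 negative - a wrong sign means swapped channels
and is an error, not a warning), and the standards' concentration range
stored as validity bounds. Quantification inverts the line; results
outside the bounds are flagged `extrapolated`, negative inversions are
clipped to zero and flagged. Spatial maps report GSH, H2O2 and an
H2O2/GSH layer per grid point, with unvisited or failed points masked.
The H2O2/GSH layer divides quantified concentrations (uM/mM) by default
because concentrations are the quantity with physical units; a
`raw_ratio` mode (r2/r1) exists for sensitivity analysis.

# Two-stage genotype calling

Stage 1 separates tumor from normal on the GSH channel; stage 2, fitted
on tumor points only, separates MUT from WT on the H2O2 channel. Both are
univariate maximum-likelihood logistic regressions, with a
ridge-stabilized fit (slope penalty, via `optim`) substituted and flagged
when the classes are perfectly separated. Two feature recipes mirror the
two deployment settings: `"ratios"` (stage 2 on r2, the animal-study
form) and `"h2o2_gsh"` (stage 2 on the quantified H2O2/GSH quotient, the
patient-tissue form). The decision threshold defaults to 0.5 at both
stages; a point exactly at the stage-1 threshold is called tumor
(sensitivity first). A single multinomial three-class fit (via
`nnet::multinom`) is available for comparison because the published
two-variable logistic figure is ambiguous between the two readings; the
hierarchical form is the default since the published workflow is
explicitly two-step. ROC curves sweep every distinct score as a
threshold; the trapezoidal AUC then equals the Mann-Whitney probability
with ties counted 1/2, which the tests verify against brute-force pair
enumeration and against an independent library implementation.

# Numerical choices and degenerate inputs

* Max normalization requires a positive maximum; all-zero spectra are
  errors, not silent NaNs. The reference peak must extract positive
  intensity or the point is masked/errored rather than quantified.
* Batch correlation requires non-zero feature rows (cosine undefined);
  the layer raises rather than epsilon-guarding silently.
* `round()`'s round-half-to-even is used for split sizes; stratified
  apportionment breaks remainder ties by stratum order, so splits are
  bit-reproducible.
* Weight initialization is He-normal; convolutions carry biases; no batch
  normalization is used (at the reduced scale it is unnecessary, and the
  full topology is exercised for its contract, not trained to
  convergence).
* Early stopping compares validation loss with a 1e-9 absolute margin;
  the LR scheduler and stopper share the plateau counter reset.

# Known limitations

* The simulator's affine responses make the calibration problem more
  linear than a real probe's chemistry; the deep models are therefore
  validated on recovery and relative comparisons, not on absolute
  difficulty.
* Per-sample inference after cohort-mode training leaves a small
  train/test regime gap for DBCNet; at the default sharp temperature the
  gap is minor, but it is the price of predictions that do not depend on
  batch company.
* The published AUCs (0.9992/0.9801 animal, 0.9851 patient) and
  enhancement percentages (63/31/33%, 66/20/32%) were measured on
  undeposited instrument data; this package checks the corresponding
  directions and magnitudes on synthetic cohorts only.
* The full 18-layer backbone is provided and contract-tested but not
  trained in CI; training it on 287-point spectra is an instrument-scale
  job, not a desk-scale one.
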