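---
title: "Classifying and tracking ICA components with focis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying and tracking ICA components with focis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focis)
library(dplyr)
```

## The problem

Spatial ICA decomposes a resting-state fMRI dataset into a user-chosen
number of independent components (NIC), each a spatial statistic map paired
with a time course. Only some components reflect resting-state functional
networks (RFN); the rest are artifacts (ART) from head motion, vessels,
ventricles, susceptibility, or the scanner. Manual sorting is slow and
biased, and the choice of NIC itself reshapes every component. `focis`
automates the binary RFN/ART decision with a feature-optimized SVM, and
tracks a chosen component across decompositions of different NIC.

## The classification model

Each component is first filtered with the standard rule: voxels must exceed
the one-sided p < 0.001 cutoff (z, or Student-t when degrees of freedom are
given) and belong to a contiguous cluster of at least 20 voxels
(face adjacency by default, the most conservative neighbourhood and the
analogue of AFNI's NN=1; 18 and 26 are available). Five features summarize
the surviving signal:

1. **gm_pos_overlap** — the fraction of suprathreshold positive statistic
   mass inside the gray-matter mask. Value-weighted rather than
   voxel-counted, so one strong cortical peak outweighs faint spill-over;
   both definitions are defensible, and the value-weighted one is adopted
   here as normative.
2. **peak_in_gm** — whether the suprathreshold peak voxel sits in gray
   matter. Ties at the maximum resolve to the lowest linear voxel index, so
   the feature is deterministic.
3. **freq_ratio** — periodogram power in the 0.01–0.08 Hz band over total
   non-DC power. Resting-state fluctuations live below 0.08 Hz; the 0.01 Hz
   floor excludes drift. A plain untapered periodogram keeps the value
   exactly reproducible; the low/total (rather than low/high) ratio keeps it
   in [0, 1]. Both band edges are arguments.
4. **lag1_autocorr** — lag-1 Pearson autocorrelation of the time course;
   near 1 for hemodynamically plausible series, near or below 0 for spikes.
5. **bbox_voxel_ratio** — size-weighted mean over clusters of bounding-box
   volume over cluster size; 1 for solid blocks, large for rims, sheets and
   streaks.

Components that retain no cluster are *degenerate*: their spatial features
take fixed defaults (0, 0, and the 27 worst-case bounding-box ratio of an
isolated voxel) and classification force-labels them ART, since a map with
no significant cluster cannot be a network under the filtering rule.

Features are conditioned (mean-centred, scaled by the training-set standard
deviation) before any model sees them. The classifier is a soft-margin SVM
with the Gaussian kernel `k(x, y) = exp(-sigma * ||x - y||^2)` — the
bounded LIBSVM/kernlab convention — at cost C = 100 and per-class error
weights 10:1 against misclassifying true networks, reflecting the
operating philosophy that a discarded network is worse than a retained
artifact. The width sigma defaults to a seeded draw between the 0.1 and 0.9
quantiles of the inverse squared pairwise-distance statistic on a
subsample (any value in that bracket performs comparably); a deterministic
midpoint is available. Hyper-parameters can be confirmed by exhaustive grid
search over C in [10, 1000] step 10 and sigma in [0.1, 1.0] step 0.1
(1000 points) under stratified 5-fold cross-validation, maximizing pooled
accuracy subject to sensitivity = 1; ties resolve to the smallest C, then
the smallest sigma. When no grid point attains sensitivity 1, the search
falls back to plain accuracy with a warning. The solver is kernlab's
LIBSVM-derived SMO; the fitted state (support vectors, dual coefficients,
bias, conditioning) is extracted into a plain-JSON model whose stored
decision function is verified against the solver's own predictions at
training time, so serialized models reproduce decisions exactly.

## Feature selection

The F-score of a feature is the Fisher ratio
`[(m+ - m)^2 + (m- - m)^2] / (s+^2 + s-^2)` with within-class sample
variances; it is invariant to affine rescaling and label swaps. The
reduction loop ranks features, then sweeps ascending F-score thresholds:
at each threshold the low-scoring features are dropped and validation
accuracy is estimated by repeated stratified random splits (default 50
repeats, 30% holdout). The sweep stops when mean accuracy falls more than a
tolerance (default 0.02) below the best mean seen — the operational reading
of "decreases significantly", which no printed rule quantifies — and the
kept set is the smallest one within tolerance of the best. Explanatory
power is assessed with a binomial GLM (logit link) with per-coefficient
Wald tests, matching the per-coefficient t/p presentation conventional for
this model; `relative_aic(a, b) = exp((a - b)/2)` compares two fitted
models' information loss.

## Tracking across model orders

To follow one component through decompositions at different NIC, an
epsilon-SVR (epsilon = 0.1, C = 100) is trained on the conditioned features
of the reference decomposition with target 1 for the reference component
and 0 elsewhere. Applied to another decomposition, its clipped-to-[0, 1]
outputs are similarity "probabilities"; components are ranked by them (ties
by id). No probability calibration is applied — near the training order the
regression near-interpolates its targets, and raw outputs are reported.
For the tracker's kernel width the classifier's quantile-draw heuristic is
a poor fit: a single decomposition offers few, strongly clustered points,
and near-duplicate pairs push the drawn sigma so high that the kernel
cannot generalize. The tracker therefore defaults to the inverse median
squared pairwise distance, a robust single-point choice; any explicit
sigma overrides it.

Change is quantified by CISOTA, `1 / (spatial overlap x time-course
correlation)`: overlap is the fraction of the reference's binarized map
(same p < 0.001 / 20-voxel rule, configurable) covered by the candidate,
and r is the Pearson correlation of the time courses. An unchanged
component scores exactly 1. When the product is non-positive the index is
undefined and a flagged infinite sentinel is returned instead of a signed
value. ICA's sign ambiguity can be neutralized with `abs_r = TRUE`
(default off, so that sign flips are visible rather than silently
absorbed). Cross-sectional change between consecutive orders matches every
component to its minimum-CISOTA candidate in the next decomposition by
exhaustive search — a deterministic alternative to fitting one SVR per
component, with the same overlap-correlation currency.

## Cluster-extent calibration

The p < 0.001 / 20-voxel rule is calibrated by Monte-Carlo simulation in
the AlphaSim style: unit Gaussian white noise on the grid, Gaussian
smoothing at the stated FWHM (6.2 mm mirrors the average smoothness
estimated on typical inputs), re-standardization to zero mean and unit
variance within the mask — so the voxelwise cutoff stays honest after
smoothing, a step the procedure's description leaves open — thresholding,
and recording the maximum cluster size. `prob_by_size[k]` is the fraction
of iterations whose largest cluster reached k, non-increasing in k by
construction. The simulator uses z quantiles (noise is Gaussian), while
map thresholding accepts Student-t degrees of freedom, because observed
maps are typically one-sample t statistics.

## The synthetic study conditions

The generator emulates melodic-style output directly — pseudo-t maps and
time courses — rather than simulating BOLD physics and re-running ICA,
which would add melodic-scale complexity without testing anything this
package does. Defaults: 32 x 32 x 16 grid at 3 mm, 200 timepoints at TR =
2 s, blob amplitude 12 against unit map noise. The brain is an ellipsoid;
gray matter a shell (normalized radius 0.55–0.85, kept clear of the
contour); the ventricle a small core. RFN-like components are compact
Gaussian blobs centred mid-shell with band-limited slow time courses;
artifact styles are a modulated rim shell on the brain contour, a
ventricle blob, and core blobs with spiky or high-frequency (0.12–0.2 Hz)
time courses. The amplitude guarantees every planted component survives
the filtering rule, and class-conditional feature margins are wide by
construction — passing classification tests therefore demonstrates the
pipeline's correctness on separable data, not performance on real fMRI,
where class overlap, within-class heterogeneity and registration error
are all harsher.

NIC series re-use one realization of each pooled component across model
orders (small per-order perturbations), so a tracked component genuinely
persists. The tracked reference is special in two ways, both deliberate:
it stays verbatim until the planted split (the identity-tracking
invariant), and it carries a distinctive signature — an elongated blob plus
a mixed slow/fast time course (freq_ratio near 0.5, lag-1 near 0.4) that no
other component family occupies. In a five-feature space, components with
coinciding features are fundamentally untrackable; the generator plants a
reference that is identifiable, as the networks worth tracking in practice
(default-mode, motor, visual) are. At the split order the reference's blob
is partitioned across a one-voxel-plane band into two children that share
its time course, so the children's overlaps with the parent sum to ~1 and
both inherit the temporal fingerprint.

## Numerical choices and degenerate inputs

* Voxel indexing is 0-based for component ids and 1-based internally in R;
  the affine is carried but never used to resample — grid mismatches are
  errors, not warnings.
* NaN voxels are rejected at read time; no fill value is defensible.
* Peak ties: lowest linear index. Grid-search ties: smallest C, then sigma.
  Ranking ties: smallest component id.
* Zero-variance features abort conditioning with the feature named;
  constant time courses error in `feat_lag1_autocorr` and warn (returning
  0) in `feat_freq_ratio`.
* Perfect separation in the GLM is flagged, not hidden: Wald statistics at
  the optimizer's boundary are reported as-is with `separation = TRUE`.
* Problem sizes used by the test suite: classification corpora of 50 + 30
  components on the default grid; tracking series of five orders
  (8–16 components); calibration grids of 16^3 (unsmoothed null) and 48^3
  at 3 mm (smoothing comparison), 2000 iterations each. These are the
  package's chosen study conditions for a desk-scale, fully reproducible
  suite.

## Known limitations

* The five feature definitions are this package's normative reading of the
  brief criteria they encode; value-weighting and band conventions are
  documented choices, not the only defensible ones.
* Class-weight ratio (10:1) encodes "penalize discarding networks" but any
  specific ratio is a convention; it is an argument everywhere.
* The SVR tracker shares the classifier's features, so components
  indistinguishable in that space cannot be told apart, however the kernel
  is tuned.
* The Monte-Carlo calibration assumes stationary Gaussian noise and a
  rectangular (or user-supplied) mask; real fMRI noise is neither
  stationary nor Gaussian, and analytic random-field corrections are out
  of scope.
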