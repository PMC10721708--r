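---
title: "deformcyte: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{deformcyte: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Fetal and adult red blood cells (RBCs) differ in mean volume (fetal about
21% larger) and in mechanical moduli (fetal cells are more deformable).
When cells are pushed through a narrow microfluidic constriction and
filmed at high speed, both differences express themselves in the video: a
size contrast in every frame, and a deformation contrast concentrated in
the frames in and just after the constriction.  `deformcyte` implements
the full analysis chain that turns such videos into a fetal-vs-adult
classifier and into statistics about donor-level effects: synthetic video
generation with planted ground truth, cell detection, tracking, clip
extraction, a two-pathway spatiotemporal convolutional classifier,
donor-disjoint cross-validated evaluation, a variance-component analysis
of per-donor accuracies, and a data-ramping experiment.

Because no public recording archive exists for this assay, the package
ships a synthetic video generator as a first-class, tested module.  All
quantitative claims made by the package's tests are claims about this
synthetic system, not about real recordings; see "What the generator does
and does not emulate".

# The synthetic video generator

`scene_params()` describes the imaging scene: 8-bit grayscale frames,
nominally 800 x 150 px at 500 frames/s, a channel bounded by static walls
that taper into a central constriction, uniform background with Gaussian
sensor noise (`noise_sd`, default 2 intensity units), and a throughput of
2 cells/s by default with exponential (Poisson) inter-arrival times.

Cells are rendered as anti-aliased ellipses with signed contrast (default
-40: darker than background) and a Gaussian edge profile about 1 px wide.
A cell translates left to right at constant speed (default 8 px/frame),
elongates along the flow axis while inside the constriction and relaxes
back exponentially afterwards; the elliptical outline preserves its area
during elongation, so projected area is a size cue that survives
deformation.  Ground truth records, per frame, every rendered mask (the
exact-ellipse pixel set) and its centroid, plus per-cell class labels and
entry/exit frames.

Class defaults (`rbc_class_defaults()`):

* projected area: adult 120 px^2; fetal `120 * 1.21^(2/3)` (about
  136 px^2).  The +21% *volume* difference is mapped to a projected-area
  ratio of `1.21^(2/3) ~ 1.136` under isotropic scaling, since imaging
  sees a 2-D projection.  The ratio is a single configurable constant
  (`fetal_adult_area_ratio()`).
* per-cell area coefficient of variation 0.1 (log-normal).
* deformation amplitude (aspect ratio in the constriction): adult 1.3,
  fetal 1.6, with relaxation time constants of 6 and 9 frames.  These
  encode the larger deformability of fetal cells; the specific values are
  package choices, selected once to give a clearly expressed (but not
  trivial) dynamic contrast.
* donor effect: one log-normal multiplicative factor per donor (sd 0.05 on
  the log scale) on mean area and on the deformation-amplitude excess.
  This creates within-donor correlation -- cells from one donor look
  systematically alike -- which is exactly the structure that makes
  donor-disjoint splitting necessary: a donor at two standard deviations
  of the size effect overlaps the other class in area and can only be
  classified through its deformation dynamics.

## What the generator does and does not emulate

Emulated: static background with sensor noise, wall/constriction geometry,
8-bit quantization, sparse stochastic arrivals, transient elongation with
relaxation, class contrasts in size and deformation, donor-level random
variation.  Not emulated: actual fluid dynamics (no Navier-Stokes), no
optical point-spread function or focus drift, no cell-cell hydrodynamic
interaction, no rotation or tumbling, no debris or illumination drift.
Passing tests therefore demonstrate that the pipeline's machinery is
correct and can recover a planted, physically plausible contrast; they do
not demonstrate performance on real microscope recordings.

# Detection

Detection mirrors standard temporal-median background subtraction:

1. every frame is smoothed with a separable Gaussian kernel
   (`sigma` = 1 px by default; the kernel radius is `ceiling(3*sigma)`
   with edge-replicate boundaries — chosen to suppress single-pixel sensor
   noise without eroding 50 px^2 cells);
2. the background is the per-pixel median of 100 frames sampled uniformly
   without replacement (all frames if fewer); moving cells occupy any
   given pixel in only a small fraction of frames, so the median recovers
   the static scene;
3. a frame is binarized by `|smoothed - background| > 5`, a strict
   inequality on raw 8-bit values, symmetric in contrast sign;
4. connected components with area strictly greater than 50 px are
   reported as cells, with centroid and half-open bounding box.

Connectivity is 8 by default and configurable to 4.  All coordinates are
(row, col), 0-based; bounding boxes are half-open.  These conventions are
stated on every I/O surface.

# Tracking and clips

Regions in consecutive frames are paired by the largest shared pixel area
(exact pixel-set intersections, not bounding boxes), resolved greedily in
descending overlap so no region is claimed twice.  Ties are broken
deterministically toward the candidate with the smaller `(min_row,
min_col)` corner; with about 2 cells/s ties are rare, and determinism is
worth more than assignment optimality.  Unmatched regions start or end
tracks; tracks shorter than 8 frames (the slow pathway's input
requirement) are dropped.

Each track becomes a fixed-size video clip: a 50 x 50 window centred on
the region centroid (rounded to the nearest pixel) is cut from the raw,
unsmoothed frames, zero-filled where it leaves the frame.  Clips are
taken from raw rather than background-subtracted frames -- the classifier
should see the cell as imaged, and centring already removes translation
so that the network sees shape and deformation, not position.  Clips are standardized to a fixed length
for batching: longer tracks are uniformly resampled, shorter ones padded
by replicating the last frame.  The default standardized length is 64
frames; the desk-scale experiments in this package use 16 (see problem
sizes below).  The length must be divisible by the slow pathway's
temporal stride.

# The two-pathway classifier

The classifier is a two-pathway 3-D convolutional network.  The *slow*
pathway reads every `tau`-th frame (`tau = 8`) and carries the bulk of
the channel capacity -- it models spatial structure, i.e. the size cue.
The *fast* pathway reads frames at `alpha = 8` times the slow rate (every
frame, with the defaults) but at `beta = 1/8` of the channel width -- a
lightweight stream for motion and deformation dynamics.  At the stem and
after each stage but the last, fast features are carried into the slow
pathway by a lateral connection: a time-strided convolution (kernel 5 in
time, stride `alpha`) producing `2*beta*C` channels, concatenated onto
the slow features.  Both pathways are stacks of residual blocks of two
3x3x3 convolutions with batch normalization; global average pooling over
space-time, concatenation of the two pathway features, dropout (0.5) and
a linear softmax head give the two class scores.

The `tiny` depth preset (two stages of one block, slow widths 32 and 64,
hence fast widths 4 and 8) is the desk-scale configuration used by all
tests.  Deeper presets (`"50"`, `"101"`) express the ResNet-50/101 stage
layout in the configuration; they use the same two-convolution block
family, and nothing in this package trains them.

Numerical and initialization choices: He-scaled Gaussian weights; the
final batch-norm gain of every residual branch is initialized to zero so
each block starts as a near-identity map -- without this, training on
small clip sets occasionally collapsed onto a constant predictor; inputs
are scaled to `[-0.5, 0.5]`; the first convolution is adapted to one
grayscale channel.

Training uses mini-batch SGD (batch 8) with momentum 0.9, cross-entropy
loss, and a cosine warm-restart learning-rate schedule (pipeline defaults:
initial rate 0.01, first period 10 epochs, period doubling).  Validation
runs every second epoch on a held-out donor-disjoint split, measured as
macro sensitivity; early stopping triggers after a configurable number of
evaluations without improvement, and the best-scoring weights are
restored.  Train-time augmentation: random spatial jitter (default
+/- 4 px) and temporal jitter (+/- 2 frames); horizontal flipping is
*disabled* by default because flow direction is physically meaningful.

# Splitting, metrics, and evaluation

`make_splits()` partitions donors (never clips) into `k = 5` sets by
class-stratified greedy balancing: donors are ordered by descending cell
count (ties in seeded random order) and each is assigned to the split
with the smallest running total *of its class*, with overall totals as
tie-break.  Plain greedy balancing ignores class and can produce
class-pure splits on small cohorts, which silently breaks validation and
testing; stratification preserves the "approximately 20% per split, both
classes everywhere" structure of the cohort design.  One split (closest
to `1/k` of cells, preferring splits containing both classes) is the test
set; the remaining four are cross-validation folds.  Each fold's model
trains on three folds and early-stops on the fourth; the test split is
scored by all four models.

`compute_metrics()` reports AUC (rank statistic), macro sensitivity (the
unweighted mean of per-class recalls -- the single "sensitivity" number
alongside separate per-class recalls only makes sense as a macro
average, and the ramping experiment defines it that way explicitly),
accuracy, precision and F1 for the fetal class, each in percent with a
95% confidence interval from the normal approximation: Wald
`p +/- 1.96*sqrt(p(1-p)/n)` for proportion-type metrics and the
Hanley-McNeil variance for the AUC.  Given one score column per fold, the
headline numbers are fold means and the confusion matrix is averaged
entrywise across folds; pooled metrics over concatenated folds are
attached alongside.  `per_donor_accuracy()` builds the donors x folds
accuracy grid and summarizes donor-averaged accuracies per class with
every donor weighted equally.

`run_ramping()` holds out the test split, sets aside about 10% of the
training data (donor-disjoint, by cell count) for early stopping, trains
one model per fraction {10%, ..., 100%} of the remaining training clips,
and reports test macro sensitivity against the fraction of the *total*
data ({7%, ..., 70%} under this bookkeeping).

# Donor-effect statistics

Per-donor, per-fold accuracies `A[d, f]` follow the mixed model

    A[d, f] = mu + alpha_d + a_f + eps[d, f],
    a_f ~ N(0, sigma_A^2),  eps ~ N(0, sigma^2),

with donor effects fixed (sum-to-zero; the model writes the donor term
without a distribution) and the cross-validation fold as a random effect.
The design is exactly balanced (every donor scored under every fold), so
REML has closed forms: with `lambda1 = sigma^2 + D*sigma_A^2`, the
restricted likelihood separates into the between-fold sum of squares
(df `F-1`, expectation `lambda1` per df) and the donor-by-fold
interaction sum of squares (df `(D-1)(F-1)`, expectation `sigma^2` per
df).  The REML estimate of `sigma_A^2` is `max(0, (MS_fold -
MS_resid)/D)`.  `lrt_random_effect()` computes the restricted
likelihood-ratio statistic against the model without the random effect
and halves the chi-square(1) upper-tail p-value, because `sigma_A^2 = 0`
sits on the boundary of the parameter space; `p_boundary` can therefore
never exceed 0.5, and under the null the variance estimate piles up at
zero in about half of replicates.  The log-likelihood uses the
conventional restricted-likelihood form with the treatment-contrast
design matrix, which reproduces `lme4`'s `logLik` exactly (the test suite
checks this); AIC is `-2*logLik + 2*k` with `k` counting mean parameters
plus variance parameters, so the reduced (no-random-effect) model on a
32-donor grid has `k = 33`.  No iterative mixed-model solver is used; the
general-purpose solver (`lmerTest`) appears only as an independent
cross-check in the tests.

`anova_donor_fixed()` is the one-way fixed-effects ANOVA over donors with
folds as replicates (df `D-1` and `D(F-1)`; 31 and 96 for the 32 x 4
design), through `stats::aov`.  A zero residual mean square is flagged
degenerate with an infinite F.  `anova_class_difference()` tests for a
class difference in the donor-averaged accuracies: although such tables
are sometimes labelled two-way, with one value per donor and a
two-level class factor the analysis has df 1 and `D-2` (1 and 30), which
is what the implementation does.

# Problem sizes of the desk-scale experiments

The package's own end-to-end check (`synthetic_recovery()`) uses 12
donors (6 per class) of about 50 cells each, rendered into 256 x 150 px
videos at 40 cells/s so a donor recording stays near 600 frames; clips
are standardized to 16 frames; the network is the tiny preset; training
runs up to 60 epochs of one monotone cosine cycle at initial rate 0.05
with +/- 1 px jitter, early-stopped on a donor-disjoint validation split.
These sizes are the package's chosen desk-scale study conditions: large
enough that the planted contrast is learnable across donors, small enough
that the whole experiment runs in minutes on one CPU core.  The higher
initial learning rate (vs the 0.01 pipeline default) reflects that a tiny
model on a few hundred clips needs larger steps to converge within its
epoch budget; both values are exposed configuration, not constants.

# Known limitations

* The generator's deformation model is kinematic (prescribed elongation),
  not mechanical; absolute deformation parameters are not calibrated to
  real moduli.
* The balanced closed-form REML refuses unbalanced accuracy grids by
  design; donors missing from some folds require a general mixed-model
  solver, which is out of scope.
* AVI input/output is not provided; videos are read and written as
  multi-page TIFF.
* Deep presets are configuration only; no pretrained weights exist, and
  the training loop is CPU-bound by design.
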