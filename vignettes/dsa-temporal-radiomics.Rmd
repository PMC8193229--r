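---
title: "Temporal and radiomic quantification of DSA for AVM detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal and radiomic quantification of DSA for AVM detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsavm)
```

## The problem and the model

Digital subtraction angiography (DSA) records the transit of a contrast
bolus through the cerebral vasculature as a time series of
background-subtracted X-ray frames, typically 20-50 frames at 166-333 ms
per frame. In a normal study the contrast fills structures in a fixed
hemodynamic order — internal carotid artery, circle of Willis, a
vessel-free capillary interval, then veins, venous vessels and finally the
dural venous sinuses. A brain arteriovenous malformation (AVM) shunts
blood directly from arteries to veins: the venous sinus opacifies while
the arteries are still filled, venous structures appear out of order, and
the capillary interval disappears.

`dsavm` quantifies exactly this signature. Per-frame bounding-box
detections of five vascular structures are reduced to *structure events*
(first/last frame at which each class is present at detector confidence
`tau`, default 0.5), a *phase timeline* (pre-contrast, early/late
arterial, capillary, early/late venous, post-contrast), and five binary
*temporal features*:

* **T1** — sinus first appears at or before the last artery/Willis frame;
* **T2** — sinus first appears at or before the last Willis frame;
* **T3** — sinus first appears strictly before the venous vessels;
* **T4** — vein first appears at or before the last Willis frame;
* **T5** — the timeline has no capillary frame.

All five are 0 in a normal study and 1 in a shunting one. The "at or
before" (non-strict) reading of T1/T2/T4 versus the strict reading of T3
follows the phrasing of the feature definitions ("before the end /
disappearance" admits co-occurrence; "appear before" does not).
Comparisons whose left-hand event never occurs score 0; an absent
right-hand event in T3 with a present sinus scores 1 (the sinus appeared,
venous vessels never did); absent right-hand events in T1/T2/T4 score 0.

Spatial information is captured by a 1,750-dimensional radiomic vector:
five key frames are sampled in equal proportion over the developed span
(`f_i = first + round(i (last - first) / 4)`, rounding half up), and each
contributes 350 features — 16 first-order intensity statistics, 54
texture features (22 gray-level co-occurrence + 16 run-length + 16
size-zone, on a 32-level quantization), and 280 wavelet-domain features
(8 subbands x 35). Temporal and radiomic features are fused by iterative
sparse representation (ISR) ranking and classified with a linear SVM.

## Phase rules and their edge cases

A frame with any venous structure present is venous (`late_venous` when
the sinus is present, else `early_venous`), *even if arterial structures
co-occur*: the venous definitions are stated by venous content, and
arteriovenous shunting is precisely this co-occurrence. Arterial frames
are split into early/late at the arterial frame of maximal summed
detection-box area, a proxy for completeness of the arterial tree (the
tie rule takes the earliest maximal frame as the start of the late
phase). Empty frames are pre-contrast before the first presence,
post-contrast after the last, capillary strictly between the last
arterial and the first venous frame; any other interior empty frame
inherits the previous frame's label. That last rule is the degenerate
case of a mid-phase detection dropout: it keeps a one-frame dropout from
inventing a capillary phase (which would flip T5) and confines the
perturbation to that frame, consistent with computing temporal features
over all frames rather than trusting any single one.

## The phantom generator

Real annotated clinical DSA is not distributable, so the package ships a
seeded phantom generator that emulates the *timing structure* of the
modality on a fixed anteroposterior layout: artery inferior-center,
Willis annulus at center, vein superior, venous vessel superior-left,
venous sinus superior-right, and for AVM cases a nidus blob. Schedules
draw onset/offset frames with uniform jitter inside diagnosis-consistent
windows, so ties and near-ties are exercised without ever violating the
ordering ground truth; frame counts span 20-50 and frame intervals
166-333 ms, matching routine acquisitions. Structures render as dark
templates (background 230, depth 120 gray levels) whose intensity ramps
in over the first two active frames and out over the last two at weight
0.6 before reaching 1.0 — deep enough that presence is decided
deterministically at the default noise level, while still exercising
confidence thresholding in the detector. Additive Gaussian noise
(default sd 5 gray levels) is applied per pixel before 8-bit
quantization. Defaults use 96 x 96 px frames, large enough to host the
layout with margins and small enough to keep cohort-scale feature
extraction fast.

The grade surrogate makes high-grade AVMs differ from low-grade ones by
a larger nidus (20-26 px vs 10-14 px diameter) and an earlier sinus
onset (15% vs 45% of the arterial span), echoing the clinical
association of grade with nidus size and shunt severity; no claim of
clinical fidelity is made. The generator does **not** simulate vessel
trees, X-ray physics, patient motion, or anatomical variability, so
passing tests demonstrate the correctness of the temporal logic, the
feature bank and the evaluation protocol — not clinical performance.
The reference detector (median-background subtraction, 8-connected
components of pixels more than 30 gray levels dark, minimum area 12 px,
nearest-anchor class assignment, confidence = normalized mean contrast
depth) is a stand-in for a trained detection network and is only
meaningful on the phantom layout; components nearest the nidus anchor
are discarded because the nidus is not one of the five structure
classes. External detectors plug in by emitting the detection-table CSV.

## Detection evaluation

`average_precision()` uses all-point interpolation of the
precision-recall curve at IoU >= 0.5 (the modern convention for
region-proposal detectors; the 11-point variant is not used), greedy
score-ordered matching with ties broken by stable input order, and
half-open integer boxes so that areas are exact. Classes without ground
truth are excluded from mAP rather than given an arbitrary AP.

## Feature bank conventions

Quantization is equal-width over the frame's own min-max range.
Co-occurrence matrices are symmetric, distance 1, direction-averaged over
0/45/90/135 degrees. Degenerate statistics on constant frames are pinned
to documented values: correlation and IMC1 to 0, homogeneity-type
features to 1, entropy to 0, uniformity to 1, skewness/kurtosis to 0.
The wavelet stage is a two-level Haar decomposition with symmetric
padding; retaining both approximation images (LL1 and LL2) is the
minimal convention that yields exactly eight subbands. Which 35 features
per subband make up the 280 wavelet features is not recoverable from the
count alone; the package uses the 16 intensity features plus the first
19 of the canonical 22-feature co-occurrence order, and treats only the
counts (16 / 54 / 8 / 280 / 350 / 1,750) as normative.

## Selection and classification

ISR standardizes features on the supplied table, codes labels -1/+1, and
for each of `K` iterations solves a lasso on a class-stratified
subsample of fraction `rho` (coordinate descent via glmnet); importance
is the mean absolute coefficient and the selection frequency the
fraction of nonzero fits. `lambda = "auto"` is chosen once per table by
5-fold cross-validation and then held fixed. `K` and `rho` are not fixed
by any external constraint; the package defaults are `K = 100`,
`rho = 0.8` for standalone ranking and `K = 50` inside the leave-one-out
protocol, where the ranking is re-estimated in every fold and the
fold-level averaging makes the larger `K` redundant. Subsampling is
index-based, so reordering cases changes the Monte-Carlo draws (not the
asymptotic scores); rescaling features changes nothing because
standardization absorbs scale.

The classifier is a linear SVM (p >> n after radiomics extraction makes
a linear margin the natural default; the kernel is configurable) with
the cost selected from {0.01, 0.1, 1, 10} by stratified inner
cross-validation. Three scoring conventions matter and are deliberate:

* training uses class weights inverse to class frequency;
* case scores are SVM decision values oriented deterministically from
  the factor-level order, not probability-calibrated (Platt scaling
  inside leave-one-out folds of small cohorts is unstable); predicted
  labels threshold the score at 0;
* held-out scores are centered at the midpoint between the training
  class means of the decision value.

The weights and the centering both counter a known artifact of pooled
leave-one-out scores: holding out a case leaves the training set
imbalanced by one, which shifts every fold's decision function against
the held-out class and biases the pooled AUC downward — most visibly
under permuted labels, where the naive protocol measurably drops well
below 0.5 when feature selection runs inside the fold. Even with both
corrections a *single* permuted-label run retains substantial variance
(pooled LOO scores are not independent across folds), which is why the
package's permutation-null checks average over several permutation
seeds.

`loo_cv()` runs standardization, ISR ranking, top-`m` selection
(default `m = 20`) and the SVM strictly inside each training fold; the
leakage-prone alternative (selection once on the full table) exists
behind `dsa_config(select_once = TRUE)` only to mirror an ambiguous
reading of the protocol, and is not the default. `split_evaluate()`
implements the 7:3 protocol: stratified split, LOO on the 70% cohort,
one refit scored once on the untouched 30%. Grading (high vs low) uses
the cross-validation protocol only, on the AVM cases.

## Problem sizes and numerical choices

The shipped tests and the acceptance script exercise: temporal recovery
on 50 noise-free and 50 noisy phantom cases; the AP implementation
against a brute-force envelope oracle on 200 small instances (tolerance
1e-9); AUC against exhaustive pair counting for n <= 12; planted-signal
ISR recovery at n = 200, p = 100, effect 1 sd over 20 seeds; a
diagnosis cohort of 120 cases and a grading cohort of 100 AVM cases
evaluated end-to-end; and a 3-seed permutation null on the
cross-validation cohort. Bootstrap CIs use 2,000 stratified resamples
by default (500 in the cohort-scale runs). Haar reconstruction is exact
to 1e-8; all randomness flows from explicit integer seeds and every
reported run is reproducible bit for bit.

## Known limitations

* The phantom's fixed layout makes the reference detector's class
  assignment trivially correct; detection *evaluation* is general, the
  reference *detector* is not.
* DICOM input is not supported (no reader available in the dependency
  set); PNG directories and multipage TIFF are.
* The 35-feature-per-subband composition of the wavelet group is a
  documented convention, not an externally fixed list.
* Clinical performance numbers cannot be reproduced or verified with
  synthetic phantoms; the cohort-scale checks validate protocol
  direction (combined >= single feature sets; permutation at chance),
  not absolute accuracy.
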