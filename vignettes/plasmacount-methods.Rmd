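---
title: "Counting plasma cells on CD138-stained marrow images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting plasma cells on CD138-stained marrow images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The marrow plasma-cell percentage — CD138-positive cells as a fraction of
all nucleated cells — is a diagnostic criterion for plasma cell neoplasms
(the 10% cutoff separates myeloma from MGUS), yet in routine practice it is
usually a visual estimate. On a CD138 immunostain, plasma cells carry a
brown DAB membrane signal and other nucleated cells a blue hematoxylin
nucleus, so the quantity is in principle countable. `plasmacount`
implements a full counting pipeline: point annotations at cell centers are
turned into a per-pixel training target, a fully convolutional network
regresses class "heatmaps", cell centroids are recovered as heatmap peaks,
and agreement with reference counts is scored with assignment-based
matching, macro-averaged F1 and the intraclass correlation coefficient.

## The model

### Point labels as a segmentation surrogate

Each annotated cell is a single pixel: 1 for CD138-negative, 2 for
CD138-positive, 0 for background (`encode_labels()`). Single pixels carry
too little spatial support for a segmentation loss, so labels are expanded
by grayscale dilation with a Euclidean disc (`dilate_labels()`). The disc
radius is not dictated by the upstream protocol; the default here is 5 px,
i.e. 1.25 µm at 0.25 µm/px — comfortably below the 10 px peak-separation
scale, so discs of neighboring cells rarely merge. Max semantics mean a
positive disc (value 2) wins where it overlaps a negative one; collisions
are counted and reported.

### Network

The network is an encoder–decoder: stages of 3×3 convolution /
batch-normalization / ReLU with 2×2 max pooling between stages, then a
decoder that upsamples with bilinear interpolation followed by convolution,
ending in a 1×1 convolution onto three logits (background, CD138−, CD138+)
at input resolution. A per-pixel softmax turns logits into
pseudoprobability heatmaps. Because the architecture is fully
convolutional, any input whose sides are divisible by 2^(stages−1) is
accepted, which is what makes padded-tile and whole-slide inference
consistent with patch training.

The test and example default is deliberately small — two stages of 8 and 16
channels, receptive-field radius 9 px — so the entire pipeline trains in
minutes on one CPU. A VGG-scale five-stage preset (`network_preset()`)
mirrors the full-scale configuration; it is an interpretation (the exact
VGG variant and decoder widths are not pinned down upstream) and nothing in
the test suite requires it. No deep-learning framework exists in the
supported toolchain, so forward and backward passes (including batch
normalization) are implemented in the package itself on Rcpp/Armadillo
kernels; the backward pass is verified against finite differences in the
unit tests indirectly via training behavior, and was checked exactly during
development.

The analytic `receptive_field_radius` accumulates (k−1)·jump over the layer
stack (jump doubles at each pooling, halves at each upsampling, bilinear
interpolation contributing kernel extent 2). The tests compare it against
an empirical perturbation probe; the analytic value is an upper bound and
the probe may fall a few pixels short when ReLUs zero out border paths.

### Training

The loss is pixelwise categorical cross-entropy with per-class weights,
normalized by the total weight so that rescaling all weights by a common
factor changes nothing (a property the tests assert). Optimization is
plain SGD; momentum 0.9 is on by default and logged in the checkpoint
metadata (the upstream description says only "stochastic gradient
descent"). Augmentation applies the identical geometric transform to image
and labels — flips, rotation with reflect-filled corners (nearest-neighbor
for labels so class codes survive), and a multiplicative brightness jitter
on the image only, default [0.8, 1.25], symmetric in log space. Rotation
angles are uniform in [0°, 360°) by default since reflect padding only
matters for non-right angles; a right-angle-only mode exists, and right
angles are implemented by exact array transposition so four 90° rotations
compose to the bit-identical identity.

After every epoch the validation score is computed by running the *full*
detection pipeline — heatmaps, smoothing, peak calling, assignment
matching, confusion matrix — and taking macro-F1 over the pooled matrix.
The checkpoint returned is the best-validation epoch; among epochs with
equal macro-F1 the one with the lower training loss is kept (the more
converged weights — a tie-break this package chooses, since validation F1
saturates at 1.0 quickly on easy synthetic data). Learning rate and class
weights are exposed through an exhaustive `grid_search()` with first-in-
grid-order tie-breaking; cells that abort (non-finite loss) are marked
failed and never selected.

## Detection and evaluation

Heatmaps are post-processed with a 3×3 median filter then a Gaussian blur
(σ default 1.0 px — the upstream account fixes the filters but not σ),
both with symmetric reflection at borders. Peaks are local maxima at or
above a score threshold, greedily accepted in descending score order with
ties broken in row-major scan order; an accepted peak suppresses anything
at Euclidean distance ≤ 10 px (strictly-greater separation survives). The
score threshold defaults to 0.5 — majority class under the 3-way softmax —
and is applied after smoothing; both choices are configurable because the
upstream account states neither. Peaks are called per class map and then
merged: where a negative and a positive peak fall within the minimum
distance, the higher score wins (exact ties go to positive). The merge is
this package's addition — without it one cell could be counted as both
classes.

Detections are paired with ground truth by a linear sum assignment
(Hungarian algorithm, implemented here since no solver is available in the
supported R stack) on the Euclidean distance matrix, with every distance
above the 15 px (3.75 µm) gate replaced by a sentinel cost
B = threshold·(n+m)+1. B exceeds any feasible total of real distances, so
the solver maximizes the number of gated matches before minimizing
distance; sentinel-cost pairs are then discarded as unmatched. Matching is
class-agnostic so that cross-class confusion cells can be populated.
Matched pairs, unmatched truth and unmatched detections fill the 3×3
confusion matrix over {negative, positive, background}; macro-F1 averages
the two cell-class F1s, and a class absent from both truth and predictions
scores 1 so an empty patch handled perfectly does not sink model selection.

Rater agreement on percentages uses the single-measure two-way
random-effects absolute-agreement ICC, ICC(A,1) =
(MSR − MSE) / (MSR + (k−1)·MSE + (k/n)·(MSC − MSE)); an all-constant table
is defined as 1 with a warning. Clinical reports that state ranges are
reduced to midpoints ("5–10%" → 7.5), and "normal" / "not increased" /
"less than 5%" all map to 2.5, the middle of 0–5%.

## Whole-slide inference

A sliding window (2048 px default) is padded by 32 px of context per side
(2112 px network input); reads past the slide border are mirror-reflected.
Detections in the pad ring are discarded — they belong to the neighboring
tile that owns them — and survivors are offset into slide coordinates.
Because cores are disjoint, stitching needs no deduplication and is
order-free, and whenever the pad covers the receptive-field radius plus the
smoothing and suppression scales, stitched detections equal whole-image
inference exactly except within the receptive field of the outer slide
border (where whole-image inference sees the convolutions' zero padding
but tiles see reflected slide content). The package warns when a
configured network's receptive field exceeds the pad. A tissue mask
(optionally downsampled) skips tiles whose core contains no masked pixel
and filters detections afterward. Overlap deduplication and the mask
resolution are not specified upstream; the discard-pad-ring rule and
"level-0 or stated downsample" semantics are this package's choices
precisely because they make stitching exact.

Slides are read through a minimal reader abstraction (in-memory array or
PPM file). The supported toolchain has no TIFF/SVS codec, so pyramidal
formats are out of scope here; the tiling, padding and stitching logic is
independent of the storage backend.

## The synthetic world

No clinical images ship with the package; every stage is exercised on
synthetic scenes with exact ground truth. A scene is a stated world, fixed
once: a 192×192 px patch with 20 nucleated cells — 5 CD138+ (25%, a
plasma-cell burden well into the neoplastic range) and 15 CD138− —
nucleus radii 4–7 px, centroids ≥ 16 px apart, a 3 px brown membrane ring
around positive nuclei, one nonspecific brown blob carrying no truth
point, and i.i.d. Gaussian noise (sd 8 of 255) clipped to [0, 255].
Placement is rejection sampling capped at 10,000 attempts per object, and
generation is deterministic in the seed.

The geometry is stylized rather than photometrically literal: at a true
40× scale a nucleated cell spans tens of pixels, but what the pipeline
depends on is the color *topology* that separates the classes (ring versus
bare disc), the peak-separation scale relative to the 10 px constraint,
and the 15 px matching gate. Shrinking cells keeps the desk-scale
network's 9 px receptive field sufficient to see a positive cell's ring
from its center. Consequently a green test establishes that the machinery
— label encoding, optimization, peak recovery, matching, stitching,
serving — is correct and self-consistent; it does not establish clinical
performance on real marrow, which involves stain variability, touching
cells, megakaryocytes and scanner differences the generator deliberately
omits.

Whole-slide fixtures are mosaics of independently seeded patches (patch i
uses seed+i) with truth in slide coordinates, and an optional background
margin excluded from the tissue mask.

## Numerical choices and degenerate inputs

* Softmax is max-subtracted; cross-entropy clamps log arguments at 1e−12,
  so a diverging run fails through non-finite activations (caught and
  reported) rather than silent -Inf losses.
* Boundary handling is symmetric (edge-duplicating) reflection everywhere
  a border appears: smoothing, rotation refill, mirror crops, tile reads.
* An empty detection set, an empty truth set, and their combination are
  legal everywhere; percentage on zero cells is an error
  (`plasma_percentage`) or an explicit undefined flag (snapshot service).
* Batch statistics are frozen in eval mode, so inference is bit-exact
  deterministic; two identical uploads produce identical service replies.
* The placement sampler errors (naming the constraint) rather than
  degrading when a scene cannot satisfy the separation constraints.

## Known limitations

* The generator does not emulate marrow texture, stain spectra via color
  deconvolution, or touching/overlapping cells; recovery scores on it are
  upper bounds, not clinical claims.
* Image I/O is PPM/PGM only (no PNG/TIFF codec in the supported stack);
  whole-slide pyramids are represented by the reader abstraction.
* The web service is a single-threaded demonstration loop around a pure
  request handler; the handler, not the socket loop, is the tested
  contract.
* ICC is returned without confidence intervals, and F1 without bootstrap
  uncertainty.
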