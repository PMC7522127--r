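---
title: "Cascaded 2D-3D segmentation of whole-body FDG-PET/CT: models and methods"
author: "petseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascaded 2D-3D segmentation of whole-body FDG-PET/CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Eyes-to-thighs FDG-PET/CT scans of lymphoma and lung-cancer patients contain
metabolically active tumors whose total volume (TMTV) and peak uptake
(SUVmax) are prognostic markers. Delineating the full tumor burden by hand is
slow and reader-dependent, and the segmentation problem is severely
unbalanced: roughly 99.5% of the voxels of a whole-body scan are
tumor-free, physiological uptake (brain, heart, liver, kidneys, bladder)
mimics tumor intensity, and scans are too large for a single 3D network at
full resolution. `petseg` implements a cascaded architecture built for
exactly these constraints:

1. **2D stage** -- a dilated separable residual U-Net segments every axial
   and sagittal slice; the two orientation probability volumes are averaged.
2. **Anatomy stage** -- deterministic detectors locate the brain, liver and
   lungs and split the body into head-neck, chest and abdomen-pelvis slabs.
3. **3D stage** -- candidate lesions (26-connected components of the
   thresholded 2D probabilities) are refined by a region-specific V-Net on
   cubes of 32/64/96 voxels; the final mask is the thresholded average of
   the 2D and 3D probability volumes, from which TMTV and SUVmax are read.

## Data model and conventions

All volumes are `voxel_grid`s indexed `(z, y, x)` with z index 1 the most
superior slice, y index 1 most anterior, x index 1 patient-right ("left on
the radiological display"). PET is converted to body-weight SUV,

$$\mathrm{SUV}(v) = \frac{a(v)\, m}{D \cdot 2^{-\Delta t / t_{1/2}}},$$

with $a(v)$ the activity concentration (Bq/mL), $m$ the body weight in
grams, $D$ the injected dose (Bq) decay-corrected over the delay $\Delta t$
between injection and acquisition start ($t_{1/2}$ = 6586.2 s for F-18).
Body-weight SUV with a single decay correction is the most widely used
normalisation and is assumed whenever the source data does not state one.
Both modalities are resampled to 2 mm isotropic voxels (trilinear for
intensities, nearest-neighbour for masks) before anything else runs; all
later thresholds (erosion radii, patch edges, window offsets) are stated in
mm and converted at that spacing.

DICOM series and NIfTI volumes are both accepted. The bundled DICOM reader
is deliberately minimal -- explicit/implicit VR little endian, single-frame
16-bit files, rescale slope/intercept, and the calibration tags including
the radiopharmaceutical information sequence -- because its only job is to
feed the SUV computation; NIfTI plus a JSON calibration sidecar is the
recommended path for bulk work.

## The 2D network

Each resolution level of the U-Net holds two residual sub-blocks. A
sub-block applies two separable convolutions, each computed as four
depthwise 3x3 convolutions at dilation rates 1, 2, 4 and 8 whose outputs
are concatenated and fused by a pointwise convolution, followed by batch
normalisation; the residual sum (pointwise projection when channel counts
change) passes through a ReLU. Dilation buys a large receptive field (33
pixels for a sub-block, vs 5 undilated) without extra downsampling -- the
property that lets a slice network see enough context to reject organ
uptake while keeping small lesions at full resolution. The default
architecture has depth 6 and 8 base filters (doubling per level) on
448x512x2 inputs (PET and CT channels); max pooling downsamples,
nearest-neighbour upsampling and skip concatenations restore resolution,
and a pointwise convolution plus sigmoid emits probabilities.

Choices the architecture description leaves open, fixed here: the four
dilation branches are merged by concatenation plus pointwise fusion
(addition is available via `merge = "add"`); the branches do not share
depthwise kernels; per-level filter counts follow the standard
doubling-per-level convention. Batch statistics are computed per sample
over the spatial positions (running averages serve evaluation); with
mini-batches assembled by gradient accumulation this makes the training
loss independent of how a batch is split, at the cost of noisier statistics
than cross-batch normalisation.

Inputs are normalised by fixed affine maps (SUV / 5; (HU + 1000)/1500) so
both channels are O(1); the network itself treats inputs as-is, which keeps
the analytic zero-input anchor (untrained net, zero biases, output exactly
0.5) testable.

## The 3D networks

The refinement V-Net has four encoder blocks of 16/32/64/128 filters with
3x3x3 kernels and ReLU activations. The first block works at full patch
resolution and each subsequent block begins with a stride-2 convolution;
three upsampling blocks (nearest-neighbour upsampling, convolution, skip
concatenation, residual stage) restore the input resolution, so a
stated count of "four downsampling blocks and three upsampling blocks" is
realised with three actual resolution halvings and output cubes that match
input cubes -- the only reading under which patch edges of 32 are usable.
Patch edges are region-specific (32 head-neck, 64 chest, 96
abdomen-pelvis), reflecting typical lesion sizes per region; each edge must
be divisible by 8.

## Training losses

The 2D loss combines a soft Dice term with a class-frequency-weighted
binary cross-entropy,

$$L_{2D} = \Big[1 - \frac{2|P \cap T|}{|P| + |T|}\Big] +
\frac{1}{|V|}\sum_{v}-\Big[w\, y_v \log \hat y_v + (1 - y_v)\log(1 - \hat y_v)\Big],
\qquad w = \frac{|V|}{\sum_v y_v},$$

with soft cardinalities ($|P| = \sum \hat y_v$, $|P \cap T| = \sum y_v \hat
y_v$). The printed form of the weighted cross-entropy in the source
material is internally inconsistent as typeset (the weight placement makes
the negative term's factor negative whenever foreground is rare), so the
package implements the standard inverse-frequency weighting above and
additionally exposes the literal printed expression behind
`weighted_bce_term(..., form = "printed")` for comparison only. The 3D loss
adds a sensitivity term and a mean absolute error to the Dice term,

$$L_{3D} = \Big[1 - \frac{2|P \cap T|}{|P|+|T|}\Big] +
\Big[1 - \frac{|P \cap T|}{|T|}\Big] + \frac{1}{|V|}\sum_v |y_v - \hat y_v|,$$

penalising false negatives and discouraging probabilities from piling up
near 0.5. The MAE is voxel-mean (the $1/|V|$ prefactor), every ratio term
carries a smoothing epsilon of 1e-6 in numerator and denominator -- which
also yields the empty-set conventions (both-empty Dice term 0, empty-target
sensitivity term 0) -- and probabilities are clipped to $[10^{-7},
1-10^{-7}]$ inside logarithms. Evaluation metrics use the complementary
conventions: the Dice *score* of two empty masks is 1, and sensitivity
against an empty truth is reported as 1 with an `empty_truth` flag, so both
stay total functions.

## Anatomy detectors

All three detectors are deterministic threshold-and-morphology procedures:

* **Brain**: threshold PET at SUV 2.5, 26-connected components, return the
  most superior component of at least 500 mL (the minimal plausible brain
  volume; bladder and heart hotspots are an order of magnitude smaller).
  The threshold is configurable; 2.5 sits well above hepatic and blood-pool
  uptake and below grey-matter uptake.
* **Liver**: inside a window 100-500 mm inferior to the brain bounding box
  restricted to the patient-right half, threshold PET at SUV 1.0 (normal
  hepatic uptake), fill 3D holes, erode with a discretised sphere of radius
  8 mm (4 voxels), and among surviving components whose center of mass lies
  in the patient-right third of the x axis return the largest ("highest" is
  read as largest-volume; ties break toward the more superior component).
  The "left third of the sagittal axis" phrasing of the source material is
  resolved against patient anatomy -- display-left is patient-right, where
  the liver sits -- and a `side` switch covers situs-inversus inputs.
* **Lungs**: threshold CT below -300 HU, keep the 8 largest 3D components,
  remove per-axial-slice 2D regions touching the slice border (this deletes
  the air surrounding the patient), erode with a 3x3x3 box (the smallest
  symmetric element that cuts airway leakage; configurable), keep the two
  largest survivors and return their combined (volume-weighted) center of
  mass. A combined single landmark, rather than two per-lung points, is
  what the region partition consumes.

The body is split at two axial planes: the top of the lungs bounding box
and the liver center-of-mass plane. Exact plane definitions are not
prescribed by the source material; these two are deterministic, robust to
partial lung/liver segmentations, and exposed in the configuration.
Connectivity is 26-neighbourhood in 3D and 8-neighbourhood in 2D slice
operations throughout.

## Cascade details

The orientation-averaged 2D probability volume is thresholded at 0.5 (ties
positive) before component labeling; each component inherits the region of
its rounded centroid. Components whose bounding box fits the region's patch
edge get one centred cube; larger components are covered by a tiling with
50% overlap; overlapping patch predictions are averaged, voxels outside all
patches get probability 0. Fusion averages the 2D and 3D *probability*
volumes (not hard masks -- the phrase "averaging the tumor masks" is
ambiguous; soft averaging dominates hard on the training set per the source
material's own experiments and makes the fusion threshold meaningful) and
thresholds at 0.5 with ties positive. If landmark detection fails, the
pipeline degrades to a single whole-volume CHEST region with a warning
rather than refusing to run.

## The phantom

`generate_phantom()` renders a seeded digital whole-body study: an
elliptical soft-tissue cylinder (40 HU, SUV 0.7) in air, a 523 mL SUV-6
brain sphere, two 268 mL air lungs (-700 HU, SUV 0.3), a 1470 mL SUV-2
liver on the patient-right side, SUV-5 heart and SUV-8 bladder hotspots,
and ellipsoidal tumors with uptake drawn from SUV 3-10. Defaults: a
220x112x128 grid at 2 mm, three tumors with semi-axes 4-10 mm placed
uniformly across the three regions (rejecting overlap with the brain or
each other), additive Gaussian noise of 0.1 SUV and 15 HU. The tumor size
range was chosen so that lesions remain geometrically smaller than every
physiological hotspot (the bladder, at 24 mm radius, is the smallest),
since shape and size are the only cues a translation-equivariant network
can use to separate lesions from organs in a phantom whose uptake values
overlap -- as they do in real scans. Organs are hard-boundary ellipsoids
with no partial-volume blur, respiratory motion or scanner point-spread
function, so passing tests demonstrate the pipeline's plumbing, losses and
learnability on idealised contrast, not clinical performance.

## Desk-scale study configuration

The canonical training plans encode the published schedules exactly
(RMSProp, 25 epochs, batch 16, 1e-5 halved every 3 epochs after 13, for
2D; Adam, 100 epochs, batch 4, 1e-4 then 1e-4/2 then 1e-4/4 at epochs
50/75, for 3D; `lr_at()` is pure arithmetic and unit-tested at every
epoch). Those plans assume thousands of scans. The package's own
reproducible study -- what the test suite and `scripts/acceptance.R` run --
is deliberately small so it completes on one CPU in minutes:

* data: 8 phantoms (seeds 1-8, three tumors each) for training; 20 held-out
  phantoms (seeds 101-120) whose tumor counts cycle through 1-6, so that
  population statistics such as the TMTV rank correlation have real dynamic
  range (per-lesion size, uptake and noise follow the generator defaults);
* 2D: depth 3, 8 base filters, ~200 rebalanced slices (10% tumor-free),
  6 epochs of RMSProp at a constant 1e-3, batch 4;
* 3D: one shared V-Net with 4/8/16/32 filters on ~50 component-centred
  32-voxel patches (half tumor-free), 45 epochs of Adam at 3e-4 dropped to
  1e-4 for the final third (the late drop settles the probability
  calibration around the 0.5 threshold), batch 2, with a positive-first
  curriculum (below; the first 45% of epochs see only tumor-containing
  patches), applied to all three regions at inference -- the architecture
  supports per-region models; at this scale separate training triples cost
  for no measurable benefit;
* evaluation: landmark recovery, held-out slice/patch Dice, and the
  TMTV/SUVmax agreement between the cascade and the phantom ground truth
  across the 20 held-out phantoms (the standalone study script,
  `scripts/acceptance.R`, evaluates a 10-phantom draw from the same
  population so a complete from-scratch run stays short).

The higher constant learning rates compensate for the few hundred optimizer
steps available at this scale; the published schedules remain the defaults
for full-scale runs.

**Curriculum for the 3D loss.** All three terms of $L_{3D}$ reach the
logits through the sigmoid derivative $\hat y(1-\hat y)$, so a V-Net pushed
to near-zero output early in training receives vanishing gradients and dies
-- and with half the patches tumor-free, the homogeneous "push everything
down" signal dominates exactly that way at desk scale (the published
full-scale recipe does not face this: its patches come from detected
components). `train_3d()` therefore optionally front-loads tumor-containing
patches (`curriculum = "positives_first"`, the desk-scale default):
positive patches alone for the first segment of training, then the full
1:1 mixture with stratified batches -- positives and negatives interleaved
so every batch carries tumor signal. Training on the plain shuffled mixture
from scratch is left available (`curriculum = "mixed"`).

## Numerical choices

* Smoothing epsilon 1e-6 on all ratio terms; probability clipping 1e-7.
* He initialisation; biases (and batch-norm shifts) start at zero, which
  fixes the zero-input output at exactly 0.5 -- a cheap structural test.
* Binarisation and fusion use >= so exact-0.5 ties are reproducibly
  positive; component labeling is scan-ordered, so ids are deterministic.
* Training runs in double precision with gradient accumulation;
  slice inference runs through a fused single-precision path with
  evaluation-mode batch norm folded into the pointwise weights (it agrees
  with the double path to ~1e-6, far below the 0.5 decision threshold, and
  is itself deterministic).
* Resampling aligns voxel centers over the shared physical extent and
  clamps at edges; at the target spacing it is the identity, so the
  operation is idempotent.

## Known limitations

* The phantom's organs sit at canonical positions and its tumors are
  ellipsoids; no partial-volume effect, motion, or inter-scanner
  variability is simulated. Desk-scale Dice values (~0.5-0.7) reflect tiny
  networks and minutes of training, not the method's ceiling.
* The DICOM reader handles the common PET/CT export layout only; unusual
  transfer syntaxes or multi-frame files must be converted to NIfTI first.
* SUV is body-weight normalised; lean-body-mass or BSA variants are not
  implemented.
* The lungs landmark is a single combined center of mass; per-lung
  landmarks and skeletal landmarking are out of scope.
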