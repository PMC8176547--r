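---
title: "Grid-division feature fusion for leaf classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-division feature fusion for leaf classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafgrid)
```

## The problem and the model

Leaf benchmarks (Flavia, Swedish, Folio and relatives) photograph a single
leaf on a uniform monochrome, red or white background, one directory per
species. Whole-image deep features discard where on the blade a cue sits;
many species differ precisely in localized structure — the base, the apex,
the margin serration. `leafgrid` classifies such images by *dividing* each
one into an n x n grid and describing every tile separately before a single
classifier sees anything:

1. **Background cropping.** Grayscale conversion
   (gray = 0.2989 R + 0.5870 G + 0.1140 B), max–min normalization to
   [0, 1], thresholding (foreground strictly below T), hole filling,
   erosion by a disk, largest-component selection, and a crop to the
   object's bounding box.
2. **Division.** The crop is split into n x n contiguous tiles; each tile
   is resized to the backbone input size (default 224 x 224) by bilinear
   interpolation.
3. **Per-tile deep features.** Every tile passes through a backbone
   feature extractor that returns a fixed 1,000-dimensional vector — in
   production, the class-score layer of a pretrained convolutional network
   such as ResNet101 or DenseNet201.
4. **Per-tile PCA.** For each (backbone, tile-position) pair, a PCA fitted
   on training data keeps the top k components ("effective features").
5. **Fusion + z-score.** The reduced blocks are concatenated
   backbone-major, tiles row-major — fused dimension is always
   n² × Σ_backbones k — and standardized per column with training-set
   statistics.
6. **Classification.** A one-vs-all SVM with the quadratic kernel
   k(x, y) = (γ⟨x, y⟩ + c₀)², evaluated by stratified 10-fold
   cross-validation; the report carries pooled accuracy and the confusion
   matrix.

With n = 2, two backbones and k = 30 the fused vector has
4 × 2 × 30 = 240 dimensions; with one backbone, 120:

```{r fused-dim}
fusedDim(fusionSpec(2, c("resnet101", "densenet201"), 30))
fusedDim(fusionSpec(2, "resnet101", 30))
```

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n` | 2 | grid order; 2–5 are the studied sizes, and 2–3 usually suffice |
| `targetSize` | 224 x 224 px | tile size after bilinear resizing |
| `kPerTile` | 30 | PCA components kept per (backbone, tile) block |
| `erosionRadius` | 1 px | Euclidean-disk radius of the mask cleanup erosion |
| `minObjectFraction` | 0.001 | smallest mask fraction accepted as a leaf |
| `gamma` | 1/fused dim | quadratic-kernel scale |
| `coef0` | 1 | quadratic-kernel offset |
| `C` | 1 | soft-margin box constraint |
| `folds` | 10 | cross-validation folds, stratified |

The kernel defaults (C = 1, c₀ = 1, γ = 1/dim) are the common "quadratic
SVM" preset of mainstream toolboxes; nothing here is tuned per dataset,
and all three are exposed in `kernelSpec()`.

## Design choices where the design was open

**Thresholding.** "The best threshold" is realized as Otsu's
between-class-variance maximization over a 256-bin histogram — a standard,
deterministic choice — with a `fixed` mode as override. Foreground is the
set of pixels *strictly below* T, i.e. the leaf is assumed darker than the
background; `invert = TRUE` flips this for dark-background collections.

**Morphological cleanup.** The structuring element is a Euclidean disk
{(x, y): x² + y² ≤ r²} of radius 1 by default (mild boundary cleanup
only); "select objects" is implemented as keep-the-largest 8-connected
component, with `minObjectFraction` guarding against a speckle winning.
Note that `EBImage::bwlabel()` is 4-connected, so the package merges
diagonal-touching labels itself.

**Remainder rule.** When H or W is not divisible by n, the ceil-sized
bands come first (225 → 113, 112). The rule is arbitrary but fixed, so
feature files are reproducible across machines.

**Resize convention.** Bilinear with half-pixel centers
(align-corners-false): output sample i maps to source coordinate
(i + 0.5)·scale − 0.5. This is the dominant convention of modern imaging
stacks; `EBImage::resize()` implements it exactly, which the tile tests
verify against direct evaluation of the interpolation weights. Tiles are
resized independently and anisotropically, so non-square tiles incur
aspect distortion — a property of the grid approach, not a bug.

**Box coordinates.** Bounding boxes are 1-based and inclusive on both
ends — the R and Bioconductor convention (as in IRanges) — including in
the CSV exports. Users of 0-based tooling should subtract 1.

**Which layer is "the" feature layer.** The 1,000-way class-score layer is
the only 1,000-dimensional layer in both reference architectures, so the
adapter contract defaults to it. Pretrained weights and a deep-learning
runtime are not bundled: `pretrainedBackbone(name, extractor = ...)`
accepts any function mapping a tile to its feature vector, and the
deterministic `standinBackbone()` (block-mean pooling to an 8 x 8 x 3
grid followed by a fixed seeded random projection to 1,000 dimensions)
fulfils the same contract for tests and examples. The stand-in is linear
and pure; it is a test fixture, not a CNN surrogate for accuracy claims.

**PCA.** Computed by SVD of the centered training matrix (`prcomp`), never
by forming the covariance matrix; the covariance eigendecomposition
appears only as an independent oracle in the tests. The
largest-magnitude loading of each component is forced positive so fitted
models are identical across LAPACK builds. Explained variances use the
n − 1 denominator throughout.

**Leakage control.** Whether PCA and z-score statistics were fitted inside
or outside the evaluation folds is a protocol choice with real
consequences at small n. The default fits *both strictly on each fold's
training portion*. `paperMode = TRUE` fits them once on all data — a
plausible reading of how such pipelines are often run, reproducible here
without being endorsed; the flag is echoed in every report.

**Degenerate inputs.** Constant images fail max–min normalization (and
Otsu) with a degenerate-image error; empty or speckle-only masks raise a
no-object error naming the failing sample; constant fused columns are
mapped to zero by the z-score epsilon guard (1e-8) rather than NaN;
multiclass decision ties break to the lowest class index; classes smaller
than the fold count reduce the fold count with a recorded warning.

**Solver.** Each one-vs-all binary machine is solved by the libsvm SMO
implementation in `e1071` (KKT tolerance 1e-3). The package's contract is
the dual-feasibility invariants the tests enforce on every fit —
0 ≤ α ≤ C, Σαᵢyᵢ ≈ 0, unit margins at support vectors in the separable
case, and a dual objective matching a brute-force grid solve on a 6-point
problem — not a bespoke solver. One caveat found while testing: "adding a
duplicated, consistently-labeled sample never decreases training
accuracy" is not a theorem for soft margins on overlapping classes (the
duplicate re-weights the loss), so the suite asserts it in the separable
regime where the margin solution is stable.

## What the synthetic generator emulates — and what it does not

`generateLeafDataset()` renders one leaf per image on a uniform gray
(0.85), red or white background, mirroring the benchmarks' setting. A
class is a parameter set — aspect ratio, lobe count and depth of the polar
contour r(θ) = R(1 + d·cos(mθ)), vein-texture frequency, leaf color — laid
out on deterministic, well-separated grids; images within a class jitter
those parameters by about ±10% plus random rotation and translation, all
driven by seeds derived from one master seed. Ground truth (exact
foreground mask and its box) is stored per image, which is what makes the
segmentation accuracy checks possible at all.

The generator deliberately omits: shadows and uneven illumination,
petioles, overlapping or multiple leaves, specular highlights, camera
noise, and any botanical realism in the contour. Passing the suite
therefore shows the pipeline's stages are correct and well-coupled on
images satisfying the single-dark-leaf-on-uniform-background premise; it
does not certify accuracy on photographic data, where cropping quality
and backbone choice dominate.

Leaf colors are constrained darker in grayscale than every background, so
the strict-below-threshold polarity holds by construction — the same
assumption the cropping procedure makes about the real benchmarks.

## Problem sizes and numerical tolerances in the shipped checks

The test suite exercises the full pipeline on 5 classes × 40 images of
128 × 128 px with the stand-in backbone, 2 × 2 division, k = 10 and
10-fold stratified cross-validation — small enough to run in well under a
minute per evaluation while leaving every stage nontrivial (raw blocks
are 200 × 1000; fused features 200 × 40). Under these conditions pooled
held-out accuracy exceeds 95%, label permutation drops it to chance
(20 ± 10% at 5 classes), and repeated runs reproduce reports byte for
byte. Segmentation recovers ground-truth boxes at IoU ≥ 0.9 (empirically
≥ 0.93 with every edge within 1 px, the radius-1 erosion being the only
systematic bias). PCA agrees with the covariance oracle to 1e-8 on
matrices up to 20 × 20; z-scored training columns hit mean 0 and sd 1 to
1e-8; Gram matrices are PSD to −1e-10.

## Known limitations

- Segmentation assumes exactly one leaf and a near-uniform background;
  multi-leaf scenes and strong shadows are out of scope.
- The bounding-box crop keeps background inside the box (matching the
  benchmarks' cropped appearance); `maskBackground = TRUE` zeroes it, but
  no contour features beyond the box are extracted.
- Per-dataset feature totals that are not divisible by n² × #backbones
  cannot be expressed with a single global k; `kPerTile` may vary per
  backbone but not per tile.
- The stand-in backbone's features are linear in the image; claims about
  *deep* feature quality require plugging in a real pretrained extractor.
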