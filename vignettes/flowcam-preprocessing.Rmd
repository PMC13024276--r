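---
title: "Processing imaging flow cytometry runs: cleaning, biovolume and classification"
author: "flowcamtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing imaging flow cytometry runs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowcamtools)
```

## The problem

FlowCam instruments photograph particles passing a flow cell and crop each
particle's region of interest (a *vignette*) out of the full-frame *source
image*. Vignettes are stored side by side in *collage* image files, and a
per-particle CSV records up to ~60 measured properties. Three practical
problems stand between that raw output and an analysable dataset:

1. the CSV schema differs between VisualSpreadsheet (VSP) software versions,
   so multi-campaign datasets cannot be pooled directly;
2. sample handling produces *duplicate* images of the same particle (sticky
   particles, clogging, flow/imaging mismatch) and particles outside the
   quantifiable size range, which must be flagged before annotation; and
3. biomass studies need a per-particle biovolume estimate, which the
   silhouette supports but the raw CSV does not carry for older versions.

`flowcamtools` addresses all three, writing its results as a
`LabelChecker_<run>.csv`: the unified original columns plus exactly seven
appended columns (`Preprocessing`, `PreprocessingTrue`, `LabelPredicted`,
`ProbabilityScore`, `LabelTrue`, `Biovolume`, `SurfaceArea`). The input
files are never modified. A shallow dual-input classifier (image branch +
particle-property branch) is included for label bootstrapping, together
with a synthetic run generator that makes the whole pipeline testable
without instrument data.

## Dialect unification

The per-version header spellings are not standardised anywhere public, so
the mapping from version-specific aliases to canonical CamelCase names
(`AbdArea`, `AbdDiameter`, `CaptureX`, ...) ships as an editable table,
`inst/extdata/vsp_dialects.csv`. `detectDialect()` scores each known
dialect by Jaccard overlap with the observed header and keeps unknown
columns verbatim (with a warning) rather than failing: a header the table
does not know is an annotation surface for the user, not an error. Columns
are documented in micrometre units where VSP reports them (sizes) and
0–255 intensity units otherwise.

## Duplicate detection

A later record *j* is linked to an earlier record *i* when all proximity
gates and at least one similarity gate hold:

* captured within **5 source images** of each other (inclusive),
* source-frame x-positions **less than 100 px** apart (exclusive),
* bounding-box intersection-over-union **≥ 30 %**, *or*
* cosine similarity of the 13 particle properties (edge gradient,
  ABD area and diameter, average blue/green/red, intensity, length, width,
  perimeter, roughness, sigma intensity, transparency) **≥ 99.9 %**.

The combination is read as (1) AND (2) AND ((3) OR (4)): the first two are
proximity preconditions, the last two alternative evidence of sameness.
Linked records form chains; each chain keeps its earliest member (first
capture, ordered by source image then id) and flags the rest `duplicate`.
Feature vectors are compared raw — cosine similarity is scale-invariant —
and a record with missing feature columns falls back to the IoU gate with
a warning. Flags are invariant to row permutation because candidates are
ordered by (source image, id) before linking.

The threshold defaults are deliberately conservative; on real data the
detector is expected to over-flag slightly, which is the cheaper error:
reviewing a small flagged subset beats hunting duplicates in the full set.

## Size threshold

`applySizeThreshold()` labels values strictly below the lower bound
`small` and strictly above the upper bound `large`, on any size-like
canonical column (typically `AbdDiameter` or `Length`, in µm). Typical
settings are a lower limit of 8 µm on ABD diameter for a 10× objective
run, or 30 µm on length for a 4× objective run. Note that ABD diameter
under-states thin elongated particles (it is the diameter of the
equal-area circle), so filament-rich samples are better thresholded on
`Length`. The duplicate flag takes precedence when both apply.

## Biovolume and surface area

Both estimators start from a binary silhouette. When VSP has exported
binary masks (version ≥ 4) those are preferred; otherwise `binarize()`
computes one: Otsu threshold, hole filling, largest connected component.
The default polarity in the run-level driver is `"border"` — foreground is
the side under-represented on the vignette border — because a particle
snugly cropped by its bounding box can occupy the majority of the pixels,
which breaks the classic smaller-pixel-count heuristic (still available as
`"auto"`).

Routing between the two estimators follows two shape criteria computed by
`shapeStats()`: the **solid of revolution** (SOR) is used when the
convex-hull-to-area ratio is below 1.2, or when eccentricity is below 0.8
and the ratio of equivalent circular diameter to major-axis length is
above 0.8 — i.e. for roughly circular or moderately elongated solid
shapes. Everything else (stars, branched filaments) goes to the
**distance map** (DM) estimator.

* SOR: the mask is rotated so the covariance-ellipse major axis is
  horizontal; each column's chord of width $w_i$ is revolved about the
  axis, $V = \sum_i \frac{\pi}{4} w_i^2$, and the surface is the
  conical-frustum lateral sum with central-difference slopes plus end
  caps. Chord widths are taken from the bilinearly interpolated gray mass
  per column rather than a re-thresholded mask, which preserves silhouette
  area under rotation.
* DM: $V = 4 \sum_p d_p$ over the Euclidean distance map (exact in the
  continuum for a sphere: $\int 4(R - r)\,dA = \frac{4}{3}\pi R^3$), and
  $SA = 4 A$ by Cauchy's mean-projection identity (exact for spheres, an
  approximation elsewhere). Both constants are exposed in
  `biovolumeConfig()`.

Pixel results scale to micrometres by the VSP calibration constant $c$
(µm/px): volume by $c^3$, surface by $c^2$. Runs without a calibration
column fall back to pixel units and say so (`unitsCalibrated = FALSE`).

### Numerical conventions

* Rasterization: a pixel is foreground iff its **center** lies inside the
  continuum shape. Under this convention a disk of radius $R$ px has pixel
  area $\pi R^2 + O(R^{2/3})$, and both estimators converge on the sphere
  closed forms with error decreasing in $R$ (≈ +1.3 % for DM and −0.1 %
  for SOR at $R = 50$; about +11 % / +2 % at $R = 10$, so biovolumes of
  particles only a few pixels wide should be treated as indicative).
* Eccentricity is $\sqrt{1 - \lambda_2/\lambda_1}$ from the eigenvalues of
  the foreground coordinate covariance, with the $1/12$ unit-square pixel
  term added to the diagonal; this keeps eccentricity strictly below 1
  even for one-pixel-wide lines. The major axis is $4\sqrt{\lambda_1}$
  (the same-second-moment ellipse). An axis-ratio definition
  ($\sqrt{1-(b/a)^2}$ on half-axes) would be equivalent here because both
  derive from the same ellipse.
* The convex hull is taken over pixel **corners**, not centers, so the
  hull area can never undercut the pixel-count area (a center hull of a
  single pixel has zero area, which would invert the hull-ratio gate).
* The distance map pads the mask with a one-pixel background ring, so
  border-touching particles get finite distances.
* Rotated masks are re-rasterized with a mass-preserving threshold (keep
  the $N$ strongest interpolated pixels, $N$ = gray mass). A fixed 0.5
  threshold locks onto the pixel lattice at angles near 45° and can
  inflate a thin rectangle's area by ~6 %, which would break rotation
  invariance through no fault of the estimator.

## The classifier

The optional model is deliberately shallow — the goal is label
bootstrapping on an ordinary CPU, not state-of-the-art recognition. Two
branches are concatenated:

* image branch: vignettes resized to 224 × 224, a fixed 2 × 2
  average-pooling stem, then three 3 × 3 convolution blocks
  (8/16/32 filters, relu, max pooling; the first two blocks use stride 2),
  flattened into a 64-unit dense layer;
* property branch: the standardised numeric particle properties through
  64- and 32-unit dense layers with relu and dropout.

The concatenation passes through a final 64-unit dense layer with dropout
and a softmax. There are no augmentation layers. Training uses batch
size 22, Adam (10⁻³), categorical cross-entropy, an 80/20 stratified
validation split, parameter checkpoints only when the validation loss
improves, and early stopping with a patience of 6 epochs (cap 25). All
widths, strides and rates are `trainConfig()` parameters; the defaults
were chosen so the bundled 3-class demonstration trains in minutes on one
core. Dropout (0.3) and the Adam step size are unstated in the upstream
description of this model family and are documented here as package
defaults.

Before training, the published table filters are applied in order:
preprocessing-flagged records out, unlabelled rows out, non-numeric and
date/time columns out, constant columns out, classes with fewer than five
images out. Features are standardised with training statistics that are
stored with the model and re-applied at prediction time. Prediction fills
`LabelPredicted` and `ProbabilityScore` for unflagged rows only and never
touches `LabelTrue` or the validated flags.

## The synthetic run generator

`generateRun()` emulates what the tests need from a FlowCam run: disk,
rod, filament (dilated random walk) and star silhouettes — disks and rods
exercise the SOR route, filaments and spiky stars the DM route — rendered
dark-on-light with additive Gaussian noise, packed into collage mosaics,
measured into a property CSV (all features computed from the rendered
masks, so generator and estimators share no code path), with classes
separated by per-class intensity Gaussians so the demo classifier can
learn them. Duplicate pairs are injected as near-copies in nearby frames
at x-offsets under 100 px; near-miss fixtures violate exactly one chosen
gate. The generator *enforces* its ground truth: records listed as
non-duplicates are laid out so at least one gate fails for every candidate
pair (re-drawing positions when necessary), and injected pairs are
verified to pass — the properties the truth asserts are guaranteed, not
merely probable, which is what makes exact-count assertions meaningful.

What it does **not** emulate: optical blur and point-spread functions,
uneven illumination, colour, touching/overlapping particles, colonies and
chains, or the heavy class imbalance of field data. Tests passing on these
runs therefore validate the pipeline's mechanics (formats, gates,
estimator identities, training plumbing), not field-data classification
performance.

Default conditions: 120 particles per run at 0.595 µm/px (a typical 10×
objective calibration), sizes 10–60 µm, 6 particles per source frame on a
1800 × 900 px frame; problem sizes in the test-suite and in
`scripts/acceptance.R` (500-particle runs for the duplicate oracle,
600 images across 3 classes for the classifier demonstration) keep a full
run in the minutes range on one core.

## Known limitations

* Per-version header aliases are best-effort; the mapping table is the
  explicit assumption surface and is meant to be edited.
* The VSP < v4 binarization procedure is not public; Otsu thresholding
  with hole filling is this package's documented substitute.
* The DM surface area is exact only for spheres; for concave shapes it is
  a projected-area proxy.
* Air-bubble detection is a reserved flag value (`bubble`) with no
  algorithm behind it — the upstream feature is an undocumented trial and
  ships disabled.
* Biovolume of particles smaller than ~10 px across carries double-digit
  discretization error; set a size threshold accordingly.
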