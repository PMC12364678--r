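---
title: "Methods: automated CPS scoring on IHC images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated CPS scoring on IHC images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science: the scoring
model and its assumptions, the parameters that matter, what the synthetic
data can and cannot stand in for, and the numerical and design choices
made where the design was genuinely open.

## The score

The Combined Positive Score for a PD-L1 IHC slide is

$$\mathrm{CPS} \;=\; \frac{N_{\text{tumor}}^{+} + N_{\text{immune}}^{+}}
                          {N_{\text{tumor}}^{+} + N_{\text{tumor}}^{-}}
                     \times 100,$$

where the denominator counts viable tumor cells only (necrotic regions are
excluded) and PD-L1$^+$ immune cells count only when they lie within tumor
nests or in stroma within 0.5 mm of tumor. The binary clinical call is
positive iff CPS $\ge 1$. `computeCps()` keeps the count ratio as exact
integers alongside the numeric value, so two pipelines that count the same
cells report bit-identical scores; the reported value is capped at 100 by
default (`cap_at_100`), a clinical reporting convention — the raw ratio can
exceed 100 when immune cells are abundant, and the cap is configurable
because the formula itself is uncapped. A denominator below
`min_tumor_cells = 100` flags `insufficient_tumor_cells` without
suppressing the number: evaluability is a reviewer decision, so the engine
flags rather than refuses. A zero denominator is `no_tumor_cells` /
`not_evaluable`.

## Pipeline and assumptions

Scoring proceeds in five stages, with no manual step:

1. **Tissue localization.** The slide is downsampled by
   `mask_downsample = 32` (20× analysis scale to 0.625× localization
   scale), converted to grayscale (Rec. 601 luma) and thresholded with
   Otsu's method; tissue is the dark side on brightfield. Components under
   `min_object_px = 4` mask pixels are dropped. This is an efficiency
   pre-filter: its only job is to keep background tiles out of the models.
2. **Tiling.** Non-overlapping `patch_px` tiles (default 256 px) in
   row-major order; edge remainders are dropped, not padded — padding
   would fabricate tissue, and the non-overlap contract keeps counting
   unambiguous. Tiles keep their tissue fraction from the
   nearest-neighbor-upsampled mask (exactness and speed over smoothness);
   tiles under `min_tissue_fraction = 0.10` are rejected. The 10% cutoff
   is this package's choice: scoring near-empty tiles wastes model calls
   and invites background false positives.
3. **Tumor-region consensus.** The patch classifier labels each tissue
   tile tumor/non-tumor; the segmenter runs *only* on classifier-positive
   tiles; the gate passes a tile iff the classifier said tumor *and* the
   segmented tumor fraction is at least `min_tumor_fraction` (default
   0.01, i.e. ~655 px of a 256² tile) *and* at least one tumor pixel
   exists. An any-pixel veto alone is noise-fragile — a single
   false-positive pixel would open the gate — hence the 1% default; 0
   restores the pure any-pixel veto.
4. **Cell detection.** The detector runs on tissue tiles intersecting the
   0.5 mm proximity zone of the gated tumor region (a superset of the
   consensus tiles). Tumor-class detections are counted only when their
   box center lies inside the gated tumor mask; immune detections inside
   the mask count unconditionally, and outside ones are kept iff their
   center is within `round(radius_um / mpp)` pixels of tumor
   (1053 px at 0.475 µm/px), computed with one distance transform of the
   mask complement — equivalent to dilating the mask by the radius but
   O(image) rather than O(cells × pixels).
5. **Aggregation** into exact counts, the CPS and the call, with full
   provenance (per-tile gate decisions, detections, stage counts,
   thresholds echoed into the report).

Two rules in the source method pull in opposite directions: detection is
described per tumor-containing patch, while the immune criterion is a
spatial 0.5 mm rule that does not care about patch boundaries. This
implementation follows the spatial rule — immune cells in wholly
non-tumor tiles within 0.5 mm of tumor are countable — and keeps the
efficiency property where it matters: the *segmenter* (the expensive
pixel model) runs only on classifier-positive tiles. Detections are
per-tile with no cross-tile stitching, so a cell straddling a tile
boundary can, with trained models, be detected twice; this is a known,
documented double-count source inherent to per-patch pipelines.

## The three models

The environment provides no deep-learning framework, so the three
trainable stages are compact classical image models with the same
contracts (train/validation/test splits, augmentation, deterministic
seeded inference, identical interfaces to the scoring engine):

* **Patch classifier** (`buildPatchClassifier`): a random forest over a
  22-dimensional pooled descriptor per patch — channel means/SDs and
  quantiles, DAB-brown and hematoxylin-blue stain-response fractions,
  violet tint, edge density. Splits 6:2:2 at patch level by default
  (slide-level splitting is available and recommended against leakage;
  patch-level is the default to match the upstream protocol, which is
  silent on leakage control). Augmentation: flips, 90° rotations
  (multiples of 90° only, so labels transform exactly without
  interpolation noise), Gaussian blur with σ ∈ [0, 1.5].
* **Tumor segmenter** (`buildTumorSegmenter`): per-pixel random forest
  over raw RGB plus Gaussian-smoothed RGB at σ = 2 and 4 (local context),
  trained on a stratified pixel sample from 7:2:1-split patches with
  flip/rotation/HSV augmentation (hue ±0.05, saturation/value ±20% —
  small enough to preserve brown-vs-blue stain identity, hence every
  label). Training patches are randomly cropped by `crop_factor = 2`,
  keeping the native-resolution-then-crop training contract at desk
  scale. An auxiliary patch-level has-tumor head is trained alongside as
  a diagnostic; only the pixel head is used at inference. Necrosis and
  glands are *non-tumor*, not separate classes.
* **Cell detector** (`buildCellDetector`): anchor-free proposals from
  stain-positive connected components (blueness > 0.18 or brownness >
  0.25, area 4–600 px), scored by a random forest over shape and
  inner/rim color features into three cell classes plus background;
  confidence is the class probability, post-processing is a confidence
  filter (0.25) then per-class greedy NMS at IoU 0.45 — conventional
  one-stage values, both exposed in `runConfig`. Training labels come
  from greedy IoU ≥ 0.5 matching against ground-truth boxes; mosaic
  (4-tile composites) and mixup (convex blends, box union) enrich the
  training set with exact box bookkeeping.

## Synthetic slides: what they emulate, and what they do not

`generateSlide` renders a 20× (0.475 µm/px) IHC-like field: a tissue blob
of pink stroma, a violet-tinted tumor bed covering `tumor_region_fraction`
of the tissue, elliptical cells — PD-L1$^-$ tumor cells as blue ellipses
(radii 3.5–5 px), PD-L1$^+$ tumor cells with an added brown membrane ring
(1.5 px), PD-L1$^+$ immune cells as smaller brown discs (1.5–2.5 px, a
learnable morphological contrast) — plus textured brown-gray necrosis
carved out of the tumor mask and ring-shaped glands outside it as
distractors. An optional fraction of positive cells (`weak_fraction`,
default 0.05) renders at reduced chroma, emulating weak staining, a known
source of scoring inconsistency. Additive Gaussian noise
(`noise_sd = 0.02`) and per-cell color jitter (0.02) roughen the palette.
Cells are placed by rejection sampling with pairwise spacing, so a
requested count that cannot fit raises a capacity error naming the
limiting class. Everything is seeded: identical parameters give
bit-identical slides.

Ground truth is exact by construction: the tumor mask, every cell's
half-open box (`[ceiling(c - R), floor(c + R) + 1)`, the tight rendered
extent), its class and region tag, the per-class tallies, and the CPS they
imply. A cell belongs to the unique patch containing its center pixel
(half-open grid) — the source method never states its rule for cells
fragmented across patches, and the center rule is chosen here because it
makes per-patch annotations partition the cell list exactly.

What passing tests on this generator demonstrate: the *pipeline logic* —
gating, region assignment, the proximity rule, counting, the formula, the
agreement statistics — is exact, and the model contracts are learnable
from images alone. What they do not demonstrate: performance on real
histology. The generator has none of the hard parts of tissue — nuclear
texture, touching and overlapping cells, stain variation across
laboratories, mucin, folds, blur. Real-data figures (per-model metrics in
the high 90s, cohort kappas near 0.78) require real cohorts and are out
of scope here.

## Numerical choices

* **Otsu**: exhaustive maximization of the between-class variance over the
  256-bin histogram, classes `<= t` / `> t`, ties broken toward the lower
  threshold. Under inversion the objective is symmetric but the argmax can
  sit anywhere on a zero-mass plateau, so the tests assert objective-value
  symmetry, not threshold equality.
* **Dice**: empty-vs-empty defined as 1.0 — a perfect negative stays
  perfect. Held-out segmenter dice is reported *pooled* over test pixels
  (the conventional single test-set dice), with the unweighted per-patch
  mean alongside: per-patch dice is degenerate on patches whose true tumor
  area is a few pixels, where one boundary pixel flips the value between 1
  and 0, making a small-sample mean needlessly noisy.
* **AP**: all-point interpolated area under the precision-recall curve
  (not 11-point), greedy confidence-ordered matching, ties by input
  order, one truth per prediction; classes without ground truth are
  reported absent, not 0.
* **Kappa interpretation bins**: the clinical scale's ranges overlap at
  their boundaries, so the package fixes half-open bins
  $[0, 0.2), [0.2, 0.4), [0.4, 0.6), [0.6, 0.8), [0.8, 1]$, negative
  values labeled "poor".
* **Oracle recovery runs** use `tissue_filter = "none"` and
  `min_tumor_fraction = 0`: with noise-free oracle masks the any-pixel
  veto is exact, whereas the noise-robust defaults (Otsu pre-filter, 1%
  gate) can drop a boundary sliver that contains a cell center. The
  defaults are for model-driven runs; the oracle configuration isolates
  the engine's arithmetic.
* **Determinism**: all randomness flows through explicit seeds
  (`withr::with_seed`); scoring reports exclude wall times
  (kept in a separate `timings.json`) so reruns are byte-identical.

## Problem sizes

The test suite and the acceptance script run at desk scale on one CPU:
training cohorts of 6 slides at 640² px, classifier patches at 64 px,
segmenter/detector patches at 128 px, ~30k training pixels for the
segmenter, 150–200 forest trees; recovery and gating cohorts of 20 slides
at 512–640² px with per-slide cell counts around 110–200, chosen so the
denominator matches the evaluability convention while placement stays
comfortably below the packing limit of the canvas. These sizes are the
package's choice of a regime where forests separate the classes cleanly
and the whole suite runs in minutes.

## Known limitations

* No cross-tile stitching of detections (double-count source at tile
  boundaries with trained models; the ground-truth oracle assigns each
  cell to one tile and is exact).
* The patch classifier defaults to patch-level splitting, which leaks
  slide context between splits; use `mode = "slide"` for honest
  generalization estimates on multi-slide datasets.
* Forest models carry no notion of the unfrozen-layer / transfer-learning
  machinery of CNN backbones; the corresponding knobs are forest size and
  feature configuration.
* The synthetic renderer snaps `tissue_fraction` above ~0.7 to
  edge-to-edge tissue (the largest inscribable ellipse covers ~72% of the
  canvas).
* TPS and multi-threshold CPS strata (≥ 5, ≥ 10) are not implemented; the
  latter are trivially derived from the reported CPS.
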