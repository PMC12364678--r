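# PDL1cps

Automated PD-L1 Combined Positive Score (CPS) estimation from
immunohistochemistry (IHC) images of gastric cancer tissue.

## The problem

PD-L1 CPS guides whether a gastric cancer patient is offered immune
checkpoint inhibitor therapy, but manual CPS reading suffers from
substantial inter-observer variability. For a 22C3-stained slide,

```
CPS = (PD-L1+ tumor cells + PD-L1+ immune cells)
      ─────────────────────────────────────────── × 100
      (PD-L1+ tumor cells + PD-L1− tumor cells)
```

with the clinical positivity cutoff CPS ≥ 1. The denominator counts
*viable* tumor cells (necrotic areas excluded), and PD-L1+ immune cells
count only within tumor nests or stroma in direct spatial proximity to
tumor (a 0.5 mm radius).

`PDL1cps` implements a fully automated scoring pipeline for slides scanned
at 20× (0.475 µm/pixel):

1. **Tissue localization** — Otsu thresholding on the grayscale slide at a
   32× downsample (0.625× magnification), then tiling into non-overlapping
   256×256 patches over tissue.
2. **Tumor-region consensus** — a patch-level tumor/non-tumor classifier
   screens tiles; a pixel-level segmenter runs only on classifier-positive
   tiles; a tile enters cell counting only when *both* models agree
   (consensus gating). Gating cuts segmentation work several-fold on
   slides whose tumor occupies a small fraction of the tissue.
3. **Three-class cell detection** — one-stage detection of PD-L1+ tumor
   cells, PD-L1− tumor cells and PD-L1+ immune cells, with per-class
   non-maximum suppression.
4. **CPS engine** — region assignment by box center against the gated
   tumor mask, the 0.5 mm immune proximity rule
   (`round(500 / 0.475) = 1053` px via a distance transform), exact
   integer-ratio CPS, the cap at 100 and the ≥ 1 call.
5. **Evaluation** — classification/segmentation/detection metrics with
   bootstrap CIs, Cohen's kappa with the clinical interpretation bins, and
   a gated-vs-ungated efficiency benchmark.

Because no public WSI cohort accompanies this problem, the package ships a
first-class **synthetic slide generator** (`generateSlide`,
`generateCohort`) that renders IHC-like fields — brown-membrane PD-L1+
cells over blue counterstain, necrosis and gland distractors — with exact
ground truth (tumor mask, cell boxes/classes, true CPS), so every stage is
trainable and testable end-to-end. The three models are compact
random-forest image models sized for CPU desk scale; the pipeline accepts
any model handle that honors the classify/segment/detect contracts,
including perfect ground-truth oracles (`oracleModels`) used by the
recovery tests.

## Worked example

```r
library(PDL1cps)

sp <- synthParams(canvas_px = c(512, 512), n_tumor_pos = 40,
                  n_tumor_neg = 90, n_immune_pos = 20, seed = 42)
sl <- generateSlide(sp)
sl$truth
#> SlideGroundTruth: 48982 tumor px; cells TP=40 TN=90 IP=20; true CPS 46.154

cfg <- runConfig(patch_px = 128, tissue_filter = "none",
                 min_tissue_fraction = 0, min_tumor_fraction = 0)
sc <- scoreSlide(sl$slide, oracleModels(sl$truth), cfg)
sc$result
#> CpsResult: CPS 46.154 (60/130 x 100), status valid, call positive

sc$n_patches
#> $total: 16   $tissue: 16   $classifier_positive: 6
#> $consensus: 6   $detector: 16
```

The slide renders 130 tumor cells and 20 immune cells; scoring with
ground-truth oracle models recovers the exact ratio 60/130 × 100 = 46.154
and the positive call, and the consensus gate confines segmentation to the
6 of 16 tiles that actually contain tumor cells. Swap `oracleModels(...)`
for trained handles (`trainPatchClassifier`, `trainTumorSegmenter`,
`trainCellDetector`) to run the learned pipeline; `vignette` sources under
`vignettes/` describe the models and every threshold.

A command-line wrapper is installed at `inst/scripts/pdl1cps` with
subcommands `synth`, `tile`, `train-classifier`, `train-segmenter`,
`train-detector`, `score`, `evaluate` and `benchmark`; every run writes a
`manifest.json` (configuration, seeds, input checksums) and scoring
reports keep wall times in a separate `timings.json` so `report.json` is
byte-reproducible.

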