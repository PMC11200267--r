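---
title: "Assessing maize tassel states from UAV imagery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing maize tassel states from UAV imagery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tasselstate)
```

## The problem

In hybrid maize seed production, tassels must be removed from female rows
before pollen release (detasseling / emasculation), and the quality of that
operation has to be verified plant by plant. A low-altitude UAV survey
photographs the canopy; each plant center is in one of three states:

* **Tassel-N** — tassel removed or absent,
* **Tassel-S** — tassel formed but not yet emerged,
* **Tassel-L** — tassel fully emerged and mature.

Counting the three states per frame tells a field manager both the growth
stage and whether another detasseling pass is needed. The computational
problem is not the CNN itself (any modern detector works on a 1,024-px
crop) but everything around it: how to annotate objects with fuzzy
boundaries, how to cut a 8,192 × 5,460 frame into detector-sized blocks,
how to undo the double counting that overlapping blocks cause, and how to
score counts. This package implements that surrounding machinery, with a
controllable truth-conditioned mock detector standing in for the CNN so
the whole chain is testable end to end.

## Blocking geometry

All coordinates are 0-based with x rightward and y downward; windows are
half-open `[x0, x0 + side)`. This makes tiling algebra exact in integer
arithmetic. Three center-anchored patterns are provided, anchored on the
center because lens perspective distorts the periphery of a wide frame:

* **Pattern 1** — 2 × 2 blocks of side $b$ with mutual overlap $o$; union
  is a centered square of side $2b - o$ (1,848 px at the defaults
  $b = 1024$, $o = 200$).
* **Pattern 2** — 3 × 3 centered; union side $3b - 2o$ (2,672 px).
* **Pattern 3** — the full non-overlapping grid of
  $\lfloor W/b \rfloor \times \lfloor H/b \rfloor$ blocks (8 × 5 = 40 on
  the default frame). The leftover margin is split evenly (extra pixel to
  the right/bottom) so the grid stays centered, consistent with the
  center-privileging analysis; `anchor = "topleft"` preserves the
  alternative reading.

When a centered union cannot be placed symmetrically (odd parity), it
shifts left/up by one pixel, deterministically. A generic sliding-window
plan with inward-snapping last row/column (fixed window size, full pixel
coverage) covers everything else. With a ground sampling distance $g$
cm/px, a $W \times H$ frame covers $(Wg/100)(Hg/100)$ m² — 279.552 m²
(~280) for the default frame.

## Annotations and box standardization

Labels use the YOLO text format (`class cx cy w h`, normalized). Emerged
tassels (Tassel-L) have real boundaries and are annotated as drawn;
Tassel-N and Tassel-S lack crisp boundaries, so their boxes are replaced
by fixed squares at the same center — 140 px by default, the size the
box-size sweep identifies as a robust compromise (the sweep harness
enumerates 50–500 px in 50-px steps, then 50–300 px in 10-px steps; the
per-category optima 200/160 px are available via `optimal_target_sides()`).
Standardized boxes are clipped at image borders and the pre-clip geometry
is kept in `pre_w`/`pre_h`.

Dataset statistics report per-category and pooled box-area and
length–width-ratio moments, with the ratio defined as
$\min(w,h)/\max(w,h) \in (0,1]$ so a square scores 1.

### Cropping labels to blocks

A box is kept in a block when at least `min_visible_frac` (default 0.5) of
its area is visible there; kept boxes are translated and clipped, and the
record keeps both the clipped geometry and the full-box center
(`cx_full`, `cy_full`). One subtlety is worth stating precisely: if a
box's center lies inside a block (and the box is no larger than the
block), its visible fraction there is at least 1/4 — not 1/2 — because
both axes can clip simultaneously at a corner. Hence the guarantee "every
center-owned box survives in at least one block" holds for thresholds up
to 0.25; at the default 0.5 a box straddling a tile corner of a
non-overlapping grid can be dropped everywhere. The package evaluates
counts against *plan-evaluable* ground truth (objects surviving cropping
in ≥ 1 block, deduplicated), which keeps the comparison internally
consistent at any threshold.

## Augmentation

Five label-aware operations expand a training set: rotation, random
cropping, brightness, shadow, and chromatic adjustment. Photometric ops
never touch coordinates. Rotation maps box corners and refits the
axis-aligned hull — exact for right angles, slightly inflating for small
angles (±15°), which is recorded per derived image in the manifest.
Random cropping drops boxes below the visibility threshold and resizes
back to the input size, so object scales change by `1/frac` while the
detector input size is preserved. Because the canonical expansion (800
sources → 4,200 entries) is not an integer multiple of five, operations
are sampled uniformly with replacement to a target count; the manifest
(`derived_id, source_id, op, params_json, seed`) makes every derived
entry reproducible. Shadow is a seeded random convex quadrilateral at
configurable opacity; chroma gains default to [0.8, 1.2] — parameter
ranges chosen to be label-preserving.

## The detector contract and the mock

Detections are rows `class, cx, cy, w, h, conf, block_id` in block-local
pixels; externally produced detections (real CNN output) enter through a
6-column text importer, and a confidence screen (default 0.3) filters
them. The mock detector is *truth-conditioned*: it never looks at pixels,
but samples errors on the ground truth of each block:

* per-category miss probability at the frame center, plus a **radial
  slope** (added miss probability per 1,000 px of distance from the frame
  center) — the surrogate for perspective distortion, which degrades real
  detectors away from the center;
* Poisson false positives per block, Gaussian localization jitter,
  a row-stochastic category-confusion matrix, and a clamped Gaussian
  confidence model.

Emitted centers anchor on the full-box (plant) center carried through
label cropping, not on the clipped-box center. This is deliberate: the
annotation convention is plant-center squares, so a detector trained on
them localizes the plant even when a block boundary truncates the box.
Anchoring on clipped centers would shift edge detections by up to a
quarter box width toward neighbours, chain distinct plants inside the
merge radius, and make even a perfect detector miscount — an artifact of
bookkeeping, not of detection.

## Fusion: remapping and redundancy merging

Block-local detections are remapped by adding the block origin, then
merged **within each category** by single-linkage clustering on center
distance at a 50-px radius: clusters are connected components of the
"centers within 50 px" graph, computed by union-find. Each cluster yields
one object at the confidence-weighted mean center carrying the maximum
member confidence. Proximity (not IoU suppression) is the right notion
here because duplicates of one plant seen from two overlapping blocks have
nearly coincident centers but possibly dissimilar clipped boxes.
Detections are pre-sorted (confidence desc, then x, then y), making the
result invariant to input permutation. A one-pass greedy variant
(`method = "greedy"`) is provided; it splits chains that single linkage
joins, and the test suite pins both behaviours.

The 50-px radius presupposes that distinct plants are farther apart than
the radius — it is half the 100-px plant spacing at the default GSD.

## Metrics

**Detection level.** Matching is category-strict, greedy in confidence
order, one-to-one, at IoU ≥ 0.5 (ties on IoU broken by truth order).
Precision $TP/(TP+FP)$ and recall $TP/(TP+FN)$ follow; the "accuracy"
variant $(TP+TN)/(TP+FP+FN+TN)$ is reported with TN fixed at 0, since
true negatives are undefined for open-world detection — it is auxiliary
only. AP integrates the precision envelope over recall across every
distinct confidence threshold (all-points interpolation; tied confidences
enter together so the result equals an exhaustive threshold sweep); an
11-point variant exists for comparability. mAP is the unweighted mean
over the three categories; 0/0 cases are flagged, never silently zeroed.

**Count level.** With $P_{ij}, G_{ij}$ the predicted and true counts of
category $i$ in image $j$:

$$\mathrm{ED} = \operatorname{mean}_j \sqrt{\textstyle\sum_i (P_{ij}-G_{ij})^2},
\qquad \mathrm{ACC} = \operatorname{mean}_j \frac{\sum_i P_{ij}}{\sum_i G_{ij}},$$
$$\mathrm{RMSE} = \sqrt{\operatorname{mean}_j \Delta_j^2},\quad
\mathrm{MAE} = \operatorname{mean}_j |\Delta_j|,\quad
\mathrm{MPAE} = \operatorname{mean}_j \frac{|\Delta_j|}{\sum_i G_{ij}},\quad
\mathrm{MDR} = \operatorname{mean}_j \frac{-\Delta_j}{\sum_i G_{ij}},$$

where $\Delta_j = \sum_i G_{ij} - \sum_i P_{ij}$. Two readings of the
typeset formulas were ambiguous and were resolved by internal
consistency: RMSE takes the root of the *mean squared* deviation (the
only reading with RMSE ≥ MAE, which published result tables exhibit), and
ED is reported both summed across categories (as printed) and per
category (as the accompanying analysis uses it). Two identities hold
exactly and are enforced by tests and by a post-aggregation validation
pass in the pipeline: $\mathrm{ACC} - 1 = \mathrm{MDR}$, and
$\mathrm{MPAE} \ge |\mathrm{MDR}|$ with equality when every image's
deviation shares one sign. Images with zero total ground truth are
excluded with a warning (ratio metrics are undefined there) and the
exclusion count is reported. Because blocking patterns differ in block
count (4/9/40), `per_block_ed()` divides pattern-level ED by the block
count for a comparable per-block scale.

## The synthetic world

`generate_scene()` is a stated world, not a tuning dial. Its defaults:

* **Frame** 2,048 × 2,048 px at 0.25 cm/px for desk-scale work; the full
  8,192 × 5,460 survey frame is available (`uav_frame_spec()`), cheaply in
  truth-only mode (`render = FALSE`) since the mock detector never reads
  pixels.
* **Grid** 25 cm plant / 60 cm row spacing → 100 / 240 px, the standard
  planting geometry the annotation-size analysis appeals to; rows
  alternate 4 female : 1 male, a common hybridization layout.
* **Stage mixtures** (N, S, L): spikelet (0.02, 0.88, 0.10) — S dominant
  with sporadic emerged tassels; tasseling (0.02, 0.18, 0.80) — L
  occupies most plants; detasseled — female rows (0.90, 0.08, 0.02),
  male rows (0.05, 0.35, 0.60). Real stage mixtures per field are not
  published; these encode the qualitative stage descriptions and are
  fully configurable.
* **Position jitter** Gaussian with SD 10 px, truncated at ±3σ and capped
  at 24% of the grid spacing. Truncation reflects mechanical seeding
  precision, and the cap guarantees distinct plants stay farther apart
  than the 50-px merge radius — the assumption the merge step itself
  rests on. Without it, two real plants occasionally land within the
  radius and merge, so even a perfect detector would undercount for
  reasons unrelated to detection.
* **Occlusion probability** 0.05: a plant whose tassel is hidden by
  leaves is absent from truth and render alike.
* **Boxes** N/S are 140-px squares; L boxes follow a normal area law
  (mean 8,647 px², SD 2,000, the published L-box mean with a
  conservative spread) at length–width ratio 0.75 with random
  orientation.
* **Perspective surrogate** the radially dominant axis of L boxes is
  stretched by $1 + k\,r/1000$ at radius $r$ px (default $k = 0.05$),
  mirroring the "plants look slenderer away from the lens axis" effect on
  the box statistics.

Rendering is schematic (procedural glyphs on a noisy green background,
PPM output). What a green end-to-end test establishes is therefore that
the *geometry, bookkeeping and statistics* of the pipeline are correct
under a realistic spatial layout — not that any real detector reaches a
particular accuracy on real canopies. Radiometric realism (sun angle,
wind blur, lens PSF) is explicitly out of scope.

## Numerical choices and degenerate inputs

* 0/0 precision or recall → 0 with a `defined = FALSE` flag; AP with zero
  truth → `NA` with a warning.
* Merge ties: detections sorted by confidence desc, then x, then y before
  clustering; fused tables sorted by class, x, y.
* Greedy matching breaks IoU ties by truth order; confidence ties by
  input order.
* All seeds are explicit; derived seeds are reduced mod 2³¹ − 1 in double
  arithmetic so large master seeds cannot overflow R integers.
* Empty inputs (no boxes, no detections, empty files) flow through every
  stage and return empty, correctly-typed results.

## Known limitations

* The mock detector samples errors on truth; it cannot surface failure
  modes that depend on appearance (blur, exposure, cultivar differences).
* Cross-frame deduplication across a UAV survey's 70–80% inter-frame
  overlap is out of scope; fusion is within-frame only.
* The box-size sweep harness demonstrates mechanics with the mock
  detector; reproducing the published accuracy-versus-size curves
  requires GPU training on the confidential field data and is not
  attempted.
* At `min_visible_frac` > 0.25, corner-straddling boxes can vanish from
  all blocks of a non-overlapping grid (see above); evaluation against
  plan-evaluable truth keeps scores consistent, but absolute counts over
  pattern 3 slightly undercount the frame total by design.
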