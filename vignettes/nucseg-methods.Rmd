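---
title: "Methods: instance post-processing, metrics and whole-slide QC in nucseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: instance post-processing, metrics and whole-slide QC in nucseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucseg)
```

`nucseg` is the downstream half of a nucleus segmentation system: it takes
the two per-pixel maps a segmentation network emits for an H&E image — a
nuclear-material probability map and a nuclear-center detection map — and
produces instance-level nucleus data, evaluates it, and screens it at
whole-slide scale. This vignette explains the models and procedures, the
parameters that matter, and the design choices made where more than one
reasonable construction exists.

## From two maps to instances

Thresholding the probability map at `prob_threshold` (default 0.5) gives
the nuclear-material foreground. Nuclei frequently touch, so the binary
foreground alone under-counts; the detection map supplies the evidence to
split it. Connected components of `det_map >= marker_threshold`
(default 0.5), intersected with the foreground, become **markers** — one
per detected nucleus center.

The split itself is a marker-controlled watershed. The maps pin down
*where* instances are but not *where the boundary between two touching
instances runs*; we resolve it by geodesic nearest-marker region growing
(`EBImage::propagate`) over an inverse-probability landscape with a large
spatial regularizer, which grows each marker outward through the foreground
and places the inter-instance boundary along the ridge spatially equidistant
between markers. This is the standard instantiation of "watershed on
detected centers and segmentation results" in the R imaging stack; it is
isolated inside `segment_instances()`, so an alternative landscape (e.g. a
raw distance transform) is a local change.

Two policies are configurable because the underlying convention is genuinely
open:

* **Markerless foreground components** (material with no detected center)
  are kept as instances of their own by default — favoring recall, since a
  missed center should not delete real nuclear material. `keep_markerless
  = FALSE` drops them instead.
* **Minimum instance area** defaults to 9 px at 40X (0.25 µm/pixel, so a
  ~0.75 µm-wide object); anything smaller is more plausibly noise than a
  nucleus.

`labels_to_records()` converts each instance into the released-data record:
exact pixel area, `physical_size = area × (40/mag)²` projecting the count
to the 40X reference grid, and the outer boundary contour as an ordered
vertex chain (0-based, x = column, y = row, implicitly closed). Degenerate
objects whose contour has fewer than 3 points get their bounding-box
corners, keeping the ≥ 3-vertex invariant of the CSV format. Polygon CSV
cells serialize vertices as `[x0:y0:x1:y1:...]`; coordinates print as
integers when integral, else with 2 decimals — the round-trip contract of
the format assumes at most 2 decimals of vertex precision.

Whole slides are processed as 4000-px tiles laid row-major from the origin;
truncated edge tiles with any side strictly below 2000 px are skipped, and
nuclei cut by tile borders are *not* stitched — both are deliberate,
documented properties of tiled processing, and evaluation inherits them.

## Stain normalization

Staining intensity varies across scanners and batches, and fixed thresholds
downstream assume it does not. `normalize_stains()` uses the classic
channel-statistics (Reinhard-style) approach: convert to CIE Lab, shift and
scale each channel to the reference mean and standard deviation, convert
back, clip to valid sRGB. A near-zero-variance source channel is
mean-shifted only, so uniform inputs cannot divide by zero. The method
identity (statistics matching in a perceptual space) is a package decision,
kept behind a single function so a stain-deconvolution alternative could be
swapped in.

## Evaluation metrics

Evaluation restricts to the **central 226×226 window** of each 256×256
patch (anchored at `floor((size − crop)/2)`), because annotation near patch
borders is ambiguous — nuclei there are cut off by the field of view.

* **Pixel Dice** `2|A∩B|/(|A|+|B|)` measures class-level overlap; it is
  undefined when both masks are empty, and such patches are excluded from
  aggregates but counted. The **dataset Dice** weights per-patch Dice by
  `w = t + p` (true + predicted nuclei count), emphasizing patches that
  contain nuclei.
* **Instance-Dice** (ensemble form) measures joint segmentation *and*
  separation quality: each true object is paired with the predicted object
  of maximal overlap and vice versa, each matched pair's intersection is
  counted once, and the score is `2·Σ matched intersections / (Σ|g| +
  Σ|p|)`. Merging two nuclei into one prediction loses score even at
  perfect foreground, since only one pairing per object direction is
  credited. The exact formula is locked by a brute-force oracle in the test
  suite; an alternative in circulation (mean of per-pair object Dice) is
  available as `method = "aggregated"`.
* **Object precision/recall** makes the visual "both precision and recall
  at least 75 %" region judgment computable: objects are matched one-to-one
  greedily by descending IoU with an inclusive threshold (default 0.5).
  Empty-map conventions are (1, 1) for both empty, (1, 0) for an empty
  prediction, (0, 1) for an empty truth.
* **MAE%** is the ratio of means, `mean(|p − t|)/mean(t) = Σ|p−t|/Σt`, as a
  percentage — scale-invariant and dominated by patches with many nuclei,
  matching the weighting philosophy of the dataset Dice. Pearson
  correlation of the count vectors completes the bundle.

Instance-Dice can never exceed the pixel Dice of the binarized masks (its
numerator is a sub-sum of the total intersection over the same
denominator); this inequality is asserted over randomized label maps in the
tests.

## Two-level quality control

**Region level.** Fifteen 256×256 regions are sampled uniformly per slide
(`sample_patch_locations()`, distinct origins whenever the slide permits,
deterministic per seed). Each region is judged adequate iff precision and
recall are both ≥ 0.75 (inclusive). The slide's bad-region percentage then
assigns the quality group: Best at exactly 0 %, then upper-inclusive cut
points at 1/15, 2/15 and 3/15 (6.67 / 13.33 / 20.0 %), Unacceptable above —
so 0–4 bad regions of 15 map to the five groups, and the percentages
generalize the rule to other denominators. The cut points are stored as the
exact fractions rather than their printed roundings so that 2 of 15
(13.33 %) classifies as Adequate, as the interval "6.68–13.3 %" intends.
A failed slide-level visual assessment forces Unacceptable regardless of
region counts. Unjudged regions are excluded from the denominator and
reported separately.

**Slide level.** Scanning every slide visually is infeasible, so slides are
screened by statistics: per-slide nucleus count, mean nuclear size, and the
population standard deviation of size (high *or* low size variation both
being suspicious — apparent pleomorphism can reflect segmentation errors as
well as biology). Within each cancer type, the `⌈0.02·n⌉` most extreme
slides in **each tail** of **each statistic** are selected for visual
assessment, by rank with ties broken by slide id, so selection is exact and
deterministic rather than dependent on a quantile interpolation rule. When
a cancer type's first round looks bad, escalation doubles the fraction
(another 2 %, 4 % in total). A visually assessed slide is acceptable iff at
least 80 % of it (inclusive) meets the region criterion.

`qc_report()` materializes the bookkeeping: per-cancer-type totals and
failure counts, per-group slide counts, and the three released-data CSV
tables (slide list with passed/failed verdicts; visual-QC table with the
`?`-encoded unknown flag; region-checking tallies). Headers use space-free
forms (`AreaInPixels`, `NumNucleiSample`, ...) for machine friendliness.

## The synthetic patch generator

The generator exists so that every downstream stage can be exercised with
*exact* ground truth and *known* error rates. It emulates the
random-polygon view of nuclear masks:

* **Geometry.** Each nucleus is a star-shaped polygon: vertex angles
  jittered on a regular grid, vertex radii `r·(1 ± irregularity·u)` — the
  `irregularity` knob (default 0.25) is the synthetic analogue of nuclear
  pleomorphism. Defaults: 256×256 patch at 40X, 20–40 nuclei, base radii
  4–10 px (≈ 2–5 µm, right for tissue nuclei at 0.25 µm/pixel), 8–14
  vertices. Placement is rejection sampling with a 3-px enforced gap;
  nuclei are disjoint because the instance-mask representation assigns one
  label per pixel.
* **Rendering.** Nucleus pixels near a hematoxylin purple, background near
  an eosin pink, Gaussian blur (σ = 1 px) and additive noise (σ = 0.03).
  This deliberately does **not** emulate real tissue texture, chromatin
  patterns, or scanner artifacts — those matter for training CNNs, not for
  exercising post-processing, metrics and QC arithmetic. Passing tests on
  synthetic data therefore validate the *pipeline*, not segmentation
  accuracy on real tissue.
* **Model maps.** The ideal probability map is `0.5·1_fg + 0.5·blur(1_fg)`:
  thresholding at 0.5 recovers the foreground *exactly* (foreground pixels
  are ≥ 0.5 by construction; background pixels stay strictly below since
  their own zero contributes to the blur), which gives the pipeline-closure
  tests an exact target while keeping soft edges. The detection map holds a
  Gaussian bump per nucleus (peak 1.0 at the object pixel nearest the
  centroid, σ = equivalent radius / 2, truncated at 3σ).
* **Corruption.** `fn_rate` erases nuclei from both maps (Bernoulli per
  nucleus); `fp_count` injects spurious blobs into *both* maps — a
  detection bump alone in empty background would be invisible to the
  marker-intersect-foreground rule, making the knob inert; `boundary_shift`
  dilates/erodes the foreground; `map_noise_std` adds clipped Gaussian
  noise. Provenance records every true nucleus and its erasure flag, so
  tests can compare recovered error rates against the injected ones.

Everything is a pure function of the config seeds (`withr::with_seed`, so
the session RNG is untouched); datasets regenerate byte-identically from
their manifest.

## Numerical choices and degenerate inputs

* Group-boundary comparisons absorb floating error with a 1e-9 epsilon at
  the k/n breakpoints.
* Undefined metrics (Dice with both masks empty, MAE% with zero total true
  count, correlation of constant vectors) return `NA` and are excluded from
  aggregates, with the count of such patches reported.
* Label renumbering after cropping/filtering orders labels by first pixel
  in storage order, so outputs are deterministic.
* Masks with ≤ 255 labels round-trip through 8-bit grayscale PNG; larger
  label counts use the 16-bit TIFF container (lossless, up to 65535), and
  the PNG writer refuses rather than truncate.
* Tie-breaks in object matching (equal overlaps or IoUs) resolve toward the
  smallest label index, mirrored exactly by the brute-force oracles in the
  tests.

## Problem sizes used in validation

The test suite and the acceptance script run the full pipeline at sizes
chosen to give tight Monte-Carlo checks while staying quick on one CPU: 50
uncorrupted patches for closure (scores must be exactly 1.0 / 0 %), 200
patches at `fn_rate = 0.25` for parameter recovery (mean recall within 3
standard errors of 0.75, MAE% within 3 standard errors of 25 %), 200-patch
batches per corruption level for the recall-monotonicity property, 200
patches for the polygon-area calibration, and 50 randomized label-map pairs
per metric against the brute-force oracles. Bookkeeping checks recount the
released dataset's published summary tables (5,060 slides, 576 failed, 971
patch labels) through `qc_report()` from reconstructed per-slide fixtures.

## Known limitations

* Synthetic nuclei are disjoint star polygons; real overlapping or crushed
  nuclei, mitoses, and out-of-focus regions are not modeled, so real-data
  segmentation quality cannot be inferred from these tests.
* The watershed boundary between touching nuclei is the equidistant ridge;
  a probability-weighted landscape could place it differently when the
  model's confidence is asymmetric.
* Stain normalization matches global channel statistics; it does not
  separate hematoxylin from eosin, and strong stain imbalance can survive
  normalization.
* Nuclei split across tile borders remain split, by design; counts near
  tile edges are biased accordingly.
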