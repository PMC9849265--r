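---
title: "Counting caribou in drone orthomosaics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting caribou in drone orthomosaics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and conventions behind `herdcount`: what
each stage computes, which choices were genuinely open and how they were
resolved, and what the synthetic test bed does and does not establish about
real survey imagery.

## The problem

A drone survey of a caribou herd yields a handful of very large stitched
orthomosaics (one per flight), annotated by observers and/or a detector as
labeled bounding boxes in pixel coordinates. Three classes are used:
`adult`, `calf` (separable by body size), and `ghost` — an animal that
moved between the overlapping photos from which the mosaic was stitched and
was rendered blurred or semi-transparent by the photogrammetry. Ghosts are
annotated as their own class precisely because they are a double-counting
hazard: the same animal can appear sharp in one place and ghostly in
another. The analysis questions are how closely a detector or a team of
naive observers reproduces an experienced observer's counts, class by class
and mosaic by mosaic, and where their errors concentrate.

The experienced observer is taken as the reference: the evaluation assumes
the reference misses nothing and mislabels nothing. Every "error" this
package reports is therefore a *disagreement with the reference*, which is
the operational quantity a survey coordinator can actually measure.

## Coordinates and the annotation dialect

Boxes are integer-pixel, 0-based, half-open `[x0, x1) × [y0, y1)`, origin
at the mosaic's top-left. Half-open integer boxes make areas and
intersections exact integer arithmetic and make tile translation loss-free.
Annotation files are headered CSV —
`mosaic_id,label,x0,y0,x1,y1,confidence` — one box per row, confidence
blank for humans. The original field files recorded "a type of label and
vertex coordinates"; a two-corner encoding is assumed, since four vertices
of an axis-aligned rectangle are redundant. Label phrases such as
"adult caribou" are normalized to the bare class token; any label outside
the three-class vocabulary is a hard error, because silent label coercion
is how annotation sets rot.

## Tiling geometry

Detectors cannot ingest a 50k × 50k mosaic, so mosaics are cut into
`tile_size` × `tile_size` tiles (default 1000 px) whose starts advance by
`stride = tile_size − overlap` (default overlap 100 px, so stride 900).
The final row/column is clipped to the mosaic rather than padded or
shifted; padding is a rendering concern, and shifting would make tile
origins data-dependent. Tile counts per axis are the smallest number whose
extents cover the axis, `max(1, ceil((dim − overlap)/stride))`.

The overlap prevents split animals from being lost, but creates a
double-counting hazard of its own, resolved by *ownership*: each tile has
a core of one stride per axis, the cores partition the mosaic, and an
annotation belongs to the single tile whose core contains its top-left
corner. Two consequences drive the whole design:

* any box with both sides ≤ overlap is fully contained in its owner's
  extent (except at the mosaic's own boundary), so the owner always sees
  the whole animal — this is the formal version of "an animal on a tile
  edge is counted in the following tile";
* per-tile counts summed over owners equal mosaic counts exactly, which
  the test suite checks as a round-trip identity.

The last tile's core per axis extends to the mosaic edge (not to
`(i+1)·stride`), otherwise the final `width − n·stride` pixels would have
no owner and the partition property would fail. Boxes larger than the
overlap can overhang their owner's extent; they are kept, flagged
`clipped`, and warned about, because truncating data silently is worse
than an honest flag. At the default geometry the overlap corresponds to
2.4–3.7 m on the ground — comfortably larger than a caribou — so the
flag should not fire on real annotations.

Merging per-tile detections inverts the assignment: translate to mosaic
coordinates, keep a detection only if the emitting tile owns it, then
optionally apply same-label non-maximum suppression (default IoU 0.5) for
residual duplicates whose observed top-left moved because a tile boundary
clipped them. The baseline detector additionally discards blobs cut off at
an interior left/top tile edge before merging: such a fragment belongs to
an object that starts in — and is fully visible to — an earlier tile, and
its clipped corner would otherwise fall into the emitting tile's own core.

The train/test split of tiles is seeded and, by default, stratified per
mosaic (round to nearest, ties upward), since survey reports quote
per-mosaic tile counts; a global unstratified draw is available. Tiles
without annotations participate as negative examples.

## Matching and error accounting

No published criterion exists for when a predicted box "matches" a
reference box in this setting, so the criterion is explicit configuration:
greedy one-to-one matching over all cross pairs in order of decreasing
IoU, ties broken by smaller center distance, then reference index, then
predicted index; a pair is accepted only if both members are free and IoU
≥ `iou_threshold`. The default threshold 0.3 is deliberately loose:
human boxes around a 40-px animal are sloppy, and overlapping adult/ghost
pairs rule out pure containment tests. Greedy matching is order-free given
the tie-breaks (hence reproducible) and is bounded above by the true
maximum matching; the suite verifies the bound by exhaustive search on
small instances and verifies equality whenever no reference is ambiguous.
Matching is class-agnostic by default so that label disagreement is scored
as *misclassification* rather than as a missed-plus-spurious pair.

From a match, pooled ("species-level") counts ignore labels: pairs are
TP, unmatched predictions FP, unmatched references FN. Per class, a
mismatched pair contributes an FP to the predicted class *and* an FN to
the reference class — the convention under which the per-class tallies of
the published tables this package mirrors are internally consistent. The
confusion table records pair labels, a `missed` column for unmatched
references, and an `object` row for unmatched predictions (spurious
detections of rocks, birds, trunks — or of animals the reference did not
record; the evaluation cannot distinguish these and does not pretend to).

## Metrics

True negatives are undefined for box detectors, so accuracy is
`TP/(TP+FP+FN)`; precision and recall are standard. Algebraically
accuracy ≤ min(precision, recall), fuzz-tested in the suite. Degenerate
zero denominators raise errors at the function level and become `NA` cells
(flagged, never silently 0) in assembled tables.

Two conventions needed resolving:

* **Percentage difference.** Published per-mosaic tables are consistent
  with `100(n_source − n_ref)/n_ref` at the species level but with a
  source-count denominator in several per-class rows. Both are
  implemented; the reference denominator is the default and the choice is
  a documented argument, not an interpretation buried in arithmetic.
* **Misclassification proportion.** The denominator that reproduces every
  checkable published cell is `n(y→x) / (n(y→x) + TP_x)` — the
  misclassified boxes relative to the correctly detected members of the
  *predicted* class. It is exposed as `misclass_proportion()` so the
  convention is visible and testable.

Report tables round proportions to 2 decimals and percentages to 1, half
away from zero, matching how such tables are printed; raw values are
always retained, and `recall + missing_proportion = 1` holds exactly
before rounding. Per-tile agreement between two sources is the sample
Pearson correlation of per-tile counts (≥ 3 tiles, non-zero variance on
both sides required; undefined cells are flagged).

"All observers" aggregate metrics are computed from mean counts (the
convention of the summary tables mirrored here) *and* as means of
per-observer metrics; the two differ whenever observers are heterogeneous,
so both are emitted under distinct names.

## The synthetic test bed

No field imagery is publicly available, so the generator produces scenes
with the statistical structure the analysis assumes:

| parameter | default | rationale |
|---|---|---|
| adult length | 1.3–2.1 m | adult caribou body length |
| calf scale | 0.5–0.7 × adult | calves separable by size |
| body aspect | 0.30–0.45 | elongated dorsal silhouette |
| body tone | 0.82–0.95 gray | high contrast against ~0.48 background |
| ghost alpha | 0.25–0.6 | "blurred or even transparent" |
| ghost blur σ | 1–3 px | mosaicking smear |
| GSD presets | 2.4, 3.7 cm/px | 75 m and 120 m flight altitudes |
| min separation | 40 px | mostly bedded, non-overlapping animals |

Backgrounds are a bilinearly interpolated coarse random field (meadow /
water / shrub patchiness) plus white noise. Ghosts are the same sprites
composited at low alpha after an exact separable Gaussian blur, which
makes "ghosts have measurably lower contrast than adults" a generator
property the tests assert. Truth boxes are the tight bounding boxes of
each sprite's rendered pixels — all animal pixels, minimal background —
and tightness is audited pixel-by-pixel. Distractors are rendered into
the raster but excluded from truth. Placement is rejection sampling with
bounded retries; infeasible requests raise a capacity error reporting the
achieved counts instead of quietly under-filling.

The observer error model mirrors the error taxonomy the evaluation
measures: per-class miss probabilities, a confusion matrix over recorded
labels (each row plus its miss probability must sum to 1), Gaussian box
jitter, and spurious caribou annotations on distractors at a configured
rate per 100 distractors. Human-observer defaults keep that rate at 0 —
in the mirrored surveys people never mistook objects for caribou, while
the detector did. Detector-style models draw Beta confidences so NMS has
something to rank. Scene and observer use separate seeded streams, so
observers can be re-simulated without re-rendering, and a fixture suite of
four scenes (two per GSD preset) with expert, five naive observers, and a
detector-like source is byte-for-byte reproducible from one master seed.

What passing tests show: the pipeline's bookkeeping is exact (ownership,
merging, counting rules), planted error rates are recovered without bias
(miss 0.2 recovered within 3 binomial standard errors over 200 seeds of
500 animals), and the geometry conventions are self-consistent. What they
do not show: anything about real imagery — real observers err on the same
hard individuals (the model assumes independence), real backgrounds
contain caribou-shaped stones, and real ghosts follow photogrammetric
physics, not an alpha composite. The generator is a test bed for the
*analysis*, not a simulator of cameras.

## The baseline detector

The bundled detector exists so the end-to-end loop runs without a GPU:
blockwise local-median background (120-px blocks; animals occupy a small
fraction of any block, so the median tracks terrain), foreground at
`max(4 × MAD-sd, 0.06)` absolute contrast, 8-connected components
filtered to 0.05–6 m² (GSD-scaled), labeled calf below 0.5 m², adult
above, relabeled ghost below mean contrast 0.25. It clears a smoke floor
(precision and recall ≥ 0.95) on easy scenes — high-contrast adults,
no ghosts, no distractors — which is a pipeline sanity bound, not a
performance claim. On scenes with distractors it misclassifies rocks and
trunks as low-contrast animals, which is useful: it exercises the
`object` row of the confusion table the way a trained CNN does. It is
explicitly an adapter slot; any `function(tile raster) -> annotation_set`
can replace it.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale by design:
scenes up to 2800 × 1900 px, 500-animal planted-rate recoveries over 200
seeds, 500 random matching instances with ≤ 6 boxes per side for the
exhaustive-matching oracle, and 1000-box tiling round trips. These sizes
were chosen so each property is measured with enough replication to be
meaningful (binomial standard errors of a few tenths of a percent) while
the whole suite stays fast enough to run on every change. All randomness
flows through per-artifact integer seeds; nothing depends on global RNG
state, and every generated artifact is reproducible bit-for-bit.

Known limitations worth keeping in mind: the reference-is-truth assumption
caps measurable recall at the reference's own completeness; greedy
matching can (rarely, in dense clutter) fall below the optimal assignment;
inter-observer correlation of errors is not modeled; and the published
species-level metric cells of the mirrored survey are not all derivable
from their printed TP/FP/FN triples, so only the per-class cells are used
as worked-example anchors.
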