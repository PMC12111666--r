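---
title: "Weakly supervised surgical component localization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised surgical component localization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camcrm)
```

## The problem

Recognition models for surgical action triplets (instrument, verb, target)
are trained from frame-level presence labels only, yet their class
activation maps (CAMs) carry coarse spatial evidence: a positive cell in
the `grasper` channel says "a grasper is around here". Two obstacles stand
between that evidence and usable bounding boxes:

1. **The target guide is mislocated.** Triplet models reuse the
   instrument's activation as a positional attention guide for the tissue
   target, so the target channel's positive area converges on the
   *instrument*, not on the tissue being operated.
2. **CAMs are coarse.** An 8 x 14 grid over a 256 x 448 frame localizes to
   32 px cells at best.

`camcrm` post-processes the outputs of such a recognition model together
with scored candidate masks from a promptable segmentation backend. The
networks themselves are out of scope: the package consumes their outputs
(CAM grids, mask proposals with predicted-IoU and stability scores, and a
binary Instrument/Tissue region classification) through documented
contracts, which is what makes every stage testable on synthetic scenes.

## Attention guide correction (AGC)

Instruments enter a laparoscopic scene from the periphery and work toward
its center, so the tissue an instrument operates on lies ahead of it along
that direction. The correction translates each target channel cyclically
by `(Kh, Kv)` cells:

    x' = (x + Kh) mod W,   y' = (y + Kv) mod H

The magnitudes `|Kh|`, `|Kv|` are configuration (default 2 cells each);
the signs are inferred per channel from the channel's own activation: take
the 4-connected positive component with maximal mean activation, compute
its activation-weighted centroid, and shift component-wise *toward the
grid center* (`sign((W-1)/2 - cbar)` horizontally, `sign((H-1)/2 - rbar)`
vertically, rows positive downward, `sign(0) = 0`). A channel with no
positive cell is left unshifted and flagged.

Two notes on choices that were genuinely open:

* **Direction rule.** Worked examples of the forward-direction idea can be
  stated with inconsistent sign conventions (an upper-right instrument
  "moving toward bottom-left" and a bottom-right instrument with a target
  "at the upper left" cannot both give `Kh < 0, Kv < 0` under one axis
  convention). The toward-grid-center formulation is the single rule that
  reproduces the bottom-right example and is the one implemented; the
  generator's `direction = "random"` mode exists to stress-test it.
* **Wrap-around.** The modular translation is implemented literally, so
  activation mass can wrap across an edge. Physically an instrument
  leaving bottom-right does not re-enter top-left; the `clip_wrap` flag
  zeroes wrapped mass instead. Both behaviors are tested; the literal rule
  is the default because the equation is explicit, and shifts of 1–3 cells
  inferred toward the center rarely wrap in practice.

The shift is exactly mass-preserving per channel, `shift` followed by its
inverse is the identity, and shifting by `(W, H)` is the identity — these
are the package's core conservation properties and are tested as such.

## From CAM to preliminary boxes

Per present channel: positive cells (strictly above the configurable
threshold, default 0 for pre-pooling logit maps) that are maxima of their
8-neighbourhood seed boxes; each seed grows to its 4-connected positive
component; the component's cell bounding box is lifted to pixels (cell
`(r, c)` covers `[c*cell_w, (c+1)*cell_w) x [r*cell_h, (r+1)*cell_h)`);
per-channel greedy NMS (default IoU 0.5) scored by the component's mean
activation removes duplicates. Plateaus of equal activation are resolved
to the top-left cell; multiple peaks in one component yield one box.
"Boxes centered on maximal points" could alternatively be read as
symmetric windows around each peak; component bounding boxes were chosen
because they adapt to blob extent and make the box independent of where
inside the component the peak sits.

## Candidate regions

Any automatic-mask-generation backend (or the synthetic generator)
supplies, per frame, binary masks with a predicted-IoU (confidence) and a
stability score. The filter pipeline runs in the order: score floors
(defaults 0.88 / 0.95, the reference automatic-mask-generation settings —
the thresholds themselves are exposed configuration), greedy NMS on mask
bounding boxes ranked by `(pred_iou + stability) / 2`, removal of regions
*strictly* smaller than 2000 px (spurious components from reflections and
water stains), rank-sort, truncation to the top 10. The pipeline is
idempotent, and "confidence" in the rank score is read as the
predicted-IoU score — the only per-region confidence available.

## Candidate region matching (CRM)

A trained binary classifier labels each surviving region `Instrument` or
`Tissue`; the package ships the contract plus an oracle implementation
(fixture labels) and a geometric demo heuristic (elongated, thin masks are
metal tools). The matching cost between preliminary box `i` and region
`j` is reciprocal:

    C[i, j] = 1 / ( Overlap(box_i, reg_j) + mean activation of box_i )
    Overlap  = [gate] * ( CIoU(box, reg bbox) + K )

with `gate = 1` only for kind-compatible pairs (instrument-class box with
Instrument region, target-class box with Tissue region) and the
simplified complete IoU

    CIoU(a, b) = IoU(a, b) - rho^2 / c^2

(`rho` the center distance, `c` the enclosing-box diagonal; the
aspect-ratio term of full CIoU is intentionally absent). `K` (default 2)
must exceed 1 so `CIoU + K > 0` always; it is validated at configuration.

The assignment is solved by a Jonker–Volgenant-style Hungarian solver
written for this package (O(n^3), rectangular matrices solved over the
smaller side, deterministic tie-breaks) and verified against
exhaustive-permutation brute force in the test suite. Because the cost of
a gate-0 pair is finite (the activation term remains), the literal
minimum-cost assignment can select an incompatible pair; the default
`post_filter` mode solves on the literal matrix and then drops gate-0
pairs from the result (a preliminary box may end unmatched), while
`hard_forbid` assigns a large sentinel cost before solving. Both are
available because the order of forbidding relative to solving is a
genuine ambiguity; `post_filter` is the default as the more literal
reading. The assignment runs jointly over instrument and target boxes —
the gate already separates the two groups, so a per-group solve would
give the same matching.

Each surviving pair becomes a detection: the region's bounding box, the
preliminary box's class, the preliminary box's mean activation as the
score (a detection confidence is otherwise undefined in this setting),
and the matching cost as provenance.

## Evaluation

Per class: detections are ranked by score and greedily matched to
same-frame, same-class ground truth at an IoU threshold (each ground
truth consumed once, best IoU first). AP integrates the monotone
(all-points interpolated) precision envelope over recall; mAP\@0.5 is the
headline number. AR is *twice* the area under the recall-vs-IoU-threshold
curve on [0.5, 1]: recall is evaluated on the grid 0.50, 0.55, ..., 0.95
*plus the right endpoint 1.0* and integrated by trapezoid — without the
endpoint the normalization property "recall 1 everywhere gives AR exactly
1" cannot hold on the 10-point grid. Assignments are redone independently
at each threshold. Macro means run over classes with at least one ground
truth instance; empty classes report `NA` and are excluded.

## The synthetic scene generator

The generator is the package's study design, not a convenience: its
defaults encode the conditions the method assumes.

* Frames 256 x 448 px, CAMs 8 x 14 (32 px square cells), 1–2
  instrument/target pairs per frame, pairs placed in separate frame
  halves with instrument centers kept off the central axes — instruments
  sit peripherally, which also keeps the direction rule's sign well
  defined.
* Planted displacement between instrument and target centers: `D_h ~
  Uniform(0.1, 0.2)` of frame width, `D_v ~ Uniform(0.1, 0.3)` of frame
  height, pointing toward the frame center — the high-density region
  observed for laparoscopic cholecystectomy, and about 2 CAM cells at the
  default geometry. `displacement_cells` plants an exact cell
  displacement instead (used by the sweep and exact-recovery fixtures).
* CAM channels carry Gaussian blobs (sigma 1.2 cells, minus a 0.15 floor
  so the positive area is compact); the *target* channel's blob sits at
  the paired **instrument's** center — the planted flaw the correction
  must undo — while ground-truth target boxes sit displaced.
* Candidate regions are the ground-truth boxes rasterized with +-4 px
  edge jitter (unstable segmentation boundaries), with high scores, plus
  3 lower-scored tissue distractor regions per frame. Distractors model
  spurious segments from reflections and water stains — areas of no
  interest — and are therefore rejection-sampled to overlap every
  ground-truth box with IoU < 0.2; a "distractor" nearly coincident with
  an annotated component would not be spurious. When two pairs share a
  frame the second is resampled until no two ground-truth boxes overlap
  with IoU >= 0.3 (two instruments operate at distinct sites; coincident
  targets would also be merged by any region NMS).
* Scores: true regions 0.97/0.98, distractors 0.90/0.96, each +- a small
  uniform noise (0.02 default).

What the generator does **not** emulate: appearance (no pixels beyond
masks, so no real classifier can be trained on it), non-rectangular mask
shapes, video temporality, class imbalance, multiple instruments of the
same class in one frame, and displacement that varies with surgical
phase. Passing tests therefore demonstrate the correctness and the
qualitative behavior of the post-processing machinery — not clinical
performance.

## Validation design and problem sizes

The deep networks and annotated surgical video needed for the reported
headline numbers are outside a desk-scale build, so validation is
property-based, at sizes chosen to keep the whole suite in a few minutes:

* Exact conservation/inversion of the cyclic shift (200 random CAMs);
  CIoU bound and hand-derived values (1000 random pairs); Hungarian
  equals brute force (500 matrices up to 5 x 5); filter semantics and
  idempotence; metric normalizations including a hand-integrated AP of
  5/6.
* **Exact end-to-end recovery**: 50 noise-free frames (zero jitter, zero
  distractors, zero score noise, displacement planted at exactly 2 cells)
  give instrument and target mAP\@0.5 of exactly 1.0. The displacement
  must equal the correction magnitude here: with displacement drawn from
  the uniform supports, the fixed 2-cell shift over/undershoots by
  design, and residual error is precisely what the sweep studies — exact
  recovery under those conditions would be ill-posed, not strict.
* **Sweep recovery**: over `|Kh| in 0..4`, `|Kv| in 1..3`, 50-frame
  batches, 10 seeds, the selected optimum is (2, 2) when the planted
  displacement is 2 cells. At this sample size the target-mAP surface
  plateaus at its maximum over adjacent magnitudes, so tied maximizers
  are ordered by mean target matching cost — a continuous alignment
  criterion that falls as the corrected guide centers on the target.
  Instrument mAP is bitwise constant across the grid (the correction
  never touches instrument channels).
* **Ablation direction**: on the default noisy scenes, target mAP with
  the correction strictly exceeds the run without it, while instrument
  mAP is unchanged.
* **Displacement statistics**: the 2-D Gaussian KDE (Scott's-rule
  bandwidth `sd * n^(-1/6)` per axis, evaluated via `MASS::kde2d` on a
  fixed 101-point lattice over [0, 0.5]^2) of 500 planted pairs has its
  mode inside the planted support on every seed tested. Fewer than two
  pairs refuse the KDE and return raw distances only.

## Numerical and degenerate-input conventions

Boxes are 0-based half-open pixel rectangles, so areas are exact integer
arithmetic and edge-adjacent boxes are disjoint; degenerate (zero-extent)
boxes are rejected at construction. NMS ties on equal scores break by
ascending `(y0, x0, x1, y1)`. The enclosing-box diagonal in CIoU is
strictly positive for valid boxes; a division guard exists anyway. Empty
inputs (no detections, no regions, no positive activation) flow through
every stage as empty tables rather than errors, except where the result
would be undefined (evaluation with no ground truth at all). All
randomness is consumed from R's global RNG under a single caller-set
seed, and the generator's `render = FALSE` mode draws the identical
stream while skipping array materialization, so geometry is reproducible
across both modes.

## Known limitations

The correction magnitude is a domain constant: 2 cells is calibrated to
laparoscopic cholecystectomy geometry and must be re-estimated (via
`displacement_stats` and `sweep_agc`) for other procedures. The region
classifier contract collapses the scene into two kinds; a region that is
neither (e.g. gauze) must still be labelled one of them. Matching is
one-to-one per frame, so a target covered by two disjoint masks yields at
most one detection. AR's right-endpoint evaluation makes AR sensitive to
sub-pixel rasterization of otherwise perfect boxes (IoU 1 exactly is
required for recall at threshold 1.0).
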