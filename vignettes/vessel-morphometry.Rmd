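---
title: "Retinal vascular morphometry: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retinal vascular morphometry: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselmorph)
```

`vesselmorph` measures retinal vascular geometry from pre-segmented
binary artery and vein masks. This vignette is the package's account of
the underlying models and of every place where the design was genuinely
open: which estimators were chosen, why, with what defaults, and what
the synthetic validation does and does not demonstrate about real
fundus images.

## The measurement model

All coordinates are 1-based `(row, col)` pixel positions (rows grow
downward); positions derived from clusters or subpixel refinement are
continuous. Lengths are in pixels and angles in degrees throughout.

### From mask to centerline graph

1. **Skeletonization.** The mask is thinned to an 8-connected,
   one-pixel-wide centerline by *directional sequential border peeling*:
   north, south, east and west layers are peeled alternately, and a
   pixel is deleted only when it is an 8-simple point (its foreground
   8-neighbors form a single connected set and a 4-neighbor is
   background, checked against a 256-entry lookup table) and not an
   endpoint. Sequential deletion with a true simple-point test cannot
   disconnect a component or erase a stroke; the classical parallel
   schemes (Zhang–Suen, Guo–Hall) were evaluated first and both delete
   two-pixel-wide diagonal runs outright, which at retinal calibers
   erases entire near-45° branches. The alternating directions keep the
   result on the medial axis, and the operator is idempotent by
   construction (it loops to a joint fixpoint with a staircase-removal
   pass that prevents redundant pixels from masquerading as junctions).

2. **Graph extraction.** Skeleton pixels with a neighbor count other
   than two are node pixels; 8-adjacent node pixels are merged into one
   node at their centroid, because thinning expresses one anatomical
   branch point as a small pixel cluster. Edges trace the maximal
   degree-2 paths between clusters; every skeleton pixel belongs to
   exactly one node cluster or one edge interior. Arc length is the
   Euclidean length of the pixel chain (1 per 4-step, √2 per diagonal).

3. **Cleanup.** Three raster artifacts are repaired at graph level, all
   scaled to the local caliber: terminal spurs shorter than
   `max(5, 1.5 × parent diameter)` px are pruned iteratively and
   through-nodes re-merged; tiny loops (thinning traps single
   background pixels where strokes overlap at shallow angles) are
   dropped; and split junction complexes — two degree-≥3 nodes within
   about one vessel diameter — are contracted to a single node.

4. **Diameters.** Per edge, the local stroke width is measured at every
   retained centerline pixel by sampling the mask with bilinear
   interpolation along both normals of the (smoothed) local tangent and
   locating the 0.5-level boundary crossing on each side. Samples are
   taken at three tangent phases to break grid aliasing, pixels within
   one junction radius of either end node are excluded, and the
   remaining per-pixel widths are averaged after trimming
   bulge-contaminated stretches from both ends (anchored on the median
   of the middle third). The same boundary crossings re-center each
   stored centerline point on the subpixel stroke midline, which is
   what gives the direction fits their accuracy. A pure
   distance-transform diameter (2·DT at the centerline) was evaluated
   first and rejected: its orientation-dependent bias (up to ~0.8 px)
   and correlated quantization noise are too large for caliber ratios
   at 4–9 px vessel widths. The distance transform (via
   `EBImage::distmap`) is still used for junction-bulge radii and
   search bounds.

5. **Rooting and crossings.** Each connected component is rooted at its
   disc-nearest node and directed outward; components farther than 3
   disc diameters from the disc center are dropped as debris. Degree-4
   nodes are vessel crossings, not junctions: their four incident edges
   are re-paired to maximize tangent continuity (each edge joined to
   the one closest to a 180° continuation, ties broken by diameter
   similarity) and merged into two pass-through vessels. A crossing of
   thick vessels at a shallow angle often thins into *two* degree-3
   nodes joined by a short connector; such connectors are detected by
   their X signature (the four outer edges pair into two near-straight
   continuations) and contracted first. Nodes of degree ≥ 5 are
   pathological and are flagged and excluded from measurement rather
   than guessed at.

### Orders, junction classes and the five parameters

Strahler orders live on edges (vessel segments): terminal edges are
order 1 and a parent is `m + 1` exactly when two or more daughters
attain the maximal daughter order `m`. A two-daughter junction is a
**bifurcation** when the daughter orders are equal and a **branching
point** when they differ; junctions with more than two daughters are
classified on the two largest-diameter daughters and flagged.

Per junction inside the measurement annulus — radial distance `r` from
the disc center with `r − D/2` in `[0.5 D, 2.0 D]`, boundaries
inclusive — the package measures:

* the **angle** between the two daughters' initial directions, each fit
  by total least squares over the first `min(path length, 3 × parent
  diameter)` px of its centerline, excluding points inside the junction
  bulge (about one parent diameter: the medial axis bends smoothly
  there) and inside the *fusion zone* where the two daughter strokes
  have not yet separated by their mean caliber;
* the **coefficient** `(d1² + d2²)/d0²`, the exponent-2 area ratio that
  is the standard caliber-based branching coefficient of the retinal
  literature. BC/BEC use identical arithmetic and differ only in the
  class of junction they average over.

Per-image values are unweighted means over qualifying junctions, one
row per vessel class; a metric with zero qualifying junctions is
reported as `NA`, never 0. The annulus restriction is applied to all
four branch metrics (symmetry of the definitions; configurable).

The **main angle** vertex is the disc *center* (a configurable override
exists): per hemifield (above/below the disc-center row) the tree with
the largest trunk diameter is selected; from its root, the
maximal-order chain is followed and the distal endpoint of the last
edge holding the maximal order is the anchor. When a hemifield holds no
tree — for instance in a rotated image — the two largest-trunk trees
overall are used instead and the record is flagged; in standard fundus
orientation these are exactly the superior and inferior temporal
arcades, which makes MA invariant to image rotation. MA is deliberately
not annulus-restricted: the anchors of the arcades generally lie beyond
the outer annulus radius.

## The synthetic generator: what it emulates

`generate_tree_spec()` builds one temporal arcade: a binary-ish tree
rooted on the disc edge, growing radially outward inside an angular
wedge. Its defaults are the package's study conditions and were fixed
once, on realism and raster-recoverability grounds:

* branch angle law `U(55°, 95°)` at the draw, floored at 26° after
  wedge clamping — first-generation arcade branchings are wide, distal
  angles shrink; junctions narrower than ~25° leave daughter strokes
  fused for longer than a segment and are not recoverable at these
  calibers;
* daughter caliber ratios `U(0.65, 0.9)` with `d1 ≥ d2`;
* trunk diameter `D/7`, first segment `1.15 D` long, lengths decaying
  by 0.85 per generation (desk-scale geometry: with a 64 px disc on a
  560 px canvas this makes distal branches 4–6 px wide, the smallest
  caliber at which a diameter ratio is still meaningfully measurable);
* the minor daughter loses one extra generation with probability 0.5,
  which yields a mixture of branching and bifurcation junctions
  (subtree-depth asymmetry is what makes daughter Strahler orders
  differ);
* a finished draw is rejected and deterministically resampled if any
  two non-adjacent segments' strokes would overlap, if any realized
  angle falls below 24°, or if any drawn segment lies within 3° of a
  multiple of 45° — a grid-aligned stroke rasterizes with its width
  quantized to a constant, so the drawn caliber cannot equal the
  planned one and the planned diameter is unrecoverable *from the
  raster by any estimator*.

Ground truth (`ground_truth_morphometry()`) is computed analytically
from the spec — planned directions, planned diameters, a recursive
Strahler assignment on the spec tree — and never touches a raster, so
it is a genuinely independent oracle for the pipeline.

What passing the recovery suite shows: on crossing-free rendered
arcades the pipeline recovers junction angles within ±3°, coefficients
within ±10%, MA within ±2°, and junction classes exactly. What it does
not show: robustness to segmentation noise (ragged boundaries, gaps,
false branches), to central light reflex holes, to tortuous vessels
(segments here are straight), or to the caliber statistics of real
eyes. Those failure modes enter through the masks, which this package
treats as given.

`simulate_cohort()` draws per-image metric values independently from
per-group normal distributions. Normality matches the downstream
one-way ANOVA and the symmetric reported intervals. Published tables
report group means with 95% CIs rather than SDs, so
`reference_cohort_params()` recovers `SD = (CI half-width/1.96)·√n`
with the published per-group image counts (279/1193/510/384) — an
inversion this package documents as its own, not as the original
authors' values.

## The statistics layer

`describe_group()` is the sample mean, `n−1` SD and t-based CI.
`one_way_anova()` is the standard fixed-effects decomposition, fitted
through `stats::lm`/`stats::anova`. Pairwise mean differences default
to Fisher's LSD with the pooled within-group MSE of the full four-group
fit — the unadjusted pairwise p-values alongside a one-way ANOVA mirror
the common SPSS workflow that produces tables of this shape — with
Bonferroni and Welch alternatives available in the configuration.
Images are treated as independent observations (both eyes enter
separately), matching the published unit of analysis; a mixed model for
eye-within-child correlation would be the stricter choice and is out of
scope here.

One calibration fact belongs in the open: at the published venous
main-angle means, with CI-derived SDs and published group sizes, the
ANOVA noncentrality is ≈ 24, so the power to reach p < 0.001 is ≈ 0.87
per simulated cohort — the headline significance reproduces in the
clear majority of replicates and the median replicate p is ≈ 1e-5, but
no simulation at these SDs can make 95% of replicates cross that line.
The acceptance script therefore reports the median p over 101 seeded
replicates rather than a single draw.

## Numerical choices and degenerate inputs

* Ties in crossing re-pairing are broken by diameter similarity; ties
  in the maximal-order chain by daughter diameter.
* Angles are clamped into `(0°, 180°]`; a zero angle is reported `NA`.
* Edges too short to retain any width sample fall back to the
  all-pixel mean and are flagged; single-pixel-scale edges fall back to
  the distance transform.
* An empty mask yields a flagged record (`"no vasculature"`), not an
  error; an empty skeleton raises a warning only.
* Degenerate cohorts (SD = 0) are exact: every simulated value equals
  its group mean. The degenerate reproduction tests use SD = 0.001 so
  the t-based interval machinery stays defined.
* All generators are pure functions of their parameters and seed; the
  generator restores the caller's RNG state.

## Problem sizes used by the test suite

The suite validates recovery on 50 seeded two-arcade images at
560×560 px (depth 3, ~5 junctions each), Strahler ordering against a
brute-force recursion on 200 random trees of up to 63 edges, null
calibration of the ANOVA on 2 000 four-group replicates, and the
invariance of all five metrics under 90° rotation and uniform 2×
scaling. These sizes were chosen so the full suite completes in about a
minute while every tolerance is exercised at its stated value.

## Known limitations

* Masks with many same-class crossings (pathologically tortuous eyes)
  can produce degree-5 complexes, which are excluded rather than
  resolved.
* Diameter estimation assumes locally straight, solid strokes; hollow
  vessels (central light reflex) would need preprocessing.
* The hemifield fallback for MA assumes the two largest trunks are the
  temporal arcades; in images where a nasal trunk dominates, the
  configurable vertex/selection should be reviewed.
* Strahler order is the only ordering scheme offered (no
  diameter-based Horton ordering).
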