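---
title: "Image-based drought phenotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-based drought phenotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`shootpheno` implements an end-to-end analysis of image-based drought
phenotyping for single potted plants: a synthetic trial generator with
known ground truth, shoot segmentation, thirteen shape and colour
traits, rank-based treatment screening with quantile-regression outlier
removal, and PCA / t-SNE embeddings of the trait space. This vignette
explains the models behind each stage, the parameters that matter, and
the choices made where the design was genuinely open.

## The synthetic trial

Real drought-screening image sets are rarely public, so the package
ships a generator whose output is a pure function of a configuration,
a variety panel, a stress model and one root seed. The default design
mirrors a realistic greenhouse screen: 28 varieties in 7 randomized
plots (2 unstressed, 5 drought-treated), with 16 varieties excluded
from the second unstressed plot for space, giving 180 individuals.
Plants are imaged from a vertical and a horizontal angle on days
-7, 0, +7, +14, +21 and +28 relative to the start of a 14-day
water-deficit treatment that is followed by a 14-day recovery.

### Growth and stress model

Unstressed projected area grows multiplicatively:
$A(d) = A_0 (1+g)^{d-d_0}$, with the variety growth rate $g$ (default
0.04/day) and baseline $A_0$ (default 2000 mm^2) scaled by a shared
lognormal "vigour" factor (sd 0.15 on the log scale). Height grows
linearly at a vigour-linked rate, which is what produces the medium to
strong correlations between hand measurements and image area that the
validation stage checks. Day-to-day biological noise is lognormal
(sd 0.06).

Treated plants accumulate a log-area deficit of
$\log(1 - s)$ per treatment day ($s$ = `area_shrink_per_day`, default
0.05 -- at day +14 the treated arm sits near half the unstressed area)
and close it at $\log(1 + r)$ per recovery day (`recovery_rate`,
default 0.04, never overshooting zero). The defaults leave a residual
deficit of roughly 16% at the end of recovery: large enough for a
per-trait rank test on 180 plants to notice, small enough that
individual plants look near-equal in vigour.

Three further stress effects persist beyond the treatment window, and
together they are what keeps recovered plants identifiable:

* **Chlorosis.** Leaf colour shifts toward pale yellow by
  `yellowing_per_day` levels/day (default 3): red rises, green rises
  slightly, blue falls. The shift decays during recovery at only
  0.03/day, because chlorotic mature tissue does not re-green --
  recovery dilutes it with new growth.
* **Patchiness.** Each leaf lobe carries a persistent chlorosis weight
  drawn from U(-1, 1): some lobes stay green while others reach twice
  the mean shift. Patchiness is what drives the three colour-*variance*
  traits rather than the mean colour.
* **Wilt compaction.** Canopy architecture compacts in proportion to
  the accumulated relative area loss (`wilt_coupling`, default 0.8):
  lobes droop toward the center and broaden, lowering caliper length,
  hull and rectangle areas relative to the projected area and raising
  roundness. The compaction fades at the chlorosis rate, for the same
  dilution reason.

All three effects are proportional to the shrink/yellowing parameters,
so a zero-effect stress model is observationally identical to no
treatment -- the property the type-I-error calibration relies on.

### Rendering

A plant is the union of 3-9 elliptical leaf lobes whose positions,
axes, orientations and colour jitters are drawn once per plant and
reused across days, so a plant keeps its shape while it grows. The
lobe union is rescaled by secant iteration until the rasterized
foreground count matches the simulated area times `px_per_mm`^2
(residual mismatch is rasterization jitter of a few percent; the
ground-truth-consistency tests allow 10% with noise on). The scene adds
a dark background, a gray-brown pot (annulus in the vertical view,
bottom block in the horizontal view) and a near-white support strut;
leaves are drawn on top, so the truth mask marks exactly the visible
leaf pixels. Per-pixel Gaussian channel noise (sd 5 levels) and
per-lobe colour jitter (sd 8) complete the image.

What the generator does **not** emulate: photorealistic leaves, 3-D
occlusion between the two views, illumination gradients, soil-moisture
dynamics, or real varietal differences in leaf shape. Passing tests on
this generator demonstrate that the pipeline's measurement and
statistics machinery is correct under controlled conditions, not that
it would achieve the same accuracy on real greenhouse imagery.

## Segmentation

The literal workflow description for this kind of pipeline -- binarize
each channel, merge the binaries, then threshold again -- is a no-op
cascade, so the default path merges the *raw* bands with excess-green
weights ($2G - R - B$, affinely rescaled to 0-255), applies one Otsu
pass, and keeps the above-threshold (green-dominant) class. The
per-band binarize-then-merge variant is retained behind
`segment_params(band_mode = "binary_merge")` for comparison. Otsu's
threshold maximizes the between-class variance over all 255 splits of
the 256-level histogram, ties broken by the smallest level; the
implementation is checked against an exhaustive search. Noise removal
is a morphological opening with a disk of radius 1 (the 4-neighbour
cross); components below 25 px are dropped; components are 8-connected,
and boundaries use the 4-neighbour convention. An image in which no
plant survives these steps yields a zero-component result with a
warning, not an error, because drought-killed plants genuinely vanish.

Obstacle exclusion is data, not code: colour boxes and fixed zones in
the configuration, with a protected foreground colour box that
exclusion rules can never claim. The synthetic default rules match the
renderer's pot and strut palettes.

## The thirteen traits

Five area traits (projected area, caliper length, convex hull area,
minimum-area rectangle area, object sum area), five boundary traits
(boundary-point roundness, circumference, convex hull circumference,
minimum enclosing circle diameter, roundness) and three colour
variances. Geometry uses **pixel centers** everywhere: a single pixel
has caliper 0, the 10x10 block has hull area 81 by the shoelace formula
but 100 by rasterized pixel count, and corner-based conventions used by
some imaging tools differ by O(1 px). One consistent convention beats a
mix.

* Convex hull: monotone chain, counter-clockwise, collinear points
  dropped. The hull-area *trait* is the rasterized pixel count inside
  the hull polygon (a count of pixels, like the other area traits); the
  polygon (shoelace) area is used for the geometric containment
  invariants.
* Caliper (Feret) length: the exact maximum pairwise distance,
  evaluated on hull vertices (the diameter is attained there).
* Minimum-area rectangle: rotating-caliper sweep over hull edge
  directions; an optimal rectangle has a side collinear with a hull
  edge.
* Minimum enclosing circle: Welzl's incremental algorithm over a
  deterministic pseudo-shuffle of the hull vertices. The circle is
  unique, so the shuffle affects runtime only, and using a built-in
  integer congruential sequence keeps the global RNG stream untouched.
* Circumference: the trait name literally describes the enclosing
  circle's circumference, which would duplicate the MEC diameter up to
  a factor of pi. The default mode therefore reports the Moore-traced
  contour perimeter (Euclidean step lengths: 1 axial, sqrt(2)
  diagonal, summed over components; single-pixel components contribute
  0; interior holes are not traced), and the literal reading is kept
  behind `mode = "literal"` so both are testable.
* Whole-plant scope: hull, caliper, rectangle and circle are computed
  over the union of retained components; `scope = "largest"` restricts
  to the largest component, in which case `object_sum_area` still
  reports all components -- both readings of the area/object-sum pair
  are available because the original convention is ambiguous.
* Colour variances: population variance (divide by n) of a channel
  over ROI pixels only. The default channel semantics are opponent
  axes (`lab8`): lightness, green-red and blue-yellow, each mapped
  onto 0-255 with neutral near 128 -- the description "0 is green,
  255 is red about a neutral level" names an opponent space, not raw
  RGB. Raw `rgb` mode is retained and selectable because the trait
  *names* say R/G/B.

Undefined traits (empty ROI, a degenerate caliper) are recorded as
missing, never zero: zeros would corrupt the rank tests downstream.

## Statistics

The Kruskal-Wallis statistic is computed on mid-ranks with the standard
tie-correction divisor -- plant trait tables are full of ties from
integer pixel counts -- and referred to the chi-square upper tail with
k-1 degrees of freedom. All values identical across groups returns
H = 0, p = 1 by documented convention. Screening tables report one row
per (trait, view, stage, day, grouping) for both the treatment and the
variety grouping, flagged at alpha = 0.005 for image traits and 0.05
for hand measurements, with **no** multiplicity correction (a
Benjamini-Hochberg column can be emitted for inspection but never
drives the flag). A calibration caveat worth knowing: in the trial
design every variety appears in both arms, so under a zero effect the
raw rank test is *conservative* (the blocked layout shrinks between-arm
differences); the calibration tests therefore use homogeneous-variety
trials, where plants are exchangeable and the empirical rate sits at
the nominal level.

Outlier removal fits linear quantile regressions of value on day at
tau = 0.05 and 0.95 within each (trait, view, stage, treatment) cell
and removes rows strictly outside the band -- symmetric 5% tails are
the mildest defensible default when nothing stronger is known. The
pinball-loss minimizer is exact: an optimal line of the LP interpolates
two data points, so the fit enumerates candidate lines through all
point pairs with distinct covariate values (vectorized; cells here hold
at most a few hundred rows). Cells with fewer than 10 observations pass
through unfiltered with a warning, and a constant covariate falls back
to the empirical quantile.

## Embeddings

Traits are z-scored per column before any embedding -- the columns mix
px, px^2 and squared levels, so unscaled distances would be meaningless.
Rows with any missing trait are dropped, never imputed. One embedding
is computed per (day, view); PCA is an eigendecomposition of the
scaled covariance with each component's sign fixed by its
largest-magnitude loading, and t-SNE is implemented in full: per-row
Gaussian bandwidths calibrated by binary search to the target
perplexity (tolerance 1e-5 in log-perplexity, which is well inside the
1e-3-bit acceptance band), symmetrized affinities, Student-t
low-dimensional kernel, and momentum gradient descent with early
exaggeration (factor 12 for 120 of 600 iterations, learning rate 200,
adaptive gains) from a seeded N(0, 1e-4) start. The embedding seed is a
required argument; there is no silent default. Treatment separation is
summarized by the mean silhouette width of the treatment partition in
the embedded plane.

At the default trial scale, the all-13-trait t-SNE at the end of
recovery separates treated from unstressed plants with silhouette
around 0.2 (and essentially 0 for zero-effect trials), while before
treatment no embedding separates anything. One honest limitation: for
this generator's unimodal, roughly Gaussian trait clouds, a 2-D PCA of
the single best trait category can match or exceed the 13-trait t-SNE
on the silhouette score, because PCA concentrates a correlated
category's signal into two coordinates while t-SNE must carry all
thirteen. The qualitative claim that combined categories beat any
single category is therefore best read on the screening tables (where
colour, boundary and area each miss different cells) rather than as a
guaranteed ordering of silhouette scores.

## Problem sizes and reproducibility

The test suite builds everything it needs in code: the shared
trial is 8 varieties x 7 plots x 2 days x 2 views (224 images at
160x160 px, 0.5 px/mm), the screening-power check runs 100 replicate
42-plant trials at day +14, the embedding checks use one 180-plant
trial at day +28 plus 5 zero-effect trials of 98 plants, and the
geometric oracle suite covers 1000 small point sets (every operator
against full enumeration) plus 30 sets of 100-500 points. These sizes
were chosen so a complete run stays comfortable on a single CPU while
every statistical check retains enough replicates to be meaningful;
`scripts/acceptance.R` re-runs the headline computations from scratch
for any seed and writes the numbers as JSON. All randomness descends
from explicit seeds: trial generation restores the caller's RNG state,
the Welzl shuffle never touches it, and rerunning any stage with the
same configuration reproduces its outputs bit for bit.
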