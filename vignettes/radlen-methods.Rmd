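---
title: "Measuring radicle length: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring radicle length: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radlen)
```

`radlen` measures the radicle (embryonic root) of germinating seeds from
RGB images. This vignette explains the statistical model and the
measurement procedure, the parameters a user may want to touch, what the
synthetic data generator does and does not emulate, and the design
decisions taken where the procedure was genuinely underdetermined.

## The measurement problem

After imbibition the radicle is the first structure to emerge; a seed is
scored as germinated once it penetrates the coat by roughly 1–2 mm.
The trait of interest is the *arc length* of the radicle from its
emergence point at the seed coat to its tip — not the Euclidean
tip-to-coat distance, because radicles curve. The pipeline therefore
reduces each radicle to a one-pixel-wide skeleton and measures a geodesic
along it.

Segmentation is delegated to a *promptable segmenter*: any model that,
given an image and a box or point prompt, returns one binary mask
(`segmenter_backend()`). The package orchestrates prompts around such a
backend but never implements one; tests use an oracle backend that
answers from synthetic ground truth, which isolates the package's own
logic from segmentation quality.

## Chromaticity model

Seed coats are roughly constant in hue while radicles are pale; both vary
strongly in brightness (shading, moisture). Classification therefore
works in the brightness-shift-invariant feature space
\(x = (R - B,\; G - B)\): adding a constant to all three channels leaves
\(x\) unchanged. The coat is modelled as a 2-D Gaussian \((m, C)\) and a
pixel's coat membership is scored by the kernel

\[ p(x) = \exp\left[-\tfrac12 (x - m)^\top C^{-1} (x - m)\right], \]

which is 1 at the mean and decays with Mahalanobis distance. A pixel is
coat iff \(p(x) > T\) with \(T = 0.006\) by default ("exceeds" is read
strictly, so \(p = T\) goes to the radicle). For a pixel drawn from the
model itself, \(-2\log p \sim \chi^2_2\), hence
\(P(p \le T) = T\) exactly: the threshold *is* the expected coat
false-negative rate. This identity is what the test suite checks by Monte
Carlo, and it gives \(T\) a direct interpretation — 0.6 % of true coat
pixels are sacrificed to keep the radicle clean.

### Training the model

\((m, C)\) are the sample mean and covariance (denominator \(n-1\)) of
the features in the 3×3 windows centred at the seed-mask centroids. The
centroid of a whole seed mask lands on the coat because the coat
dominates the mask's area — and at the coarse stage the detection box has
truncated most of the radicle anyway.

One model is fitted **per image**, pooling the 3×3 patches of all seed
masks, not one per seed. A single patch provides at most 9 samples, and a
2×2 covariance estimated from 9 draws is unreliable in a specific,
damaging way: with appreciable probability the fitted ellipse is nearly
degenerate, its \(p > T\) region collapses, and a large fraction of the
coat is misclassified (simulation puts the mean misclassification near
7 % with a ~2 % chance of exceeding 30 % per patch). Pooling across the
15–30 seeds of a typical tray image makes the estimate stable; the
per-image model also matches how a single imaging condition (one
illumination, one variety) behaves. The fine stage re-fits the model at
the classified coat centroids, which are strictly interior coat points.

Degenerate pooled patches (uniform colour) still occur, so
`fit_gaussian()` adds a ridge \(\lambda = 10^{-6}\max(\mathrm{tr}\,C, 1)\)
whenever \(\det C < 10^{-12}\); the applied ridge is recorded on the
model. Features are kept as signed reals — 8-bit wraparound would fold
the feature space.

## Coarse-to-fine segmentation

Box-prompted masks are intersected with their prompting box even if a
backend returns pixels outside it. This codifies the documented behaviour
of box-prompted segmenters and makes the coarse stage's limitation —
radicles clipped at the box edge — reproducible and backend-independent.
The fine stage prompts with the coat and radicle centroids as foreground
points in a single prompt and does *not* clip, which is precisely the
mechanism that recovers the clipped radicle. Whether the fine stage
should also receive the box is undetermined; points-only matches the
observed un-truncated fine masks and is what this package does. Per-seed
masks may overlap (adhering seeds); no global pixel arbitration is
attempted because measurement is per seed.

## Skeleton metrology

Both component masks are thinned with the classical Zhang–Suen
two-subiteration algorithm until fixpoint. The skeleton becomes an
undirected weighted graph: one vertex per pixel, edges between
8-neighbours, weight 1 for orthogonal and `diagonal_weight` for diagonal
steps.

* `diagonal_weight = 2` is the package default, following the graph
  convention of the measurement procedure this package implements. Note
  that weight 2 makes the metric Manhattan-like: a diagonal step of true
  length \(\sqrt 2 \approx 1.414\) costs 2, overestimating oblique
  lengths by up to 41 %. The alternative `sqrt(2)` gives Euclidean
  polyline lengths and is a supported configuration
  (`skeleton.diagonal_weight`). Accuracy claims in the test suite use
  axis-aligned radicles, for which the two conventions coincide.

The radicle length is the geodesic between

* \(p_e\): the radicle-skeleton **endpoint** (degree-1 vertex) with the
  largest Euclidean distance to the coat skeleton — the root tip. Using
  the *farthest* endpoint also makes the measurement robust to plumules,
  which are shorter than radicles and would otherwise offer competing
  endpoints.
* \(p_i\): the **junction** (degree ≥ 3 vertex) with the smallest
  distance to the coat skeleton — the emergence point.

Three degenerate situations need decisions the procedure itself does not
make:

1. *No junction.* Thin, unbranched radicles skeletonize to a simple path
   with no degree-3 vertex. The fallback takes the component vertex
   nearest the coat skeleton and flags the record
   `no_intersection_fallback`. This is the common case for clean
   synthetic radicles.
2. *Disconnected radicle skeletons.* Classification noise produces
   specks; the component containing the globally farthest endpoint is
   measured, the rest ignored, flagged `skeleton_disconnected`.
   \(p_i\) is always restricted to \(p_e\)'s component so the geodesic
   exists.
3. *Ties.* All arg-max/arg-min ties break to the smallest (row, col), so
   results are bit-reproducible across platforms.

Empty radicle masks (or masks that vanish under thinning) yield length 0
with flag `no_radicle`. Each seed is measured on a crop padded by 2 px so
border pixels have full neighbourhoods; coordinates are mapped back to
the image frame.

## Calibration

A quadrilateral of known physical area — by default one sixty-fourth of
an A4 sheet, \(210 \times 297 / 64 = 974.53125\) mm² — is photographed
once under the same camera geometry. Detection: morphological opening,
Canny edges (Sobel gradients, 4-direction non-maximum suppression,
double-threshold hysteresis), largest closed contour, and the contour
points nearest the corners of the contour's minimum-area rotated
rectangle as vertices. The rotated-rectangle corner matching is a
package decision; any reference frame for "the four corners" would do as
long as it is consistent. The pixel area is the cyclic shoelace sum
(implemented for any simple \(n \ge 3\)-gon), and

\[ R = \sqrt{S_p / S_r} \quad\text{(px per mm)}, \qquad l_r = l_p / R . \]

The conversion divides: \(R\) is defined as pixel length over true
length, so true length is pixel length over \(R\). No lens-distortion or
perspective correction is attempted; the camera is assumed fixed between
calibration and seed images.

## Evaluation metrics

`segmentation_scores()` implements Dice, IoU, PA, FPR over the combined
coat+radicle foreground and per-class IoUs with their mean (mIoU). Two
conscious fidelity choices: **PA** is intersection over ground truth —
i.e. foreground recall, not all-pixel accuracy — implemented exactly as
defined for this pipeline's evaluation; and undefined ratios (empty
ground truth or empty background) are returned as `NA`, never 0, so
averages are not silently inflated.

## The synthetic scene generator

`generate_scene()` renders what the pipeline assumes about real trays:

* near-black background (non-reflective cloth), default RGB (12, 12, 14);
* elliptical seed coats whose features are drawn iid from
  \(N(m_{true}, C_{true})\), defaults \(m = (85, 55)\),
  \(C = [[36, 8], [8, 25]]\) over a blue level of 70 — a brownish-yellow
  coat typical of rice;
* radicles as width-3 tubes along a centerline of exactly known polyline
  length (default 20–60 px), either axis-aligned straight (integer-exact
  geometry) or gently curved (quadratic Bézier rescaled to the requested
  arc length); the radicle colour (235, 235, 228) sits at Mahalanobis
  distance ≫ 6 from the coat model, so classification difficulty is
  controlled by \(C_{true}\) alone;
* detection boxes that tightly cover the coat plus the 25 % of the
  radicle nearest it — reproducing detector boxes that truncate long
  radicles, which is the condition the fine stage exists to fix;
* additive Gaussian channel noise, default \(\sigma = 1\) 8-bit unit;
* optionally a bright calibration square of known px and mm side.

The rendered centerline is anchored 2 px inside the coat boundary while
the stored ground-truth arc length covers only the boundary-to-tip
polyline. The anchor compensates, by construction, for the one-pixel
erosion that Zhang–Suen thinning applies at each end of a tube: the
thinned skeleton then spans almost exactly the boundary-to-tip distance,
so generator ground truth and Algorithm output are commensurable. With
ground-truth masks fed directly to the length measurement, recovery is
exact on straight radicles.

What the generator does **not** emulate: spatially correlated coat
texture (real coats are smooth, not iid), awns, shadows, specular water
bubbles, perspective distortion, overlapping radicles from different
seeds, and real segmentation-boundary error beyond the `dilate1`
corruption. Passing tests therefore demonstrate the correctness of the
pipeline's own logic — classification calibration, skeleton metrology,
calibration arithmetic, orchestration — under the stated statistical
assumptions, not detector or segmenter performance on real imagery.

The oracle backend answers box prompts with the best-overlapping seed's
ground-truth mask (clipped under `box_clip`, dilated under `dilate1`) and
point prompts with the full mask of the first seed containing a prompt
point; a point missing every seed returns an empty mask, modelling a
segmentation miss.

## Threshold sweep

`run_threshold_sweep()` evaluates the classification threshold over
0.001–0.010 in steps of 0.001 (the grid is configurable). With the
oracle backend the combined coat+radicle region is prompt-determined and
therefore threshold-invariant, so the sweep scores the *radicle
component* against ground truth — the quantity the threshold actually
moves. The sweep doubles as a property check: the coat mask grows
monotonically as the threshold decreases.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use 200×200-px scenes with 3
seeds, radicle lengths 20–60 px, 50 scenes per end-to-end experiment, 100
random skeletons (≤ 400 px) for the geodesic oracle, 1,000 random
quadrilaterals for the shoelace oracle, and 10,000 feature draws for the
threshold-calibration check. These sizes put every statistical assertion
comfortably past its standard error on a single CPU while keeping the
whole suite under a minute; results are invariant to scaling the scenes
up.

## Known limitations

* Weight-2 diagonals overestimate oblique radicle lengths (up to 41 %);
  use `diagonal_weight = sqrt(2)` for curved-radicle work in physical
  units.
* The Gaussian coat model assumes one dominant coat colour mode per
  image; trays mixing strongly different varieties would need per-variety
  models.
* The iid chromaticity assumption makes patch-based covariance estimates
  noisier than on real (smooth) coats; the per-image pooling is the
  mitigation.
* Calibration assumes a fixed camera and negligible lens distortion.
* Non-germinated seeds bypass measurement entirely (length 0,
  `no_radicle`): germination status is taken from the detector's class,
  not re-decided here.
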