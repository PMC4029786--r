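---
title: "Overlap-corrected rosette area estimation and logistic growth analysis"
author: "RosetteGrowth authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Overlap-corrected rosette area estimation and logistic growth analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RosetteGrowth)
```

## The problem

Top-view imaging is the standard way to phenotype rosette plants such as
*Arabidopsis thaliana* at scale: a camera above the tray records one
grayscale (often fluorescence) frame per plant every few minutes, and the
number of plant pixels in each frame is taken as the plant's area. The
weakness of that pixel count is leaf overlap: as a rosette matures, younger
leaves grow over older ones and the projected area increasingly undercounts
the true summed leaf area. Segmenting every individual leaf would solve
this but is notoriously unreliable on dense rosettes.

This package implements a middle road. It never segments overlapping
leaves; instead it uses the geometry that rosette leaves radiate from a
common center:

1. **Plant center.** A few *simple* (isolated, non-overlapping) leaves are
   detected in the foreground mask. Each contributes an orientation line --
   the longest chord across the leaf -- and the center is the point closest
   to all lines. The center of mass is the baseline and the fallback when
   fewer than two usable leaves exist.
2. **Leaf tips.** The outline of the foreground mask is expressed as a
   polar radius profile $r(\varphi)$ about the center, one bin per degree.
   A circular moving average over $k$ bins merges the serrated outline into
   one hump per leaf; tips are the raw radii at the local maxima of the
   smoothed profile, thresholded at a minimum radius $T_r$.
3. **Per-leaf area.** The leaf length is the center-to-tip radius $r$
   (petiole included, since all petioles meet at the center). The curvature
   ratio $cr = (r - r_s)/r$, where $r_s$ is the smoothed radius at the tip,
   separates round from elongated leaves, and a piecewise model maps length
   to area: $32.9\,r - 769.9$ for $cr < 0.07$ and $513.8\,e^{0.0146\,r}$
   otherwise. The coefficients ship as an editable calibration (they are
   species- and optics-specific) and can be refit from training leaves,
   including the $cr$ cutoff itself via a two-component Gaussian mixture.
4. **Plant area.** With the summed model areas $a_l$ and the observed
   top-view area $a_t$, the overlap percentage is
   $p_{overlap} = |a_t - a_l| / \max(a_t, a_l)$ and the corrected plant
   area is $a = a_l\,(1 + p_{overlap})$. When $a_l > a_t$ (tips found for
   overlapping leaves) this equals $2a_l - a_t$; when $a_l < a_t$ (inner
   tips missed) it equals $2a_l - a_l^2/a_t$. Both identities are
   property-tested.

The resulting area series feeds a three-parameter logistic model

$$A(t) = \frac{A_0\,A_a}{A_0 + (A_a - A_0)\,e^{-\gamma t}},$$

fit by Levenberg-Marquardt nonlinear least squares, with first-order 95%
confidence intervals. From the fitted curve the package derives absolute
and relative growth rates (finite differences over a step $\Delta t$),
closed-form velocity and acceleration, and phase-plane features.

## Phase-plane analysis

The trajectory of acceleration against velocity of a logistic growth curve
is a closed loop: it starts at the origin (dormant), passes the maximal
acceleration (point b), crosses zero acceleration at maximal velocity
(point c, the inflection $A = A_a/2$, velocity $\gamma A_a/4$), reaches the
strongest deceleration (point d) and returns to the origin at the
asymptote. The enclosed area $\oint a\,\mathrm{d}v = \int a(t)^2 \mathrm{d}t$
summarizes how much "growth energy" the episode transferred; for an exact
three-parameter logistic it equals $\gamma^3 A_a^2/30$, which the tests use
as an independent oracle for the trapezoid integration the package
performs.

Two conventions deserve a note. First, the inflection of the model above is
at $A = A_a/2$ exactly; a sometimes-quoted $(A_a - A_0)/2$ is not a zero of
the second derivative and is not used here. Second, the first derivative of
a logistic is nonnegative everywhere, so point d is reported with positive
velocity; phase-plane plots that mirror the deceleration branch to negative
velocities are a display convention only.

Genotype summaries average replicates in one of two modes:
`"replicates"` (default) computes each replicate's features and averages
them -- extrema of individual plants, then the mean -- while `"curve"`
first averages the curves (no longer an exact logistic) and then extracts
features numerically. They disagree when replicates are staggered in time;
both are exposed because which one a published summary used is often
ambiguous. Before averaging, replicates whose area series differ from
their peers (two-tailed Welch t-test of one replicate's per-timepoint
areas against the pooled rest, $p < \alpha$) can be flagged and excluded.
With very extreme outliers this leave-one-out scheme also inflates the
statistics of the sound replicates (the outlier contaminates their
comparison pool), so flags should be read jointly, worst first.

```{r phase-plane, eval = FALSE}
fits <- arabidopsisLogisticFits()
kept <- subset(fits, retained & genotype == "WT")
wt <- averageReplicates(list(as3plFit(kept$gamma[1], kept$A0[1], kept$Aa[1]),
                             as3plFit(kept$gamma[2], kept$A0[2], kept$Aa[2])))
wt$features
```

## The synthetic-rosette generator

Because validation images of real plants cannot ship with a package, every
stage is validated against a synthetic generator with *exact* ground
truth. A rosette is a set of convex leaf polygons (ellipses for round
leaves, two-circular-arc lenses for elongated ones) radiating from a
center; the union area is computed by polygon clipping
(inclusion-exclusion over convex intersections), never by pixel counting,
so the truth carries no raster error. Rasterization uses the
pixel-center-in-polygon rule on 0-based (row, col) coordinates with pixel
centers at integers -- stated once here and used everywhere. Intensities
emulate a 12-bit fluorescence frame: background 100, plant 3000, additive
Gaussian noise with a standard deviation of 2% of the 0-4095 dynamic
range, clipped to the range; rendering is bit-reproducible given the seed.

Growth series evolve each leaf so its exact polygon area follows the
logistic law: the length is obtained by inverting the length-to-area
model (linear branch for ellipse leaves; exponential branch for teardrops
where invertible, i.e. where the target area exceeds the exponential
scale, otherwise the always-invertible linear branch), and the width is
then solved numerically so the polygon area matches the logistic value
exactly. This keeps the length-area relation and an exact area oracle at
the same time.

What the generator does *not* emulate -- leaf texture and venation,
twisting and curling, circadian movement, intensity vignetting -- bounds
what passing tests show: they validate the geometry and the estimators,
not robustness to every nuisance of real imagery.

## Parameters and defaults

| parameter | default | unit | role |
|---|---|---|---|
| `edge_threshold` | Otsu | fraction of max gradient | edge map cutoff |
| `dilation_radius` | 2 | px | close gaps in the edge map |
| `erosion_radius` | `dilation_radius + 1` | px | boundary-bias compensation |
| `bin_width` | 1 | degrees | polar profile resolution |
| `k` | 9 | bins (odd) | profile smoothing window |
| `T_r` | 0.15 x max radius | px | minimum tip radius |
| `s_min` | 0.85 | -- | simple-leaf solidity screen |
| `A_min`, `A_max` | 100, half of `a_t` | px^2 | simple-leaf size screen |
| `round_min` | 1.2 | -- | skip round leaves for orientation |
| `cr_cutoff` | 0.07 | -- | length-to-area branch split |
| `dt` | 0.35 | days | growth-rate step |
| `alpha` | 0.05 | -- | outlier flagging level |

A global intensity threshold is deliberately not offered: fluorescence
intensity drifts across a day, so segmentation is gradient-based per
frame. Several defaults are conventions rather than published values --
the smoothing window, the relative tip threshold (a relative threshold
adapts across plant ages, where a fixed one would either miss young
plants' tips or hallucinate old ones'), and the simple-leaf screen. All
are config-overridable and serialize losslessly through YAML.

## Numerical and design choices

* **Boundary bias of the mask.** The published chain (Sobel edges,
  dilation, corner flood fill) leaves the filled region one dilated edge
  band too wide. A compensating final erosion (`erosion_radius`, the
  dilation radius plus the one-pixel Sobel half-band) restores an unbiased
  outline; on a noiseless disk of radius 50 the area error is well under
  5%. Disable it (`erosion_radius = 0`) to reproduce the raw chain.
* **Background connectivity.** The flood fill is 4-connected and
  foreground components are 8-connected, the standard complementary
  pairing that avoids topological paradoxes.
* **Center objective.** The center is defined as the minimizer of summed
  perpendicular distances to the orientation lines. The default minimizes
  *squared* distances, which has a closed form (2x2 normal equations) and
  is exactly reproducible; an IRLS mode minimizes the plain L1 objective
  for robustness to one bad line. For near-concurrent lines -- the typical
  rosette case -- the two agree to well under a pixel.
* **Simple-leaf screening is geometric.** Published descriptions of
  Laplacian/Canny-based leaf isolation leave the acceptance criteria
  unspecified; here a mask component is a simple leaf if it is hole-free
  with a single closed contour, has solidity at least `s_min`, and a
  plausible area. Overlapping pairs form lobed, low-solidity complexes
  and are excluded wholesale rather than segmented.
* **Ties and plateaus.** Plateau maxima of the smoothed profile return
  their central bin (lower index for even plateaus); the longest-chord
  search breaks ties lexicographically by (row, col). Both make outputs
  order- and rotation-deterministic.
* **Branch boundary.** A curvature ratio exactly at the cutoff takes the
  exponential branch (the "otherwise" reading); negative linear-branch
  predictions for very short leaves are clamped to zero with a warning.
* **Missed inner tips are accepted by design.** The polar profile sees
  only the outermost edge, so tips of fully occluded inner leaves are
  invisible; the overlap correction is what compensates, which is also why
  the corrected area is the better estimate precisely when overlap is
  substantial.

## Problem sizes used by the test suite

The suite validates on rosettes of 3-12 leaves in 192-400 px images, a
30-frame 512 x 512 synthetic growth series for the end-to-end run, and a
100-repetition Monte-Carlo calibration of the logistic fit (900 points,
2% noise) -- sizes chosen so the full suite runs in a few minutes on one
CPU while every stage still has headroom above its tolerances.

## Known limitations

* The shipped length-to-area coefficients are calibrated for one imaging
  setup and genotype family; any new optics or species requires
  recalibration from training leaves.
* One plant per image is assumed; tray-level multi-plant segmentation is
  out of scope.
* Strictly 2-D rosettes only: without leaf height, the projected-area
  logic does not transfer to 3-D canopies.
* Tips are detected per frame independently; tracking tips across frames
  would raise recall on dense mature rosettes but is not implemented.
* Only the three-parameter logistic family is fitted. One- and
  two-parameter variants are special cases that fit growth data poorly;
  four- and five-parameter variants add flexibility at the cost of
  over-parameterization on series of this length, and are documented here
  but intentionally not implemented.
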