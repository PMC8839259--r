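---
title: "Straightening oligoclonal bands in IEF gel lanes: model and methods"
author: "gelwarp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Straightening oligoclonal bands in IEF gel lanes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelwarp)
```

## The problem

Isoelectric focusing (IEF) with IgG immunoblotting separates proteins
along a pH gradient; oligoclonal bands (OCBs) appear as thin, ideally
horizontal bands in each vertical lane of the scanned membrane. Counting
CSF-specific OCBs supports multiple sclerosis diagnosis, and automatic
detection works on each lane's 1-D densitometric profile — the mean of
the lane's pixel rows. Uneven migration conditions bend the bands
("smile" distortion, local warps). A bent band spreads its contrast
across many rows of the 1-D profile: its peak broadens and shrinks, and
faint bands disappear entirely. Straightening the bands before peak
detection is therefore a load-bearing enhancement step, particularly for
low-IgG samples such as tears.

gelwarp corrects the *vertical* component of band distortion in a single
rectified lane. Horizontal distortion is assumed to have been removed
upstream by lane rectification (also provided here, from externally
supplied edge contours).

## The deformation model

A lane is a grayscale grid $I(x, y)$ with $y$ the migration axis
(downwards) and an out-of-band boolean mask of *missing* pixels (empty
rectification borders, masked artifacts). All processing happens in
"signal" polarity: bands are peaks. The warp applies a per-pixel vertical
shift field $\Delta Y(x,y)$:

$$I'(x,\; y + \Delta Y(x, y)) = I(x, y),$$

resampled per column by linear interpolation of the inverse map.
Straightening looks for the field minimizing

$$E(\Delta Y; I) \;=\; f\!\big(\bar R(\Delta Y; I)\big)
  \;+\; w_x \lvert \partial \Delta Y / \partial x \rvert
  \;+\; w_y \lvert \partial \Delta Y / \partial y \rvert ,
  \qquad \text{s.t. } \textstyle\int \Delta Y(x, y)\, dx = 0
  \;\; \forall y .$$

* **External energy.** $\bar R$ is the mean pairwise Pearson correlation
  of lane columns, each pair computed only over rows where both columns
  are non-missing (so masked artifacts cannot bias it), with negative
  correlations clamped to zero and pairs below a minimum overlap or with
  zero variance excluded. Straight bands make columns collinear
  ($\bar R \to 1$); $f(c) = (1 - c)^p$ with $f(0) = 1$, $f(1) = 0$
  converts this to an energy. With the default $p = 1$ the marginal
  reward of correlation is constant; larger $p$ emphasizes lanes that are
  already well correlated.
* **Internal energy.** $\lvert \cdot \rvert$ is the sum of absolute
  forward differences. The $w_x$ term penalizes shear (adjacent columns
  shifting differently), the $w_y$ term dilation/compression along the
  migration axis. Both act as a total-variation-like regularizer: strong
  but smooth deformations are cheap, oscillating ones are not.
* **Constraint.** Zero mean shift per image row prevents the optimizer
  from compressing band-free regions (which have little correlation to
  lose) onto band-rich ones.

### The constraint projection

Node moves on a deformation grid redistribute the shift within the grid
row — the moved node takes $s\,\delta$, every other node in its row
$-s\,\delta/(c_g-1)$ — which zeroes the *node* row mean. Because border
nodes carry less interpolation weight than interior ones, plain bilinear
interpolation of such a grid leaves small nonzero *pixel* row means. The
constraint is stated as hard, so the optimizer additionally subtracts
each pixel row's mean from the interpolated field before evaluating any
energy. Every field the optimizer ever scores therefore satisfies the
constraint exactly (tested to 1e-6 px); `grid_to_field()` itself remains
pure bilinear interpolation and is exact at the nodes.

## Background removal

Pixel intensity mixes band signal with membrane background. A
*rolling-ellipsoid* filter estimates the background as the upper envelope
reachable by an ellipsoid with radii $(r_x, r_y, r_z)$ rolling beneath
the intensity surface — a grayscale opening with a non-flat ellipsoidal
structuring function, computed exactly (an equivalence test against a
brute-force roll holds to 1e-6). The anisotropy is the point:

* $r_y$ (default 300 px) is far larger than any band FWHM (7-30 px), so
  the ellipsoid bridges band valleys and band peaks survive subtraction;
* $r_x$ (default 15 px) is at the band-width scale, so the ellipsoid
  drops into narrow along-x irregularities and removes them;
* $r_z$ (default 40 intensity units) sets the intensity reach.

Missing pixels are filled by nearest-neighbour inpainting before the
morphology (otherwise artifact holes would carve artificial valleys) and
re-masked afterwards.

A consequence of the large $r_y$ worth knowing: along-y background
variation whose curvature exceeds $r_z / r_y^2$ (sharper than the
ellipsoid bottom) is bridged, not followed, and therefore retained in the
subtracted lane. This is deliberate — at that scale such structure is
indistinguishable from broad bands — and it is harmless to the
straightening energy, because a background profile shared by all columns
raises every pairwise correlation uniformly. It does mean that repeating
background removal is only *nearly* idempotent in general; within the
filter's design envelope the second pass changes the lane by well under
1% of its dynamic range.

## The optimizer

Direct minimization over per-pixel fields is hopeless; the search runs
over a hierarchy of rectangular deformation grids whose bilinear
interpolation (plus the row projection) yields the field, coupled to an
image pyramid. Four steps use row/column downsampling factors
$(f_r, f_c) = (8,8), (4,8), (2,8), (1,4)$ — columns are reduced more
aggressively because the column-correlation is the dominant cost — with
node shift magnitudes $\delta = 8, 4, 2, 1$ px (full-resolution units,
divided by $f_r$ at each level). Each step sweeps a list of grid sizes,
by default $\langle 2,3\rangle, \langle 3,3\rangle$ up to
$\langle 10,11\rangle$, refining within the step; the running field
transfers between grids and resolutions through normalized node
coordinates.

For one grid, the moves are greedy: nodes are visited in a seeded random
permutation; each node is tried down then up by $\delta$; a move is kept
only if it strictly lowers the total energy. On acceptance the node's
in-bounds 4-neighbours are appended to the queue (no deduplication) and
half- and one-and-a-half-sized variants of the shift are scored, the
best of the three winning with ties resolved toward the smaller shift.
Sweeps repeat until a full pass accepts nothing, then the next grid (or
step) begins. Accepted-move energies are therefore strictly decreasing
within a move type, and the whole run is bit-reproducible from its seed,
which is the optimizer's only source of randomness (the caller's RNG
state is restored).

The regularizer weights are divided by the pixel count of the image at
each pyramid level, making energies comparable across levels and lane
sizes.

### Parameter defaults and calibration

| parameter | default | meaning |
|---|---|---|
| `wx` | 0.05 | shear penalty, per px of absolute x-difference (size-normalized) |
| `wy` | 0.025 | normal-strain penalty, per px of absolute y-difference |
| `p` | 1 | exponent of $f(c) = (1-c)^p$ |
| `min_overlap` | 8 rows | minimum shared non-missing rows per column pair |
| `rx, ry, rz` | 15, 300, 40 | rolling-ellipsoid radii |
| $\delta_j$ | 8, 4, 2, 1 px | node shift per hierarchical step |

`wx` and `wy` were calibrated on a training set of simulated lanes
(generator seeds disjoint from any seeds used in the test suite): they
are the smallest round values at which band-free lanes acquire about 1 px
of unnecessary deformation — matching what is achievable on real
band-free profiles — while band straightening remains essentially
unimpaired (mean residual band SD about one sixth of the input SD).
Substantially smaller weights leave the noise-driven correlation gain
unopposed and band-free lanes pick up 2 px or more of spurious warp;
substantially larger ones start to resist legitimate corrections of
faint bands.

## The synthetic lane generator

Real membrane data cannot be shipped, so the generator produces lanes
with known ground truth; it defines the package's study conditions:

* **Geometry**: 480 rows x 190 columns. 190 px is the real lane pitch of
  a 600-dpi membrane scan (ten lanes across a ~1905-px-wide image); 480
  rows is a representative IgG-zone height at the same scale.
* **Bands**: count uniform on {1..12}; positions uniform over the lane
  height; FWHM $= 7 + \mathrm{Exp}(\text{mean } 7)$ px (floor 7 px, mean
  14 px); Gaussian profiles, constant across columns; peak amplitudes
  log-uniform on [8, 80] intensity units, exercising the faint-band
  regime.
* **Background**: a procedural smooth 1-D vertical profile (base level
  plus 3-6 broad Gaussians, amplitudes <= 25 units, lightly smoothed)
  replicated across columns; a hook accepts real band-free profiles
  where available.
* **Deformation**: per-pixel uniform noise smoothed with a 2-D Gaussian
  kernel (sigma uniform on [30, 80] px) and rescaled to a maximum
  absolute shift uniform on [2, 10] px.
* **Degradation**: Poisson(3) missing-value disks with radii uniform on
  [2, 10] px; multiplicative speckle noise of unit mean and variance
  0.01.

The ground-truth band midlines are the deformed positions
$y_b(x) = p_b + \Delta Y_{\text{true}}(x, p_b)$, so evaluation needs no
band detection. What the simulator does *not* emulate: band-shaped
artifacts, lane-edge curvature (rectification is tested separately on
constructed geometries), intensity saturation, and spatially correlated
scanner noise. Passing the synthetic suite therefore demonstrates the
geometry-recovery machinery, not robustness to every real-world artifact
class.

A consequence of the bounded smooth deformation (max 10 px, smoothing
sigma >= 30 px) is that midline SDs above ~4 px are rare: across one
hundred seeded lanes only a handful of bands exceed 4 px and very few
exceed 5 px before straightening. The evaluation counts below those
thresholds are correspondingly small.

## Evaluation protocol

Deformation of a band midline $y(x)$ is its population SD over the
integer columns of its extent, $\mathrm{SD}_x(y(x))$; after straightening
it is $\mathrm{SD}_x(y(x) + \Delta Y(x, y(x)))$ with $\Delta Y$ sampled
bilinearly. Population rather than sample normalization is used because
a midline is a fully observed curve, not a sample (this makes the
$\sqrt 2$ value of the 5-point ramp example well defined). Bands with an
input SD at or below 1 px are excluded from before/after comparisons:
that is within annotation variability and irrelevant to peak detection.
The remaining bands are counted against thresholds $t = 2, 3, 4, 5$ px
before and after, and the ratios $\rho_t = \text{num}^{\,t}_{\text{before}} /
\text{num}^{\,t}_{\text{after}}$ summarize the improvement ($\infty$ when
a threshold count empties; 0/0 is reported as absent). For band-free
lanes the unnecessary deformation introduced is the mean over rows of the
per-row SD of the field.

The tracing-assistant warp (`straighten_from_annotations()`) maps each
annotated midline to the horizontal line at its mean height,
interpolating shifts linearly in $y$ between lines and extending them as
constants beyond. The continuous map flattens annotated bands exactly;
its rasterization to a per-pixel field is exact away from the annotated
lines' kinks and accurate to interpolation resolution (a few hundredths
of a pixel) across them.

## Numerical choices and degenerate inputs

* Warping inverts the per-column forward map $t(y) = y + \Delta Y$ by
  linear interpolation; if a fold makes $t$ non-monotone the first
  crossing from the top is used. Targets outside $[t(0), t(H-1)]$ are
  missing; an interpolation endpoint with exactly zero weight does not
  propagate its missing status, so the zero field is an exact identity.
* Rectification treats edge contours as half-open ($[x_l, x_r)$, width
  $x_r - x_l$), uses sub-pixel linear resampling, and flags out-of-lane
  columns missing.
* Acceptance requires a strict energy decrease; among refinement
  candidates ties go to the smaller shift. A move type also stops at a
  safety cap of 100 sweeps (never reached in practice; energies are
  bounded below and strictly decreasing).
* Degenerate inputs error early: lanes narrower than 2 px, lanes shorter
  than the coarsest grid, all-missing lanes, crossing annotations,
  single-column band extents.
* The pipeline processes lanes of the default geometry in about one
  second each; the test suite's hundred-lane protocol and the
  distributional checks in `scripts/acceptance.R` use the problem sizes
  stated above as the package's study conditions.

## Known limitations

* Purely vertical correction: residual horizontal misalignment after
  rectification is untouched.
* Low-contrast bands in noisy lanes straighten less reliably — the
  correlation signal they contribute is weak relative to speckle.
* The greedy search can stall in local minima of the coarse lattice;
  the hierarchy and the 0.5x/1.5x refinements mitigate but cannot
  exclude this (on tiny enumerable instances the greedy result matches
  exhaustive search when the move magnitude is commensurate with the
  needed correction).
* The rolling ellipsoid retains along-y background structure sharper
  than its own curvature, as discussed above; downstream peak detection
  should expect a non-flat baseline in that regime.
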