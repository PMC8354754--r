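---
title: "Methods: from two-photon stacks to an inflammation index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from two-photon stacks to an inflammation index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mgmorph)
```

This vignette records the model, the tunable parameters, the numerical
choices, and the limits of what the test suite establishes. It states no
empirical result that the tests or the acceptance script do not themselves
compute.

## The measurement problem

Activated microglia retract and thicken their processes and enlarge their
soma. A single shape metric (say, perimeter) captures only a slice of that
change, while testing all plausible metrics invites multiple-comparison
trouble. The pipeline therefore measures many descriptors per cell and lets
labelled training data decide, via ROC analysis and a PCA, which weighted
combination best tracks activation. That combination — the inflammation
index — is then frozen and applied unchanged to novel data.

## Stack cleaning

Input stacks are 4-D: several frames per Z plane, ordered frame-within-plane.
Cleaning has four stages, each with an explicit parameter:

* **Contrast normalisation.** Every frame is linearly rescaled to the
  mean/s.d. of the reference plane's mean frame (middle plane by default),
  clipped to the dtype range. Constant frames are left alone and flagged.
* **Blur scoring.** `blur_score()` is the standard deviation of the
  Laplacian-of-Gaussian response. The LoG scale (`sigma_log`, default
  1.5 px) is a package decision: the reference method description names the
  filter but not its scale. The score is invariant to additive intensity offsets and
  strictly decreasing under repeated Gaussian blurring; the maximum of the
  response (`method = "max"`) is implemented only as the demonstrably
  inferior comparator — on textured cell frames it is not monotone in blur.
* **Frame selection.** The `k_sharp = 3` sharpest frames are mutually
  registered (integer-pixel translation via FFT cross-correlation, ties
  broken towards the smallest shift) and averaged into a reference; all
  frames are registered to it, ranked by mean absolute difference *over the
  registered overlap only* (edge fill must not dominate), and the
  `k_keep = 2` least-different frames are averaged. Both counts are
  user-settable; 3 and 2 are the reference defaults.
* **Z reordering.** Plane similarity is the peak normalised
  cross-correlation over integer shifts — translation-invariant, because
  each cleaned plane inherits the arbitrary jitter of its anchor frame.
  Planes are chained greedily from the least-similar plane (a path
  endpoint), appending the nearest unused neighbour. Only the *order* is
  recovered (a global reversal is accepted as equivalent); continuous
  Z-position estimation is out of scope.
* **QC.** A plane is flagged when its residual difference exceeds 3× the
  median across planes — a reproducible stand-in for the manual "discard
  ruined planes" step. A stack with every plane flagged is rejected.

## Segmentation

Seeds are local maxima of depth-substack projections (10 µm substacks
separated by 20 µm gaps, so a cell is sampled once). The projection is
smoothed at roughly soma scale (σ = 3 px) before maxima detection;
prominence defaults to 10% of the dynamic range and seeds closer than
20 µm are suppressed, brightest first. On ramified cells bright process
clusters can produce additional candidate seeds; these either fail
segmentation or are removed by the review policy, mirroring the manual
seed-editing step the original workflow expects.

Each seed gets a 120 × 120 µm ROI. The mask is the 8-connected
supra-threshold component containing the seed, and the threshold is
iterated as

\[ T_{I+1} = T_I + T_I\,\frac{A_I - MS}{n\,MS} \]

from an ROI-local Otsu start (ROI-local, rather than whole-frame,
thresholding follows the reference workflow). Acceptance requires the area within
`limit` (±100 µm² default) of the target `MS`; iteration stops when the
area stabilises (relative change < 0.5% across three consecutive
iterations — the stated rule gives no tolerance, this is ours) or after
`max_iter = 25` iterations (no cap is stated). Thresholds driven above the
ROI maximum terminate the loop. One deliberate deviation, recorded in the
status enum: masks that stabilise *outside* the target band are labelled
`rejected_unstable` rather than accepted, keeping the invariant
"accepted ⇒ |area − MS| ≤ limit" exact; cells therefore drop out at
unsuitable mask sizes, which is also how the original workflow behaves in
practice. Accepted masks within 5 µm of the ROI edge are rejected.

Soma detection Otsu-thresholds the ROI and keeps particles intersecting the
cell mask with area ≥ 20 µm² and circularity 4πA/P² ≥ 0.6 (perimeter from
corner-corrected boundary tracing). Exactly one survivor is the soma;
otherwise the largest disc inscribed in the cell mask (chamfer distance
transform) stands in for the manual drawing, flagged `origin = "fallback"`.
On branched cells with gently tapering processes the Otsu particle is often
the whole connected cell and fails the circularity rule, so the fallback is
common — by design it still tracks soma size, which is what downstream
features consume.

## The 62 descriptors

Five domains; all spatial quantities in µm/µm² via the calibration.

* **Simple shape (6).** Perimeter (corner-corrected boundary length), cell
  spread (mean distance from the centre of mass to the four extremity
  pixels), eccentricity (major/minor axis of the second-moment ellipse —
  the ellipse convention is ours), roundness (its inverse), soma area,
  mask area.
* **Skeleton (11).** Zhang–Suen thinning; voxels classified by 8-neighbour
  count (endpoint < 2, slab = 2, junction > 2); adjacent junction voxels
  merge into one junction node. Branch lengths are euclidean path lengths.
  "Longest shortest path" is implemented as the weighted graph diameter —
  the standard meaning of the name — although the reference description's wording
  ("the sum of the shortest path between all pairs") reads like an
  all-pairs sum; the name was trusted over the wording.
* **Sholl (27).** Circles from the soma-equivalent radius in 2 µm steps
  (both numbers are package decisions). Intersections are counted by
  clustering annulus pixels by angle — robust on 1–2 px digitised
  processes. Primary branches are skeleton crossings of a circle 1 px
  outside the soma radius. The "best fit polynomial" is chosen by BIC among
  degrees 1…min(30, n−2), with a numerically-perfect fit short-circuiting
  to the lowest such degree. Sampled statistics use the raw counts (the
  reference plugin's convention — so a symmetric triangular profile has
  only approximately zero skewness); fit statistics evaluate the polynomial
  at the sampled radii. Skewness is Fisher–Pearson g1 and kurtosis is
  m4/m2² (non-excess). Regressions take log10 of positive counts against
  radius (semi-log) or log10 radius (log–log), whole profile and within the
  10th–90th percentile radius window.
* **Hull and circularity (15).** Convex hull of mask pixel centres; hull
  area/perimeter/circularity; maximum span and the span ratio
  (major span over the perpendicular extent); radii measured to hull
  vertices from both the hull's area centroid and the centre of the exact
  minimum enclosing circle (brute-force over hull vertex pairs/triples —
  exact and tiny). The "maximum radius" features report maxima, as their
  names say, where the reference description's prose repeats the word "mean".
* **Fractal (2).** Box counting on the mask outline over dyadic box sizes
  (2 px up to a quarter of the image side), four half-box grid offsets,
  grids anchored at the mask bounding box — making both features exactly
  translation invariant. Lacunarity is the mean over sizes and offsets of
  (σ/μ)² of per-box masses of the filled mask.
* **Branching density (1).** Skeleton area over hull area.

The schema is frozen: `extract_features()` always returns exactly these 62
names, with failed sub-domains reported as `NA` plus a reason.

## Index construction

Features are ranked by folded AUC, `max(AUC, 1−AUC)`, since a
discriminator may point either way (the folding is our choice; the reference
method ranks by AUC without addressing direction). Variant families — the
percentile-window, sampled/fit and hull-centre/circle-centre duplicates —
keep only their best member; then, scanning from the top of the ranking,
any feature correlated at |r| ≥ 0.9 with an already-kept feature is
dropped (the reference description does not fix a pruning order; greedy
from the top is deterministic). PCA runs on the standardised survivors;
PC1's sign is fixed so the activated training mean is the higher one, and
the sign is stored in the model so novel-data scores stay comparable.
Mask size and feature count are both chosen by the training AUC of the
resulting index (ties: smaller mask, fewer features), with a
random-intercept-model p-value as the alternative criterion. Group
comparisons fit `index ~ condition + (1 | animal)`; the p-value is a
likelihood-ratio test against the intercept-only model (ML refit), and the
standardized effect size is Cohen's d with pooled s.d. — the reference
method reports a standardized effect size without naming the formula.

## The synthetic world

`generate_cell_image()` renders a filled soma disc plus processes walked in
~1 px steps with heading noise proportional to tortuosity, stamped as a
swept disc of radius 1 (≈2 px width for any direction, keeping rendered
area within 10% of the analytic disc-plus-rectangles value). Foreground is
200 and background 20 on an 8-bit scale before noise; branch intensity
tapers to ~140 at the tips. The taper is deliberate: with flat foreground
the area–threshold curve of the iterative-threshold loop is a step function
and no intermediate area is reachable, whereas real two-photon microglia
have dimmer distal processes — the taper is what makes the target-area
iteration meaningful, and it was fixed at design time, not tuned to tests.

`generate_raw_stack()` models a through-focus volume as a 1 px/plane
lateral drift plus an AR(1) chain (ρ = 0.85) of smooth background fields
(s.d. 18), so inter-plane similarity decays monotonically with true Z
distance and reordering is learnable; corruption adds per-frame jitter,
per-frame Gaussian blur schedules and additive noise.

`generate_condition_dataset()` fixes the stated world of the recovery
experiments: resting cells have soma radius 3.5 µm, six primaries of mean
30 µm; activated cells 5.0 µm soma and three primaries of 12 µm, with
8–15% per-cell variability — a deliberately strong, LPS-like contrast.
What a green end-to-end test establishes is that the pipeline recovers a
*strong, known* morphology contrast through segmentation, measurement and
index training, and that a zero contrast yields chance-level held-out AUC.
It does not establish sensitivity to subtle in vivo effects, robustness to
densely overlapping cells, or 3-D effects (the pipeline measures 2-D
projections by design).

## Numerical and scope notes

* Registration is integer-pixel only; sub-pixel interpolation would blur
  the averages it feeds.
* TIFF support is a built-in minimal codec (uncompressed greyscale
  multi-page, either byte order on read) because no TIFF reader is
  available in the dependency footprint; it is not a general TIFF parser.
* The zero-effect null control runs on feature tables with latent
  correlation structure rather than 20 rendered replicates: under a zero
  effect the two groups are identically distributed by construction, so
  rendering adds no group information, and table-level replication keeps
  the suite inside its time budget.
* Known limitations: no dual-channel (vasculature) registration, no
  non-rigid motion correction, no 3-D Sholl, no claim of numeric parity
  with the original ImageJ/FracLac plugins.
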