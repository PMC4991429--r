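---
title: "Vessel morphometry: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vessel morphometry: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselmorph)
```

# The measurement problem

CD31 immunohistochemistry stains the endothelial lining of blood vessels
brown (DAB) over a blue-grey hematoxylin counterstain. A vessel cross-section
therefore appears as a brown ring — often incomplete, because the plane of
section misses part of the wall, the endothelium is discontinuous (as in
sinusoids), or staining fails locally. Naive thresholding counts stained
*wall* pixels; the biologically meaningful object is the whole vessel,
wall plus lumen. `vesselmorph` therefore:

1. unmixes the DAB signal by colour deconvolution in optical-density space,
2. thresholds it within a tissue mask,
3. **seals open outlines** by morphological closing with a small disk,
4. fills enclosed lumina and labels 8-connected regions,
5. measures each region with a size/shape descriptor suite, and
6. classifies it into a microvascular segment by caliber.

## Stain separation

Pixel intensities are converted to optical density per channel,
$OD_c = -\log_{10}((I_c + 1)/256)$, and projected onto a three-vector basis:
the hematoxylin OD direction, the DAB OD direction, and their normalised
cross product as residual axis (the standard two-stain deconvolution
construction). Defaults are the Ruifrok–Johnston H-DAB vectors,
H = (0.650, 0.704, 0.286), DAB = (0.269, 0.568, 0.872), unit-normalised;
both are configurable because scanners and staining protocols shift the
effective vectors. Negative projections are physically meaningless and are
clamped to zero.

Assumptions: Beer–Lambert additivity of the two chromogens and at most two
stains per pixel. Heavy co-localisation (DAB over dense nuclei) biases the
DAB estimate upwards; for vessel walls over stroma this is minor.

## Tissue and stained-pixel masks

A pixel is tissue when it is visibly coloured (HSV saturation ≥ 0.08) or
dark (value ≤ 0.85); bright unsaturated pixels are glass. Holes smaller than
1000 µm² are filled (lumina and staining dropouts), larger holes are kept as
genuine non-tissue (tears, vessels' open spaces at tile edges, TMA core
boundaries). The stained mask is DAB OD above a threshold — Otsu's method on
within-tissue OD values by default, with a floor of 0.1 OD so that a
DAB-free tile produces an *empty* mask instead of an arbitrary split of
background noise; a fixed threshold is available when batch consistency
across tiles matters more than per-tile adaptation.

## Closing, filling, labeling

Closing uses a disk of radius 2.5 µm by default — about half a capillary
wall thickness: it seals outline gaps narrower than 5 µm while leaving
distinct vessels (treated as ≥ 10 µm apart in the phantom model) separate.
Closing is extensive and idempotent, both properties the test suite asserts.
Enclosed holes are then filled, so descriptors see wall + lumen; the
whole-vessel convention is our design decision (the caliber language of
vascular taxonomy refers to the full vessel, and reported widths of ~7 µm
for a mean vessel only make sense wall-inclusive). It is configurable
(`include_lumen = FALSE`) for users who want wall-only geometry. Components
are labeled 8-connected (foreground) / 4-connected (background); regions
below 12 µm² are discarded as chromogen specks — small enough to keep every
5 µm capillary. Border-touching regions count toward density and stained
area but are excluded from shape statistics, since their geometry is
truncated; this too is a switch.

# The descriptor suite

With $mpp$ the calibration in µm/px:

* **area** $= N \cdot mpp^2$ over filled pixels;
* **perimeter**: arc length of the outer contour traced by marching squares
  at level 0.5, then smoothed with a 3-point circular moving average of the
  vertices. The raw staircase polygon overestimates a digital disk's
  perimeter by ~6%; after smoothing a radius-50 px disk measures roundness
  1.020 and a 100 px square 1.258 against the 4/π = 1.273 closed form.
* **length/width**: full axes of the equivalent ellipse, i.e. $4\sqrt{\lambda}$
  for the eigenvalues λ of the second-central-moment matrix divided by the
  pixel count. A Feret-diameter alternative (`axis_mode = "feret"`) is
  provided because some tools define length/width as caliper diameters; the
  ellipse convention is the default since the equivalent ellipse is the
  reference shape the aspect descriptor is defined on. Degenerate
  (collinear) regions get a one-pixel width floor.
* **aspect** = length/width; **roundness** = perimeter²/(4π·area).
* **convex contour**: hull of the traced contour vertices; **perimeter
  ratio** = hull perimeter / perimeter; **deformity** = (hull area − area)
  · $mpp^2$.
* **shape factor**: Hu invariant moments $h_1..h_7$ are computed from the
  normalised central moments of the filled region (A) and of its filled
  convex hull (B), log-scaled as $m_i = \mathrm{sign}(h_i)\log_{10}|h_i|$,
  and compared as $\max_i |m_i^A - m_i^B| / |m_i^A|$.
* **branching**: Zhang–Suen thinning of the filled region, spur pruning,
  then branch nodes where the crossing number (circular 0→1 transitions
  around the 8-neighbourhood) is ≥ 3.

## Numerical choices worth knowing about

**Hu moments on regions, not curves.** Moments are taken over filled pixel
sets (point masses at pixel centres): region moments are numerically stable,
whereas 1-px contour-curve moments are dominated by discretisation. The
disk's $h_1$ has the closed form $1/(2\pi)$; the rasterised value at
r = 50 px agrees within 1%, and all seven invariants agree with a
brute-force raw-moment double sum to ~1e−9 relative.

**Noise floor in the shape factor.** For symmetric shapes the higher Hu
invariants vanish in the continuum, so their rasterised values are pure
alignment noise; their log ratios would swing arbitrarily with rotation.
Invariants with $|h_i| < 10^{-6}$ in either shape are therefore skipped
(and indices with $|m_i^A| < 10^{-12}$, to avoid division blow-ups). The
index set itself is configurable (`hu_index_set`); the default uses all
seven, which with the noise floor reduces gracefully to the informative
subset per shape.

**Branch counting.** Thinning a blunt-ended tube produces diagonal corner
spurs (the medial axis of a rectangle has four corner branches), so spurs
are pruned by deleting endpoints to a depth of the maximum
distance-transform value (the local tube radius) plus 2 px, and the
skeleton re-thinned. An n-way anatomical junction decomposes under thinning
into several nearby 3-way nodes; branch pixels closer than half the local
radius are merged before counting, so a plus-shaped tube counts one node,
not two. Consequences to be aware of: a straight tube counts 0, a Y-tube 1,
and a star-shaped cistern — whose skeleton genuinely branches into its
lobes — counts 1.

**Tie-breaks and degenerate inputs.** Caliber bands are half-open with the
boundary in the upper class (a 15 µm width is a post-capillary, not a
capillary). Vessels narrower than `min_width` (3 µm) are excluded from
classification with a logged reason. A tile with no detectable tissue
yields a summary row with `tissue_area_mm2 = 0` and undefined densities
rather than an error; an unreadable tile is skipped with a warning and the
batch continues.

## Caliber bands

Only two calibers are anchored in the morphology of CD31-stained tumour
sections: capillaries at roughly 5–15 µm and sinusoids at roughly 20–50 µm.
The intermediate post-capillary/metarteriole band (15–20 µm), the
venule/arteriole band (50–100 µm) and the ≥ 100 µm vein/artery band are
interpolations/extrapolations consistent with vascular physiology, and all
five edges are configurable (`segment_thresholds()`). Width (the minor
axis) is the classifying caliber because it is robust to elongation — a
long capillary running in-plane is still 10 µm wide. Shape-assisted
classification (sinusoids are also more irregular than size-matched
venules) would be a natural extension but is deliberately not implemented:
caliber is the stated taxonomy, and mixing shape into the class definition
would make the per-segment shape statistics circular.

# The synthetic phantom model

`render_phantom_tile()` emulates what the segmentation stage actually sees:
DAB-brown vessel walls (OD 0.9 along the DAB vector) on a
hematoxylin-tinted tissue background (OD 0.15), optional white non-tissue
margin, and i.i.d. Gaussian pixel noise (sd 4/255) — enough to exercise
thresholding without modelling scanner physics. Six wall morphologies are
available: closed rings, open rings (a configurable fraction of the
circumference missing, emulating interrupted endothelium), elliptical
rings, straight tubes (capsules), three-armed branched tubes and star
cisterns.

**Caliber is defined as the equivalent-ellipse minor axis** of the filled
shape, for every morphology. This keeps the generator's ground truth and
the pipeline's measurement on one scale; it matters because second moments
of non-elliptical shapes do not track naive geometric widths (a rectangle's
moment width is 1.155× its side; a 3-fold-symmetric Y-tube has isotropic
moments, so its minor axis tracks arm span, not tube width). Each shape's
scale is calibrated against exact polygon (Green's-theorem) moments, or a
short fixed-point iteration on the rasterised mask where no closed polygon
model exists (branched tubes). The generator's self-consistency — caliber
within 5% of the measured minor axis — is a tested invariant.

The default study layout (`default_phantom_specs()`) is a 0.5 × 0.5 mm
tile at 0.5 µm/px carrying 30 vessels: 10 capillaries (8–12 µm), 5
post-capillaries & metarterioles (17–18 µm), 10 sinusoids (25–45 µm) and 5
venules & arterioles (62–88 µm), calibers evenly spaced within each band
and at least 2 µm from every band edge, all vessels ≥ 10 µm apart,
open-ring gaps kept under the 5 µm sealing limit of the default closing
radius. Generation is bit-deterministic given the seed.

What the phantom does *not* emulate — and what passing tests therefore do
not show about real tissue: out-of-focus blur and chromatic aberration,
stain intensity gradients, touching or overlapping vessels, CD31-negative
("mosaic") vessel walls, nuclei and immune-cell clutter, hemorrhage, and
genuinely three-dimensional branching (a 2-D section of a branching vessel
rarely shows the junction). Detection on real slides will be strictly
harder than the 100% phantom recovery; the phantom establishes that the
measurement chain itself is unbiased.

# Validation scales

The test-suite and acceptance fixtures run at sizes where discretisation
error is comfortably inside the asserted tolerances: disks at r = 50 px,
squares at 100 px, 2:1 ellipses at 40 × 20 px, and stars at
R_outer = 50 px for value checks but 80 px for rotation-invariance checks —
the 36° star tips lose their outermost ~1.5 px to rasterisation, an
angle-dependent effect that exceeds 2% of the perimeter at R = 50 but not
at R = 80. The full phantom study (10⁶ px, 30 vessels) runs in seconds.

# Known limitations

* Overlapping or touching vessels are merged into one region; no watershed
  split is attempted (a split would need a lumen model to be trustworthy).
* The Otsu threshold is per-tile; absolute SA% comparisons across tiles
  with very different staining intensity should use a fixed OD threshold.
* Branch counts on real, noisy masks depend on the pruning depth heuristic;
  treat "branched vs unbranched" as more robust than the node count itself.
* Perimeter (and hence roundness) carries ~1–3% discretisation error at
  capillary scales (10–20 px across); width and area are substantially more
  accurate.
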