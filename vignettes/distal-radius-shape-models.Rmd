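---
title: "Statistical shape modelling of the distal radius: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical shape modelling of the distal radius: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radiusSSM)
```

## What this package computes

`radiusSSM` implements a population-level shape analysis of the distal
radius as one pipeline:

1. **Surface models.** Each specimen is a watertight triangulated surface
   in millimetres, either loaded from PLY/STL/OBJ (or extracted from a
   binary segmentation mask) or generated synthetically.
2. **Alignment.** All specimens are brought into one standardized
   anatomical frame (+z distal, +y dorsal, +x lateral for a right bone):
   rigid iterative-closest-point registration to a reference specimen,
   followed by generalized Procrustes alignment (GPA) of the corresponded
   landmark sets.
3. **Correspondence.** A dense, ordered landmark set is defined on a
   template (the reference specimen) and transferred to every other
   specimen by exact closest-point projection onto its surface.
4. **Point Distribution Model (PDM).** Principal-component analysis of the
   aligned 3n-dimensional landmark vectors: a mean shape, orthonormal
   variation modes and eigenvalues. The shape variability of a group is
   summarized by the number of modes needed to explain 95% of the total
   variance (inclusive rule at the boundary). Models are fitted overall
   and separately per gender and side.
5. **Standardized cut planes.** Two anatomical landmarks are detected on
   each standardized surface -- the styloid apex (maximal axial
   coordinate) and the most dorsal point of the dorsal (Lister's)
   tubercle, searched within the distal quarter of the axial extent.
   With z~s~ and z~t~ their axial coordinates and d = z~s~ - z~t~, three
   planes perpendicular to the main axis are placed at z~t~ (distal),
   z~t~ - d/4 (middle) and z~t~ - d/2 (proximal). Each plane-mesh
   intersection is chained into a closed polygon and described by four
   morphometric parameters: maximum width (medio-lateral extent), maximum
   depth (dorso-volar extent), perimeter and area.
6. **Statistics.** Group descriptives, Lilliefors-corrected
   Kolmogorov-Smirnov normality checks, pooled-variance t-tests for
   gender and side, and one-way ANOVA across the three planes with
   Bonferroni post-hoc tests. With four morphometric parameters the
   multiple-testing threshold is alpha = 0.05/4 = 0.0125 (conventionally
   printed as 0.013); the exact value is used for decisions.
7. **Classification.** Leave-one-out cross-validation with a random
   forest (50 trees) on the shape-model coefficients, for side, for
   gender, and step-wise (side first, then gender within the predicted
   side; a combined prediction counts only if both labels are correct).
   "100 iterations" are 100 repetitions of the complete LOOCV sweep with
   fresh forest randomness -- the only reading under which a *median*
   accuracy across iterations is meaningful. The median of per-specimen
   true-class probabilities is retained as a secondary output.

## The synthetic population

No clinical imaging data ship with the package; instead a parametric
generator produces distal-radius-like bones with known ground truth, so
every stage of the pipeline is testable end to end.

**Geometry.** A superellipse cross-section (half-width a(z), half-depth
b(z), exponent p(z), linearly interpolated between stations) is swept
along a gently bowed axis; two prominences are added: a dorsal tubercle
bump (Gaussian in angle and axial position, centred *lateral of the
dorsal midline*, as Lister's tubercle is) and a distal rise of the rim
towards the styloid apex. The rise is angularly wide by design: it
emulates the ulnarly inclined articular surface, so the lateral half of
the distal rim sits more distal than the medial half. Left bones are
exact mirror images of right bones. These two features make the bone
chiral, which is what allows a classifier to recover side from shape at
all; a plain swept superellipse would be mirror-symmetric and side would
be undetectable -- an important difference from real radii, whose whole
dorsal/volar architecture is chiral.

**Calibration.** The default station profiles are solved at load time so
that the *analytic* cross-sections of the mean bone at the three plane
heights reproduce bundled published reference morphometrics of adult
female distal radii (width 29.0 mm, depth 21.0 mm, area 472.6 mm^2
distally; 28.2/19.5/427.5 at the middle plane; 26.3/17.2/353.2
proximally). Half-widths come directly from the widths; the half-depth
and superellipse exponent are found by root-finding on the exact contour
(the distal plane passes through the tubercle bump, so both relations are
implicit). The distal plane is the single calibration anchor; the middle
and proximal stations implement a fixed taper taken from the same
reference table, which avoids an over-determined fit. Mean geometry
constants (segment length 70 mm, styloid rise 6 mm, tubercle at z-fraction
0.886) place the styloid-tubercle axial distance at 14 mm, i.e. planes
3.5 mm apart on average.

**Population model.** Each specimen draws an isotropic size factor
(mean-one log-normal; males additionally scaled by 33/29, the reference
male/female distal width ratio) and mean-one shape factors for
width/depth aspect, segment length, taper exponent, tubercle prominence,
curvature, squareness and styloid height, plus iid per-vertex Gaussian
noise (default SD 0.05 mm) emulating segmentation jitter. The size SD
(0.06) and the width/depth aspect SDs are solved so the pooled
distal-plane width and depth SDs match the reference values (2.1 and
1.7 mm). Sides have identical means (mirroring only); on left specimens
the *shape* factor SDs -- not the size factor -- are multiplied by
sqrt(`side_variance_ratio`). This reproduces the qualitative published
pattern of equal sizes but higher left-side shape variance: inflating the
minor factors flattens the left eigen-spectrum, so the left model needs
more modes at the 95% threshold, whereas inflating everything uniformly
(size included) would leave mode counts unchanged.

**What the generator does not emulate.** Cortical/trabecular interior,
the sigmoid notch and articular facets, the volar tilt, age effects, and
realistic perimeter irregularity: real distal sections are non-convex
with perimeters near 86 mm at 29 x 21 mm extents, while a convex
superellipse of the same extents has a perimeter near 79 mm. Perimeter is
therefore deliberately *not* a calibration anchor (width, depth and area
are). Passing tests show the pipeline machinery is correct and the
calibration closes; they do not show that clinical accuracy figures
transfer.

## Numerical choices

* **ICP.** Point-to-point ICP with exact closest-point-on-surface
  correspondence, warm-started and finished by cheap nearest-vertex
  phases; the final vertex polish is adopted only when it does not worsen
  the point-to-surface residual, so the reported residual trace is
  monotone. Pure nearest-vertex matching is not used as the main
  correspondence: on densely meshed surfaces its tangential snapping has
  fixed points well above the true minimum. Coarse initialization by
  principal axes is available; the reference specimen is the first in
  the manifest unless overridden.
* **GPA** iterates Kabsch superposition against the evolving mean to a
  1e-9 mean-change tolerance. Scaling is off by default: size carries the
  gender signal and the morphometrics, so removing it would destroy the
  analysis target. With scaling off, centroid sizes are preserved
  exactly.
* **Correspondence** replaces description-length-style optimization with
  template projection: exact on this synthetic family, where every
  specimen is a smooth deformation of the template, and leaves the
  module interface open for a drop-in refinement. The projection guard
  (default 10 mm for a single registered specimen) is raised to 40 mm in
  the population pipeline, where honest size spread concentrates at the
  styloid tip; gross misregistration shows up at bone-length scale.
  Projection across sides (left template onto right bones) is geometric,
  not anatomical -- which is precisely why side information survives into
  the coefficients, but also why only the side model matching the
  reference's side gets mean-surface morphometrics.
* **PDM** eigendecomposition uses the SVD of the centred data matrix
  (rank-safe for n_samples << 3n), covariance divisor n-1, and a
  deterministic sign convention (largest-magnitude entry of each mode
  positive). Classification uses the full coefficient vector: the 95%
  threshold defines the *reported* mode count, but discriminative
  side differences legitimately sit in later modes.
* **Cross-sections** chain triangle-plane segments by their shared mesh
  edges (exact, no floating-point matching); vertices exactly on the
  plane are avoided by a deterministic 1e-9-scale nudge of the plane.
  Multiple loops (possible near the styloid) resolve to the
  largest-area loop. Width and depth are axis-aligned extents in the
  standardized frame, not rotating-caliper diameters, matching the
  radiological convention of medio-lateral/dorso-volar measurement; the
  proximal offset d/2 is measured along the main axis, consistent with
  planes being defined by axial positions.
* **Isosurfacing** of binary masks extracts boundary faces (surface
  nets), triangulates, applies shrink-free Taubin smoothing and rescales
  about the centroid so the enclosed volume equals the exact foreground
  voxel volume. This keeps single-voxel masks honest (volume exactly one
  voxel) while converging to smooth-surface areas within a few percent at
  sub-millimetre spacing -- a combination a midpoint isosurface of binary
  data does not achieve.
* **Remeshing** refines by conforming midpoint subdivision (never moves
  the surface) and coarsens by half-edge collapses guarded by the link
  condition and a 20-degree face-normal rotation cap, which preserves
  creases and volume.

## Problem sizes used in the tests

The shipped test-suite and acceptance checks run at deliberately modest,
fixed sizes chosen to exercise every claim while staying desk-scale:
geometry oracles at 0.2-0.5 mm equivalent resolutions; spectrum recovery
at 200 samples x 50 landmarks; classifier sanity at 40 specimens;
the end-to-end population run at 40 specimens, 1.5 mm edges,
full-vertex templates and `side_variance_ratio = 3` (the value also used
in the generator's own documentation examples for the mode-count
contrast; the package default is 2); and the calibration round-trip at
500 sampled parameter sets with analytic sections, or 500 full meshes at
1.2 mm edges in `scripts/acceptance.R`.

## Known limitations

* Template projection without refinement degrades when specimens are not
  smooth deformations of the template; real clinical populations would
  warrant a correspondence-optimization step behind the same interface.
* Mean surfaces of side-blended models (overall and per-gender) are not
  anatomically meaningful under unmirrored cross-side correspondence and
  are not sectioned.
* Published accuracy and mode-count figures of clinical CT populations
  depend on those specimens and are reproduced only directionally
  (side easier than gender, more left modes than right, male > female
  everywhere, monotone distal-to-proximal decrease).
* The Lilliefors normality check requires n >= 4.
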