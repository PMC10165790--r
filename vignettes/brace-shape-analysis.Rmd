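---
title: "Torso asymmetry and brace-fit analysis: methods and design"
author: "BraceMorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Torso asymmetry and brace-fit analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Rigid bracing is the standard conservative treatment for adolescent
idiopathic scoliosis (AIS), and the radiographic *initial in-brace
correction* (IBC) — the percentage reduction of the major-curve Cobb angle
when the brace is first worn — is a strong predictor of long-term treatment
success. When braces are designed with CAD tools, the designer has two 3D
artefacts per patient: the torso surface scan and the virtual brace model.
BraceMorph quantifies these artefacts with two families of shape measures
and relates them to IBC across a cohort:

1. an **asymmetry index** for any watertight surface (torso or brace):
   how far the shape deviates from its own mirror image, as a volume
   percentage;
2. a **signed torso-to-brace displacement field** whose positive part marks
   *pressure zones* (brace surface inside the torso) and whose negative part
   marks *expansion zones* (brace surface outside the torso), summarised by
   the peak positive and peak negative displacement in each of 12 standard
   torso segments.

Because patient scans are not publicly available, the package ships a
synthetic phantom and cohort generator with known ground truth; every
pipeline stage is exercised against analytic or brute-force oracles.

## Coordinate and mesh conventions

All meshes are triangulated surfaces in millimetres with +x = patient left,
+y = anterior, +z = superior. Faces use consistent winding; watertight
solids are oriented outward (signed volume > 0). `readMesh()` (STL, PLY,
OBJ) merges duplicate vertices within 1e-6 mm and drops degenerate faces
(area below 1e-12 mm^2), recording both counts. No unit autodetection is
attempted: CAD exports are taken at face value, since silent unit guessing
is a classic source of wrong results.

## The asymmetry index

The chain implemented in `asymmetryIndex()` is:

1. **Mirror plane.** The clinical workflow places the mid-sagittal mirroring
   plane manually; a reproducible pipeline needs a deterministic rule.
   `estimateMidsagittalPlane()` takes the plane through the vertex centroid
   whose normal is the principal axis of the vertex cloud most aligned with
   the left-right direction (the dominant principal direction is treated as
   longitudinal). Rank-deficient vertex covariance is an error;
   near-isotropic shapes (a sphere) trigger a warning because the lateral
   axis is then arbitrary. Every caller accepts an explicit `Plane3`
   override.
2. **Mirror.** Householder reflection of all vertices; winding is reversed
   so the mirrored solid stays outward-oriented.
3. **Registration.** The mirror is registered back onto the original with
   point-to-point ICP (`icpRegister()`): area-weighted surface samples on
   the source, exact closest points on the target surface, closed-form
   SVD/Kabsch update per iteration. Defaults: 5000 samples, convergence
   tolerance 1e-4 mm on the RMS-residual change, at most 100 iterations, and
   a mandatory RNG seed so a run is bit-reproducible. Five consecutive
   non-decreasing residuals end the loop in a warning state rather than an
   error.
4. **Trim.** Both solids are cut to the intersection of their z-ranges
   (`trimToEqualLength()`, error below 10 % overlap), with planar caps so
   they remain watertight.
5. **Volume ratio.** The "volume enclosed between" the two surfaces is
   interpreted as the volume of the Boolean symmetric difference of the two
   solids — the one reading that is sign-unambiguous and matches the shaded
   inter-surface region a designer sees. It is computed on a voxel grid
   (`interSurfaceVolume()`): both solids are voxelized on one common grid
   and cells contained in exactly one solid are counted. The index is
   100 x (symmetric-difference volume) / (volume of the trimmed original).

The denominator uses the *trimmed* original, consistent with trimming
preceding the volume measurement in the design chain; trimming planes are
horizontal in mesh z.

### Voxelization choices

Occupancy is decided by vertical-ray parity per grid column, which is exact
for watertight meshes up to grid resolution and robust against
near-coincident surfaces (where exact mesh Booleans are fragile). Column
centers carry deterministic sub-voxel offsets (~1e-6 of the pitch) so rays
do not pass exactly through shared triangle edges. The default pitch of
2 mm resolves torso-scale volumes to well under 0.5 % — identical solids
score exactly 0 on a shared grid — and a cell-budget guard (2e8 cells)
suggests a coarser pitch rather than exhausting memory. Exact analytic
solids (offset cubes, nested spheres) are used as oracles in the tests.

## Displacement field and segments

`signedDisplacementField()` evaluates, for every torso vertex, the exact
closest point on the brace triangle set (vertex, edge or interior, via a
uniform-grid spatial index), and signs the distance by a generalized
winding-number test of that closest point against the torso solid: inside
means pressure (+), outside means expansion (-), within 1e-6 mm of the
surface means contact (0). Point-to-surface distance was chosen over
point-to-vertex because it is independent of the brace mesh resolution and
strictly smaller or equal — the conservative choice. The field lives on the
torso vertices (not resampled), so its resolution follows the scan; this
mesh-dependence is accepted and documented. No registration is applied —
the scan and brace model are assumed to share a frame, as they do in the
CAD workflow; an optional ICP pre-alignment flag exists but defaults off.

`partitionSegments()` divides the torso into upper/mid/lower thirds of the
z-range ("equally divided" read as equal heights, not equal counts or
volumes), anterior/posterior by the centroid coronal plane, and
patient-left/right by the centroid sagittal plane (or a supplied one, e.g.
the asymmetry module's estimate). Boundaries are half-open and assign to
the lower/posterior/right side, so every vertex receives exactly one of the
12 labels ALU ... PRL. `segmentPeaks()` records the maximum positive and
minimum negative displacement per segment, 0 when a segment holds no value
of that sign, and flags empty segments.

## Cohort statistics

IBC is `100 * (pre - inBrace) / pre` on the Cobb angles of the chosen view;
the formula is the standard definition, and negative values (worsening in
brace) are legal. `spearmanRho()` wraps the rank correlation with
average-rank ties and flags constant inputs as undefined rather than
erroring. Strength categories follow the conventional bins on |rho|:
0.90–1.00 very strong, 0.70–0.89 strong, 0.50–0.69 moderate, 0.26–0.49
weak, <= 0.25 little if any; edges between the printed ranges are half-open
toward the lower category. No p-values are attached: with pilot-sized
groups the correlation magnitude is the object of interest, and the tables
annotate n instead.

One convention deserves emphasis: for peak-*negative* features the
correlations are computed on the **magnitude** (expansion depth in mm). A
negative rho in a `peakNegative_*` row therefore reads "a larger expansion
zone goes with less correction", which is how clinical brace studies report
these associations. Without this convention the sign of every peak-negative
correlation would flip and contradict its verbal interpretation.

## The synthetic phantom and cohort

`generateTorso()` builds a watertight generalized cylinder: elliptical
cross-sections (default half-axes 140 x 100 mm) swept over a 500 mm height
with a mild waist taper, a laterally offset centerline
(`lateralOffset * sin(pi s)` with the apex at `apexZ`) emulating coronal
curve convexity, and an azimuthally Gaussian radial bump emulating a rib
hump. Ring trigonometry is explicitly symmetrized so that zero asymmetry
parameters give a phantom *exactly* equal to its x = 0 reflection — the
null case of the asymmetry index is then true by construction, not just
approximately. The phantom is deliberately smooth rather than anatomically
detailed: it exercises every geometric operator while keeping analytic
ground truth (swept-ellipse volume, Gaussian bump volume, known pad
depths). Consequences for interpretation: passing tests demonstrate
correctness of the measurement chain, not realism of torso shapes — real
scans have creases, arms-at-side occlusions and scanning noise that the
phantom does not emulate.

`generateBrace()` displaces the torso surface along inward vertex normals
by summed Gaussian pad profiles in (z, azimuth-arc) coordinates: positive
depth is a pressure pad, negative a relief zone. Topology is preserved
(watertightness is inherited) and deformations that fold the surface are
rejected by a face-normal flip check.

`generateCohort()` draws per-patient pre-brace Cobb angles from the study
population distributions (Lenke 1: 38.4 +- 14.8 degrees; Lenke 5:
30.5 +- 5.8, truncated at the 20-degree inclusion threshold), scales the
phantom's lateral offset and hump with the Cobb angle (Lenke 1 thoracic
right-convex with a posterior-right hump, Lenke 5 lumbar left-convex), and
derives a brace with the group's planted relief pad (depth ~ N(-6, 2) mm,
truncated), two pressure pads and small random nuisance pads. Segment
peaks are measured through the *real* displacement pipeline, and IBC is
generated top-down as `intercept + coef * peakNegative(segment) + noise` —
the goal is statistical-pipeline validation, not biomechanics. In-brace
Cobb angles are back-computed from the generated IBC.

The noise SDs are calibrated so the planted *population* Spearman
correlations match the associations the pipeline is meant to detect:
rho ~ -0.85 for the PLM relief in Lenke 5 and ~ -0.72 for the ARM relief
in Lenke 1. With a measured peak-depth SD of ~1.7-1.8 mm at the default
24 x 24 phantom resolution and a 2 %/mm coefficient, the bivariate-normal
relation rho_Pearson = 2 sin(pi rho_S / 6) gives noise SDs of 2.0 % and
3.3 %; these are fixed as `cohortModel()` defaults. All randomness flows
from the single model seed; there is no hidden global state.

## Numerical choices and degenerate inputs

* Vertex merge tolerance 1e-6 mm; degenerate-face area threshold
  1e-12 mm^2.
* Inside/outside by generalized winding number with the 0.5 threshold —
  more robust than ray parity for slightly defective query meshes; the
  voxelizer uses ray parity internally because its inputs are verified
  watertight first.
* Slab caps are fan-triangulated about each boundary loop's centroid,
  which is exact for star-shaped cross-sections (all convex and torso-like
  solids). Strongly non-convex cross-sections could produce inverted cap
  triangles; torso and brace sections do not approach this regime.
* Segment/band boundaries: half-open, to the lower/posterior/right side.
* ICP direction: the mirrored model is registered onto the original, never
  the reverse; trimming happens after registration.
* Empty meshes, non-watertight inputs (with the open-edge count), rank-
  deficient covariance, insufficient z-overlap, under-sized correlation
  groups and infeasible pad draws all raise immediate, named errors; a
  failing patient in `runCohort()` is isolated, reported and excluded
  rather than aborting the run.

## Problem sizes used in the test-suite

The tests run phantoms at 24-48 rings and 24-142 points per ring (up to
~20k vertices for the registration-recovery checks), voxel pitches of 1-2
mm, a 100-seed Monte-Carlo over cohorts of 50 for the planted-effect
recovery, and one full study-sized simulation (11 + 14 patients) through
the end-to-end table pipeline. These sizes were chosen so each check
isolates one property at the smallest scale where its oracle is sharp.

## Known limitations

* Non-rigid registration and mirror-plane optimization by asymmetry
  minimization are out of scope (deterministic principal-axis placement
  plus manual override instead).
* Displacement does not estimate pad *pressure*; equal displacements on
  bone and on soft tissue are treated alike.
* The phantom cannot probe effects of scan noise, missing data or
  non-manifold geometry; `readMesh()` repairs only duplicate vertices and
  degenerate faces.
* Cap triangulation assumes star-shaped cross-sections (see above).
* The cohort generator's IBC model is linear in a single segment feature
  per group; it validates the correlation machinery, not clinical effect
  sizes.
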