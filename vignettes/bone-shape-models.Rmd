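---
title: "Statistical shape models of long bones: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical shape models of long bones: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ossm)
```

## The model

A statistical shape model (point-distribution model) describes a population
of corresponded surfaces by a mean shape and orthogonal modes of variation.
With K training shapes of P vertices each, flattened vertex-major into
vectors $x_k \in \mathbb{R}^{3P}$, the model is

$$x \;=\; \bar{x} + \sum_{i=1}^{M} b_i \sqrt{\lambda_i}\, \phi_i ,$$

where $\bar{x}$ is the arithmetic mean, $\phi_i$ the eigenvectors of the
$\tfrac{1}{K-1}$-normalised covariance of the centred data, $\lambda_i$ the
corresponding eigenvalues (mm²), and $b_i$ coefficients in
standard-deviation units.  A *Mode* is the deformation of the mean along a
single component; the conventional visualisation set is the mean plus the
$\pm 3$ SD shapes of the first five modes, and compactness is reported as a
table of per-mode (A) and cumulative (B) percentages of total variance.

The package computes the decomposition by SVD of the centred $K \times 3P$
data matrix rather than forming the $3P \times 3P$ covariance — with
$K \ll 3P$ the covariance route is wasteful — and the two routes are held
equal within 1e-8 by tests.  $M = K-1$ modes are retained.  PCA leaves two
genuine arbitrary choices that we pin down for determinism: the sign of
each mode (fixed so the largest-magnitude component is positive) and the
order of numerically tied eigenvalues (tied blocks are ordered
lexicographically by their coefficients).

Deliberately, **no Procrustes scaling or size normalisation precedes the
PCA**.  In bone populations global size is the dominant biological factor
and is meant to appear as Mode 1; removing it would change the question
the model answers.  `buildSSM(center_scale = TRUE)` exists for exploratory
use only.

## Pipeline stages and their parameters

**Segmentation** (`thresholdSegment`, `morphologicalClose`,
`extractSurface`).  Bone is classified as intensity $\ge$ 350 (inclusive
comparison, matching common segmentation tools; the value is the standard
initial bone threshold for CT-like intensities).  Closing uses an
ellipsoidal structuring element of **3.0 mm diameter** — we read "kernel
size" as a diameter, the convention of the usual clinical tools, and
expose `kernel_radius_mm` because the alternative reading (radius) cannot
be ruled out.  The element is built per-axis in voxel units, so
anisotropic spacings are honoured.  Surfaces are extracted at iso-level
0.5 by marching tetrahedra (six tetrahedra per grid cube, crossings
deduplicated on shared grid edges), which is watertight by construction
and table-free; classic cube-based lookup tables would serve equally.
Iso-surfacing a raw 0/1 indicator overestimates areas by ~25 % (staircase
bias), so by default the indicator is first averaged with a 3×3×3 box
filter, after which sphere areas are recovered to within ~2 %;
`smoothing = "none"` restores the raw behaviour.

**Remeshing** (`remeshUniform`).  Iterative isotropic remeshing — split
edges > 4/3 of the target, collapse edges < 4/5, flip for valence 6,
tangential relaxation with projection back onto the input surface — for 5
iterations at the pipeline's standard **2 mm** target edge.  Acceptance is
defined on edge statistics (median within ±25 % of target, coefficient of
variation < 0.35) and surface deviation (≤ half the target edge), not on
matching any particular commercial tool's output.  Inputs must be closed
manifolds; targets larger than the bounding-box diagonal are rejected
rather than silently collapsing the mesh.

**Anatomical frame** (`fitSphere`, `estimateAnatomicalAxis`,
`buildFemoralFrame`, `alignToFrame`).  Condylar articular patches (expert
landmark inputs; never auto-detected) are fitted with spheres by the
linearised algebraic least-squares system refined by Gauss–Newton.  The
anatomical axis — not constructively defined in the joint-kinematics
literature the frame follows — is taken as the total-least-squares line
through cross-section centroids over the middle 50 % of the bone
(configurable window, 15 slices).  The frame privileges the axis: Y is
kept exact, the latero-medial direction (lateral→medial condyle centre)
is orthogonalised against it, and X = Y × Z.  Frames are exactly
orthonormal and right-handed for both sides, which means the anatomical
meaning of X (cranial/caudal) flips between left and right — the side tag
is carried on the frame and meshes.  Frames within 5° of degeneracy
(axis ∥ inter-condylar line) are refused.

**Partial bones** (`cutPartialFemur`, `cutPartialTibia`).  Distal/proximal
femoral models retain two reference-sphere *diameters* from the bone's
extreme vertex along Y; the reference sphere defaults to the fit over the
union of both condylar patches (distal) or the head patch (proximal).
The proximal tibia is cut at the most distal point of the tibial
tuberosity, a manual landmark.  Cuts are vertex subsets with the boundary
left open; they preserve inter-vertex distances exactly.

**Correspondence** (`selectTemplate`, `registerNearestNeighbor`,
`buildCorrespondedSet`).  The template is the specimen of median centroid
size (lower median on even counts — size is the natural order statistic
where scale dominates), remeshed to 2 mm.  Every mesh is resampled onto
the template connectivity by nearest-neighbour queries (nearest target
vertex by default; nearest surface point as an option), with ties broken
to the lowest index and a spatial grid whose results equal exhaustive
search exactly.  One design point deserves emphasis: each registration is
initialised by a **similarity normalisation** — the target is scaled to
the template's centroid size about the anatomical origin, resampled, and
the result scaled back.  Plain closest-point matching cannot express a
large size offset at the bone extremities (template head vertices fall
*inside* the head of a bigger specimen and the map folds), which leaks
scale variance into spurious modes; the normalisation removes the fold
while leaving the corresponded vertices exactly on the target geometry
and scale fully present in the corresponded coordinates.  No non-rigid
warping is performed anywhere; residual correspondence error is logged as
the per-specimen mean nearest-neighbour distance in the QC table.  For
partial-bone groups the template's *complete* bone is remeshed first and
then cut, so the remesher only ever sees closed surfaces.

**Reporting** (`varianceTable`, `sampleMode`, `exportVarianceTable`,
`runPipeline`).  Variance percentages are exact internally and rendered
at 3 significant figures, the precision such tables are conventionally
printed at.  Each group/side run emits the mean and ±3 SD meshes of the
first five modes (11 PLY files), a 5-row variance CSV with paired A/B
columns, a QC log, and a plain-text model archive.  Pipelines are
deterministic given config + seed.

## The synthetic populations

Restricted clinical CT data cannot ship with a package, so every stage is
validated on synthetic populations with *known* latent structure
(`generateBonePopulation`, `makeGroupFixture`).  Bones are built as smooth
unions (log-sum-exp smooth minimum, 4 mm blend) of capsule and sphere
signed-distance fields — shaft tube, two condylar bulges whose separation
carries the width factor, head sphere, neck, trochanter bump — iso-surfaced
on a regular grid, then deformed by the latent factors in a fixed,
documented order: global scale `exp(N(0, scale_sd))`, then distal frontal
bend (varus/valgus), distal sagittal bend (procurvation) and distal axial
twist (torsion), each blended over a smooth mid-shaft hinge band.
Landmark patches and axis endpoints are emitted consistently with the
geometry, so the anatomical-frame stage runs unsupervised.

The generator's defaults *are* the reference validation condition: n = 30
femora, log-scale SD 0.1 (≈ ±10 % size), varus 1.5°, procurvation 1.0°,
torsion 1.5°, condylar width 3 % — size clearly dominant, frontal bend the
leading secondary factor, matching the factor ordering reported for real
canine femora (size first, varus/valgus second).  The varus SD is chosen
at the scale of the up-to-4° frontal-plane variation reported for normal
dogs.  Group fixtures map the study's composition (61 complete femora
splitting 21/18/22 into weight bands, plus 18 chondrodystrophic, 13
retrievers, 30 tibiae, 72 tibial plateaus, 85 patellae) onto base shaft
lengths of 110/150/190 mm for the small/medium/large bands — a fixture
convention, not a biological claim — with within-band log-scale SD 0.05.
Tibia (tube + plateau ellipsoid + tuberosity bump) and patella
(ellipsoid + apex) analogues are deliberately minimal.

What passing tests on these populations shows — and what it does not: the
pipeline provably recovers planted factors through segmentation,
alignment, correspondence and PCA on smooth, noise-free, self-consistent
geometry.  Real bones add segmentation noise, anatomical detail the
implicit model lacks (trochlear groove, fossae), expert landmark
variability and genuinely non-affine shape differences, so real-data
variance tables will be less compact than the synthetic ones; the
published tables' 73–97 % Mode-1 range versus ~99 % here reflects exactly
that gap.

## Numerical choices and degenerate inputs

* Inclusive threshold (`>=`); monotone in the threshold by construction.
* Sub-voxel structuring elements warn and return the mask unchanged.
* Sphere fits reject (near-)coplanar inputs via the smallest singular
  value; axis estimation rejects meshes whose first two vertex-PCA
  singular values are within a factor 1.5 (no dominant elongation).
* Nearest-neighbour ties break to the lowest target index; registration
  is deterministic for fixed input ordering.
* Cut lengths exceeding the bone return the whole mesh with a warning;
  an empty tibial cut is an error.
* ICP realignment (`rigidAlignRegions`) is rigid only (Kabsch update,
  identity start, 200 iterations); non-convergence returns the best
  transform with a warning.
* Patellae, having no elongation or reliable landmarks, are aligned by a
  deterministic inertial frame (principal axes, signs fixed by the third
  central moment).

## Problem sizes used in validation

The shipped tests run the reference n = 30 population at 1.25 mm
iso-surfacing spacing (~5–6k template vertices after 2 mm remeshing), a
full 61-specimen group fixture at 1.5 mm, 50 random corresponded sets of
up to 15 × 100 vertices against the covariance-eigendecomposition oracle,
and voxel round trips at 1 mm spacing; `scripts/acceptance.R` recomputes
the same quantities from scratch.  These sizes keep the whole validation
suite in the minutes range on a single core while leaving each property
well away from its threshold.

## Known limitations

* Correspondence is resampling, not group-wise optimisation; its accuracy
  rests on the anatomical pre-alignment and the similarity initialisation,
  and degrades where geometry has no nearby counterpart (deep concavities).
* The anatomical-axis construction is one of several reasonable choices;
  frames built with a different axis definition will shift how bend-type
  variation is distributed across modes.
* The generator cannot emulate CT noise, partial-volume effects or
  breed-specific anatomical detail; it validates the machinery, not
  biological conclusions.
* Left and right bones are modelled as separate populations; no mirrored
  pooling is performed by default.
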