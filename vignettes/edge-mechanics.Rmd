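---
title: "Edge mechanics and edge imaging: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge mechanics and edge imaging: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(edgewall)
```

`edgewall` asks a mechanical question about a cell-biological observation:
if a membrane-trafficking pathway delivers wall-stiffening material
specifically to the geometric edges of growing epidermal cells, what
should failing that delivery do to cell shape — and how would one
quantify, in images, that a marker really is edge-clustered? This
vignette is the package's own account of the models behind its answers:
what is assumed, which knobs matter, which choices were genuinely open,
and what the synthetic data can and cannot stand in for.

## 1. The wall model

### Geometry

`cell_row_spec()` describes a 2D cross-section of a file of epidermal
cells: an outer periclinal wall facing the organ surface, an inner
periclinal wall, and `n_cells + 1` anticlinal walls, adjacent cells
sharing a single anticlinal wall. `cell_width` and `cell_height` give the
outer envelope of one cell with the walls inside it, so a 10 × 10 µm cell
with 1 µm walls encloses an 8 × 8 µm lumen. Defaults — five 20 × 20 µm
cells with a 0.5 µm outer wall and 0.3 µm anticlinal/inner walls — are
round numbers in the range reported for young root epidermis; none of the
package's conclusions depend on the absolute values, because the results
are deliberately stated as trends (monotonicity, sign of stress changes)
rather than magnitudes.

A *vertex* is the cross-sectional trace of a 3D geometric edge: the
intersection of an anticlinal wall midline with a periclinal wall
midline. Both outer-side and inner-side vertices exist; softening is
applied at the outer side by default, where the anticlinal walls meet the
outer wall, with `sides = c("outer", "inner")` available. The softened
region is a disc of radius `r` around the vertex point, and an element
belongs to it iff its **centroid** is inside — centroid membership gives
an unambiguous partition of elements, where node membership would not.
The disc is measured from the wall-midline intersection, not the lumen
corner; both conventions differ by less than half a wall thickness, far
below the 0.5–1 µm radii studied.

### Meshing

`mesh_domain()` lays a tensor grid over the envelope with grid lines
snapped to every wall face and keeps the cells whose centroid is wall
material. This yields a conforming all-quad mesh (no triangles), at
least two elements across every wall thickness, deterministic for fixed
inputs. The `target_h` precondition (no larger than the thinnest wall)
keeps the two-across rule meaningful. Meshes are audited by
`mesh_check()`: positive Jacobians at all Gauss points and closed
boundary loops.

### Elasticity

The wall is isotropic linear elastic, *E* = 5×10⁸ Pa, ν = 0.45 — nearly
incompressible, as hydrated pectin-cellulose walls are usually treated,
while staying clear of the ν = 0.5 singularity. The cross-section is
solved in **plane strain** (cells are elongated normal to the section, so
out-of-plane strain is suppressed by the neighbouring material); plane
stress is available by flag. Softened vertex discs use *E/f* with the
same ν.

Turgor enters as a uniform dead pressure *P* (default 5 bar = 5×10⁵ Pa)
on every lumen-facing wall segment of every cell — the interior is
pressurized, not just the outer wall; restricting the load to chosen
cells is a flag (`load_case(cells = ...)`). Each boundary edge of length
*L* contributes a force *P·L* per unit thickness along the inward wall
normal, split equally between its end nodes (exact for straight edges
under constant pressure). The inner periclinal wall is fully constrained,
representing the stiff inner tissue; rollers (`fixed_x` / `fixed_y`) are
available for validation problems.

### Discretization and solution

Bilinear quadrilaterals at ν = 0.45 lock volumetrically under full 2×2
integration, and uniform one-point integration (the reduced-integration
element family of commercial codes) needs hourglass stabilization. The
package uses **selective reduced integration**: the dilatational (λ)
term of the constitutive matrix is integrated at the element centroid,
the µ term at 2×2 Gauss points. This removes locking without hourglass
modes and passes the patch test exactly; it is a deliberate, documented
departure from the reduced-integration-with-hourglass-control mechanics
of the element it emulates, with identical intended physics.

Everything is converted to SI internally (µm → m); displacements are
reported back in µm, stresses in Pa. The constrained system is solved by
sparse Cholesky factorization (deterministic); a residual above 1×10⁻⁸
relative, or a singular factorization, is a hard error — the solver never
returns silent garbage. Stresses are recovered at element centroids
through the full (unsplit) constitutive matrix, and principal stresses
are the closed-form eigenvalues of the 2×2 tensor.

Validation, enforced by the test suite: a pressurized thick-walled ring
matches the plane-strain closed form within 1 % (error converging at
order ≈ 2); a uniform-traction patch test is exact to 1×10⁻¹⁰; reactions
balance applied loads; scaling *P* scales the solution linearly.

### The softening experiment

`run_softening_sweep()` solves the baseline (*f* = 1) and softened cases
over *f* ∈ {1, 3, 10}, *r* ∈ {0.5, 1} µm. Two readouts had to be chosen,
because the source analysis names none:

* **Distension** = maximum outward-normal nodal displacement of the
  outer periclinal wall (+y for the cell file). The mean outward
  displacement is reported alongside, as a delocalization-insensitive
  alternative.
* **Regional stress** = area-weighted mean (and max) of σ₁ per region;
  area weighting makes the summary mesh-size independent. The "face"
  region is the outer periclinal wall minus the vertex discs; anticlinal
  walls are reported separately.

Load relocation is *confirmed* when the vertex mean σ₁ falls and the
outer-face mean σ₁ rises relative to baseline. Linear kinematics
exaggerate absolute displacements (tens of µm on a 20 µm cell at f = 10);
the claims the package makes — and tests — are the orderings, which a
geometrically nonlinear model would share in direction.

## 2. The synthetic confocal generator

`generate_cells()` builds axis-aligned box cells with shared walls. Real
lateral-root epidermal cells are rounded, anisotropic and curved; boxes
were chosen because they keep every face plane and edge segment
*analytic*, so each downstream statistic has exact ground truth — the
whole point of the generator is to be an oracle. Consequences: passing
tests demonstrate that the statistics recover what the generator planted,
not that they are robust to segmentation error, curved surfaces, or
depth-dependent attenuation, none of which are modeled.

`puncta_model()` holds the measured biology: punctum diameters
150 ± 35 nm and membrane distances 93 ± 36 nm (both normal, truncated at
zero), taken from immuno-EM characterization of the edge-associated
compartments. `edge_fraction` is the one free knob: the probability a
punctum targets the tube around a geometric edge (uniform along edges by
length, displaced inward so its distance to each of the edge's two faces
equals the sampled membrane distance) instead of the cell interior
(uniform). `edge_fraction = 0.9` emulates the edge-clustered marker;
`edge_fraction = 0` the dispersed control obtained pharmacologically in
the source experiments. The edge "tube radius" used when *classifying*
points as edge-proximal defaults to 0.3 µm (about twice the punctum
diameter) and is always reported.

Rendering: each punctum is a separable Gaussian (its diameter read as a
FWHM) combined with the PSF sigma per axis (default 0.1/0.1/0.25 µm —
confocal-like anisotropy), normalized so each punctum contributes exactly
`intensity_per_punctum` integrated counts; then background is added and
Poisson shot noise plus Gaussian read noise applied, clamped at zero. The
default contrast (2000 counts per punctum over a background of 5 per
voxel) represents bright fluorescent-protein puncta over dim cytoplasm.
A single seed drives placement and noise; identical seeds give
byte-identical stacks, which the tests assert at the TIFF level.

Default voxels are 0.1 × 0.1 × 0.3 µm. The enrichment experiments in the
tests and acceptance script instead use 12 × 12 × 6.4 µm cells at 0.2 µm
isotropic voxels, so that three 2-µm sections tile the cell depth exactly
and a 60-cell two-group experiment stays within a few minutes of compute.

## 3. Shell enrichment

The quantification mirrors the microscopy procedure: three consecutive
2-µm sections parallel to the outer surface, measured inward from the
outer face; within each section, voxels are binned by Euclidean distance
to the plasma membrane into an outer border (0–1 µm), inner border
(1–2 µm) and interior. Distance is computed from the **full 3D cell
boundary** (an exact anisotropic distance transform, implemented in C++
with the lower-envelope algorithm and verified against the analytic
box-distance oracle), not per-slice — "distance from the PM" includes
anticlinal faces. For a synthetic cell the "outer surface" is its +z
face, the stand-in for the organ surface; axis and direction are
configurable.

Relative enrichment divides each compartment's mean intensity by the
whole-section mean. Two exact invariants follow and are tested: a uniform
image scores 1 everywhere, and the voxel-count-weighted mean across
compartments is exactly 1 per section, for any image. Empty compartments
(e.g. a thin cell with no interior band) produce explicit `NA`s.

One property widely assumed of such data does **not** hold under the
measured puncta geometry, and the package documents rather than forces
it: with puncta 93 nm from the membrane, all signal lands in the 0–1 µm
band; the 1–2 µm band carries background only and, after per-section
normalization, sits slightly *below* the interior. The biologically
meaningful contrasts — outer border above 1, interior below 1, the
combined 0–2 µm border above the interior, and a flat profile in the
dispersed control — all hold and are what the tests assert.

The ANOVA stage had two unstated design choices: the second factor and
the replicate unit. The package fixes them as **compartment × treatment**
with **cells** as replicates (sections averaged within cell ×
compartment first), records the choice in the result object, and runs a
fixed-effects two-way `aov()` with Tukey HSD. A balanced-design
sum-of-squares oracle in the tests pins the arithmetic.

The periphery-distance statistic reports each punctum centre's distance
to the nearest membrane point (analytic for box cells), with quantile
summaries and a rank-sum comparison between markers. Ground-truth
centres are the default; `detect_puncta()` (local maxima above mean
background + 2 SD with greedy minimum-separation suppression) exists for
realism tests, with the caveat that a k·SD threshold admits shot-noise
maxima, so detections should be ranked by intensity where precision
matters.

## 4. Colocalization

`threshold_mask()` implements the mean + k·SD background threshold
(k ∈ {1, 2}). The default background region is the exterior, *eroded* by
5 voxels: membrane-proximal puncta bleed across the cell surface through
the PSF, and an uneroded exterior inflates the background SD. The eroded
region is only adopted when it keeps at least 500 voxels, for stable
statistics.

Reciprocal voxel-overlap (Manders-style) fractions are reported per cell.
Two estimator facts shaped the design, both quantified during
development and reflected in the tests:

* A k·SD threshold admits the upper ≈ 2 % tail of the background in
  *every* channel. For sparse puncta these false-positive voxels dominate
  the masks, so the voxel-count overlap fraction of a planted
  co-placement fraction ρ is attenuated toward the chance level; dense
  designs fail differently, through chance overlap. The voxel fractions
  are therefore asserted to be *monotone* in ρ and exact at the
  boundaries (identical masks → 1, disjoint → 0, k = 2 mask nested in
  k = 1), not to equal ρ.
* The planted quantity is object-level co-placement, and
  `object_coloc()` estimates it directly: the fraction of channel-A
  punctum centres falling in the B mask, chance-corrected as
  `(raw − q)/(1 − q)` with `q` the B-mask coverage of the cell (the hit
  rate of a randomly placed object). This recovers ρ within ±0.05 in the
  20-cell experiments the acceptance script runs. Both modes are
  reported; no randomization-based (Costes-type) correction is provided.

`fisher_exact()` enumerates the full hypergeometric support of a 2×2
table: one-sided p sums the upper tail, two-sided p the probabilities no
greater than the observed table's (minimum-likelihood rule, stated in
the output). Degenerate margins return p = 1 with a warning. The tests
cross-check against `stats::fisher.test()` on random tables — the
reference implementation serves as oracle, never as the implementation.
For the phenotype table (16/13 vs 0/26) both one- and two-sided p fall
below 10⁻⁵, so the printed bound is insensitive to the sidedness the
source left unstated.

## 5. Problem sizes and determinism

Chosen as the package's standard working sizes: unit tests run the cell
file at h = 0.2–0.25 µm (10³–10⁴ elements) and the acceptance sweep at
h = 0.08 µm (≈ 1.9×10⁴ elements, six solves); the enrichment experiment
uses 30 + 30 cells; colocalization 20 cells; generator fidelity n = 1000
puncta. All randomness flows from explicit integer seeds; geometry,
meshing and the solver are seed-free and bit-deterministic, which the
sweep-CSV byte-identity test checks end to end.

## 6. Known limitations

* Small-strain linear elasticity with dead loads: no growth, remodeling,
  large rotations or follower-pressure effects; magnitudes are
  qualitative once displacements become comparable to wall thickness.
* 2D cross-section: 3D edge curvature and longitudinal wall tension are
  outside the model.
* Box cells and Gaussian optics: no curved membranes, no depth-dependent
  PSF or attenuation, no photobleaching, no segmentation error.
* The voxel-count Manders fraction is a biased estimator of planted
  co-placement under k·SD thresholds (see §4); use the chance-corrected
  object mode when the planted fraction is the target.
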