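# edgewall

Mechanics and quantitative imaging of plant cell **geometric edges** — the
lines where two faces of a polyhedral cell meet.

In growing root epidermis, a Rab GTPase marks punctate membrane
compartments that cluster tightly along cell edges, and interfering with
it makes cells swell radially. A mechanical reading of that phenotype is
that the trafficking pathway locally stiffens the wall at the edges: in a
turgor-pressurized cell, softening only the wall near the edge
cross-sections (the *vertices* of a 2D section) redistributes load onto
the cell faces and lets the outer wall bulge. `edgewall` implements both
halves of that argument as reusable, tested code:

* **Wall mechanics.** An idealized cross-section of a file of epidermal
  cells (outer/inner periclinal walls joined by shared anticlinal walls)
  is meshed with linear quadrilaterals and solved as a 2D plane-strain
  linear-elastic problem under turgor pressure *P* (default 5 bar), with
  Young's modulus *E* = 5×10⁸ Pa and Poisson ratio ν = 0.45. Vertex
  discs of radius *r* have their modulus divided by a softening factor
  *f*. The solver uses selective reduced integration (the dilatational
  term at the element centroid) so the nearly incompressible material does
  not lock. Outputs per element are the stress tensor and its largest
  eigenvalue σ₁, the maximum principal stress.
* **Softening sweep.** `run_softening_sweep()` repeats the solve over
  *f* ∈ {1, 3, 10} and *r* ∈ {0.5, 1} µm and reports outer-wall radial
  distension and area-weighted mean σ₁ per wall region — the in-silico
  experiment behind the "load relocation from vertices to faces" claim.
* **Synthetic confocal stacks.** `simulate_stack()` renders 3D two-part
  volumes (intensity + cell labels) of box-shaped cells with ~150 nm
  puncta placed ~93 nm from the plasma membrane along geometric edges
  (`edge_fraction` controls edge clustering), Gaussian PSF blur, and
  Poisson + Gaussian noise, with exact analytic ground truth.
* **Edge-enrichment statistics.** `enrichment_table()` reproduces the
  shell quantification: three consecutive 2-µm sections parallel to the
  outer surface, each split into a 0–1 µm outer border, 1–2 µm inner
  border and interior by 3D Euclidean distance to the membrane; mean
  intensity per compartment is normalized by the section mean
  (*relative enrichment*; a uniform image gives exactly 1).
  `enrichment_anova()` runs the two-way (compartment × treatment) ANOVA
  with Tukey post hoc.
* **Colocalization and counts.** `threshold_mask()` (mean background +
  *k*·SD, *k* = 1 or 2), `reciprocal_coloc()` (voxel-overlap Manders
  fractions per cell), `object_coloc()` (chance-corrected object-level
  co-occurrence), and `fisher_exact()` — the exact hypergeometric test for
  2×2 phenotype tables.

## Worked example

```r
library(edgewall)
spec <- cell_row_spec()          # five 20x20 um cells, walls 0.5/0.3/0.3 um
sweep <- run_softening_sweep(spec, wall_material(5e8, 0.45), load_case(5e5),
                             factors = c(1, 3, 10), radii = c(0.5, 1.0),
                             target_h = 0.15)
tidy(sweep)[, 1:6]
#> # A tibble: 6 x 6
#>   factor radius n_elements max_distension_um mean_distension_um s1_vertex_mean
#>    <dbl>  <dbl>      <int>             <dbl>              <dbl>          <dbl>
#> 1      1    0.5       5508              30.9               16.8     101232660.
#> 2      3    0.5       5508              40.8               22.3      90395167.
#> 3     10    0.5       5508              64.1               36.0      69957286.
#> 4      1    1         5508              30.9               16.8      92326460.
#> 5      3    1         5508              49.0               27.1      75846518.
#> 6     10    1         5508              80.1               46.0      49735838.
```

Reading the table: the unsoftened wall (f = 1) bulges 30.9 µm outward
under 5 bar; softening the vertex discs 3- and 10-fold raises the
distension monotonically (to 80.1 µm at f = 10, r = 1 µm — linear
elasticity exaggerates absolute magnitudes, so trends, not microns, are
the result), while the mean maximum principal stress *in the softened
vertex discs* falls (101 → 70 MPa at r = 0.5 µm) and rises in the outer
faces: the load relocates from edges to faces. `autoplot(sweep)` draws
the dose-response; `plot_stress_field()` maps σ₁ on the deformed mesh.

The phenotype-specificity count data (16 of 29 dominant-negative lines
with the mutant phenotype, 0 of 26 wild-type lines):

```r
fisher_exact(16, 13, 0, 26)
#> # A tibble: 1 x 7
#>   p_one_sided p_two_sided odds_ratio     a     b     c     d
#> 1  0.00000228  0.00000246        Inf    16    13     0    26
```

Both p-values are below 10⁻⁵.

## Vignette

`vignettes/edge-mechanics.Rmd` documents the model and its assumptions,
the generator's realism and limits, all numerical choices, and the open
design decisions the package had to settle.
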