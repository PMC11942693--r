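---
title: "Methods: finite element comparison of composite restorations with and without hydroxyapatite inserts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: finite element comparison of composite restorations with and without hydroxyapatite inserts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toothfea)
```

## The problem

Resin composites contract by a few percent while they cure. In a bonded
Class I restoration that contraction cannot happen freely: it drags on the
cavity walls, stresses enamel and dentin, and pre-loads the tooth before any
bite force arrives. A prefabricated hydroxyapatite (HAP) ceramic insert,
cemented into the cavity and covered with a composite cap, replaces most of
the shrinking volume with an inert stiff disk, so less material polymerizes
in place. `toothfea` quantifies what that substitution does to region-wise
von Mises stress and displacement in a controlled, fully synthetic model:
five scenarios (healthy tooth, small and big cylindrical cavities restored
with composite only or with insert + cement + composite), two loading
phases (shrinkage first, then a distributed occlusal force), and a fixed
comparison protocol (insert scenario versus its composite-only control of
identical preparation).

## The synthetic geometry

The model tooth is deliberately idealized: an elliptic cylinder (10 mm
vestibulo-oral by 11 mm mesio-distal, 21 mm tall) with a flat occlusal
surface, an enamel crown shell (crown height 8 mm, occlusal cap 2.5 mm,
lateral band 1.5 mm), a dentin body, an elliptic pulp chamber
(semi-axes 1.5 and 1.8 mm, z from 2 to 12 mm), a 0.25 mm periodontal
ligament (PDL) shell below the cemento-enamel junction, and a
16 x 17 x 14 mm bone block whose top face sits at the CEJ. Replacing
scan-derived anatomy with closed-form surfaces removes anatomy as an
unreproducible input: every dimension is a parameter of `tooth_dims()`,
every point classifies deterministically (`classify_points()`), and
restoration volumes have closed forms that validate both the Monte-Carlo
quadrature and the mesh.

Cavities are vertical cylinders of diameter 5.5 mm entered from the
occlusal surface. Insert thicknesses of 1.7 mm (small) and 4.7 mm (big)
with a 0.5 mm cement floor and a 2.0 mm composite cap fix the two cavity
depths at 4.2 and 7.2 mm; the same depths are used for the composite-only
controls so each pair shares one preparation. The nominal component
diameters (cavity 5.5 mm, insert 4.7 mm, circumferential cement 0.5 mm)
are mutually inconsistent by 0.2 mm; we keep the cavity and insert
diameters and let the lateral cement gap be the radial difference
(0.4 mm), while the cement floor stays 0.5 mm. The deep cavity floor
(z = 13.8 mm) deliberately approaches the pulp roof (z = 12 mm),
emulating a devitalized tooth with the preparation near the root canal
entrances; geometries whose cavity would touch the pulp are rejected.

Two geometric approximations are worth naming. The lateral enamel band is
bounded by the inner *offset ellipse* (semi-axes reduced by the band
thickness), an approximation of true normal distance that is exact on the
axes and slightly thin at intermediate angles. And the PDL shell uses the
outer offset ellipse the same way, plus a thin cap under the root apex.
Neither affects the restoration stack, which is exactly cylindrical.

## Meshing

`generate_mesh()` lays a background grid of spacing `h` over the bounding
box, keeps cells whose centers classify into the domain, and splits each
kept cell into six positively oriented tetrahedra along the cell diagonal
(Kuhn split). The boundary is stair-step: no surface snapping, which

* guarantees positive element volumes and byte-identical meshes for
  identical inputs,
* makes geometric error a pure function of `h` (mesh volume converges to
  the Monte-Carlo domain volume; the suite asserts < 5 % at h = 0.5 mm),
* concentrates artificial corners on the surface, which inflates local
  stress maxima at re-entrant steps (see "What the model does and does not
  show").

Each element is tagged with the region of its own centroid, so material
interfaces are resolved at element granularity. A uniform `h` is used
everywhere (the study default is 0.5 mm, about 216,000 elements and
40,000 nodes for a scenario); we chose a single spacing over per-region
coarsening to keep the mesh conforming without hanging-node constraints.
Element shape quality is reported as `Q = 1 - V / V_reg(l_rms)`, where
`V_reg` is the volume of the regular tetrahedron with the element's
root-mean-square edge length: 0 for the ideal shape, approaching 1 for
slivers. This reproduces the range convention of commercial Jacobian
metrics, whose exact formulas are proprietary; on the Kuhn split all
elements share `Q ~ 0.34`, so the quality report is mostly a guard against
degenerate input meshes (`read_vtk_mesh()` accepts external tetrahedral
meshes with region tags).

## Materials and the shrinkage thermal analog

Each region is isotropic linear elastic (Table: `default_material_table()`;
enamel 84.1 GPa, dentin 18.6 GPa, pulp 6.8 MPa, bone 1.37 GPa, cement
4 GPa, composite 16.6 GPa, insert 100 GPa, with the published Poisson
ratios). The PDL has no published record in the study's property set; we
supply a literature-typical soft layer (E = 50 MPa, nu = 0.45),
configurable through `material_overrides`.

Polymerization contraction is emulated thermally: the composite and cement
are cooled from the 36 degC reference to 10 degC, and their linear
expansion coefficient is calibrated so free cooling reproduces a target
volumetric shrinkage S (default 3.7 %):

alpha = (1 - (1 - S)^(1/3)) / delta_T,  delta_T = 26 degC,

giving alpha = 4.80e-4 per degC. The temperature field comes from a
steady-state conduction solve with Dirichlet data only: all
composite/cement nodes at 10 degC, external surfaces and all insert nodes
at 36 degC, with the shrinking-material set winning the cement-insert
interface conflict. Because every thermally active element is pinned on
all its nodes, conductivities only enter through ratios and the default
`k = 1` everywhere is inconsequential; the discrete maximum principle
bounds the field by [10, 36] degC, which the suite asserts. Tissue and
insert expansion coefficients default to zero so the analog strains only
the curing materials; an opt-in "literature" mode assigns enamel
11.4e-6, dentin 8e-6 and HAP 13.3e-6 per degC for thermal-cycling style
questions, but is not part of the study protocol.

## The elastic solves

Elements are constant-strain tetrahedra in Voigt convention
(xx, yy, zz, yz, xz, xy; engineering shear). The thermal strain enters as
an initial strain `alpha delta_T (1,1,1,0,0,0)` in both the load vector
and the stress recovery `sigma = C (B u - eps_th)`. The occlusal force
(2 kN by default) is a uniform pressure over the occlusal facet set
(boundary facets within 10 degrees of +z near the mesh top), applied along
-z with an exactly balanced resultant. Supports fix all nodes of the
lateral bone-block faces ("full" mode, mirroring lateral fixation of the
mandible segment); a "simple" base-fixed mode exists for fixtures, and
free-floating fixtures use statically determinate 3-2-1 constraints that
are compatible with uniform scaling, so free shrinkage stays stress-free
(asserted below 1e-6 of the material stress scale).

Phase 1 applies the shrinkage loads alone; phase 2 applies shrinkage plus
the occlusal pressure in a single linear solve. Sequential load functions
and the combined solve are equivalent by superposition, which the suite
asserts to 1e-8; the combined solve lets one sparse Cholesky
factorization (CHOLMOD, supernodal) serve both phases of a scenario. The
factorization is direct - no iterative tolerance enters the results.
Reactions are recovered as `K u - f` on the constrained dofs and must
balance the applied totals to 1e-6 relative.

## Reductions

Reported statistics follow the study's conventions:

* Groups are enamel, dentin, and restoration = composite + cement +
  insert (maxima are reported for the restoration as a whole).
* "Maximum stress" is the maximum over per-element constant stresses -
  deterministic and mesh-auditable; no nodal extrapolation is used for
  maxima. Quartiles interpolate linearly between order statistics.
* The contraction rate compares restoration volume before and after
  phase 1, `100 (V0 - V1)/V0`, by two routes: summing deformed element
  volumes (default), and a cylinder fit from mean radial and axial
  boundary displacements mirroring the published description. On the free
  cylinder both agree with the calibrated target to numerical precision.
* Percent decrease is the signed `100 (control - insert)/control`;
  negative values (the insert increased the quantity) are kept signed and
  flagged rather than silently restated, since the published convention
  for one such pair is ambiguous.
* "Stress at the preparation bottom" is operationalized as the mean
  dentin von Mises stress over elements whose centroid lies within a set
  distance (default 0.5 mm) below the cavity floor, inside the cavity
  radius.

## What the synthetic model does and does not show

The geometry generator emulates the *protocol* of the study - scenario
set, material assignment, boundary conditions, loading phases - not the
scanned molar. Published stress magnitudes are tied to real anatomy
(inclined cusps, curved enamel-dentin junction, root geometry) and a
half-million-element quadratic mesh; a flat-topped elliptic tooth at desk
scale cannot and should not match them. What transfers are the
geometry-independent quantities (the calibrated 3.7 % free contraction;
global equilibrium) and the *directions* of the comparative findings,
which the acceptance suite checks at h = 0.5 mm: shrinkage-phase
displacement maxima drop with an insert in all three groups, the
combined-phase enamel stress maximum drops, and the near-floor dentin
stress in the deep cavity drops sharply.

Two caveats. First, stair-step boundaries concentrate stress at surface
steps, so point maxima are mesh-size sensitive (the suite tracks overall
displacement stability between h = 1 and h = 0.5 mm instead, at < 10 %).
Second, in this synthetic model the restoration stress *maximum* under
occlusal load moves into the stiff insert, which attracts load share; in
the published anatomy the restoration maximum sat in the composite cap.
The restoration-group stress comparison is therefore geometry-dependent
and is not part of the directional acceptance set.

## Problem sizes and runtimes

Defaults were chosen to keep a full five-scenario study at h = 0.5 mm in
the minutes range on one CPU: each cavity scenario costs one conductance
solve (about 40,000 unknowns) and one elastic factorization (about
120,000 unknowns) reused for both phases. Verification fixtures are much
smaller: the free-shrinkage cylinder (about 9,400 elements) runs in
seconds, the analytic fixtures (patch cube, series bar) in well under a
second.

## Reproducing the study protocol

```{r, eval = FALSE}
report <- run_study(study_config())   # five scenarios, h = 0.5 mm
report$percent_decrease               # insert-versus-control table
report$contraction                    # per-scenario contraction rates
autoplot(report)                      # group maxima by scenario and phase
```

A single calibrated quantity can be reproduced in isolation:

```{r}
fx <- make_fixture("free_cylinder")
sol <- run_phase(fx$mesh, fx$materials, "phase1_thermal",
                 fixed_dofs = fx$fixed_dofs)
contraction_rate(sol)
```
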