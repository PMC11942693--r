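# toothfea

Desk-scale finite element pipeline for a question from restorative
dentistry: what does replacing most of a Class I composite restoration
with a stiff, inert hydroxyapatite (HAP) insert do to the stresses and
displacements that polymerization shrinkage and biting forces put into a
tooth?

The package builds five fully synthetic restored-tooth models (healthy
tooth; small and big cylindrical cavities restored with composite only or
with insert + cement + composite cap), loads them in two phases, and
reduces the solutions to the comparative quantities a restorative study
reports: region-wise von Mises statistics and maxima, displacement maxima,
volumetric contraction rates, and insert-versus-control percent decreases.
It is aimed at computational biomechanics users who want a reproducible,
parametric stand-in for scan-derived dental FEA protocols.

## The model in brief

* **Geometry** — parametric elliptic-cylinder tooth (enamel cap, dentin
  body, pulp chamber, periodontal-ligament shell, supporting bone block)
  with coaxial cylindrical restoration stacks; every point of the domain
  classifies deterministically into one of eight regions.
* **Mesh** — background-grid Kuhn split into region-tagged linear
  tetrahedra; stair-step boundary, fully deterministic; element shape
  quality `Q = 1 - V / V_reg(l_rms)` (0 = regular tetrahedron).
* **Shrinkage thermal analog** — composite and cement are cooled
  36 → 10 °C after a steady-state conduction solve; their expansion
  coefficient is calibrated in closed form so free cooling reproduces a
  target volumetric shrinkage `S`:
  `alpha = (1 - (1 - S)^(1/3)) / ΔT` (default `S = 3.7 %`, `ΔT = 26 °C`).
* **Elasticity** — isotropic linear constant-strain tetrahedra
  (`K_e = V Bᵀ C B`, Voigt order xx, yy, zz, yz, xz, xy), thermal strain
  as initial strain, a uniform 2 kN occlusal pressure along −z, fixed
  lateral bone faces, one supernodal sparse Cholesky factorization per
  scenario serving both loading phases (phase 2 = shrinkage + load in one
  solve, equal to sequential loading by superposition).
* **Reporting** — per-element stress maxima
  (`σ_vM = sqrt(((σxx−σyy)² + (σyy−σzz)² + (σzz−σxx)² + 6(σyz²+σxz²+σxy²))/2)`),
  descriptive statistics, contraction rate `100 (V0 − V1)/V0` by deformed
  element volumes and by a cylinder fit, percent decrease
  `100 (control − insert)/control` with increases flagged.

## Worked example

The single directly calibrated quantity of the protocol — the free
shrinkage of an unconstrained composite cylinder cooled 36 → 10 °C:

```r
library(toothfea)
fx  <- make_fixture("free_cylinder")
sol <- run_phase(fx$mesh, fx$materials, "phase1_thermal",
                 fixed_dofs = fx$fixed_dofs)
contraction_rate(sol)
#> # A tibble: 2 × 4
#>   method          V0    V1  rate
#>   <chr>        <dbl> <dbl> <dbl>
#> 1 element       101.  97.4  3.70
#> 2 cylinder_fit  118. 114.   3.70
```

Both volume-comparison routes return the calibrated 3.7 % contraction:
the thermal analog is working and the finite elements reproduce the
uniform-strain state exactly. (`V0` differs between methods because the
element route sums the stair-step mesh volume while the cylinder fit uses
the fitted radius; the *rate* is the comparable quantity.)

A small comparative study (three scenarios at a coarse 1 mm mesh, minutes
of runtime; the full default protocol is `run_study(study_config())`):

```r
rep <- run_study(study_config(scenarios = c("healthy", "small_c", "small_ic"),
                              h = 1))
dplyr::filter(rep$percent_decrease, metric == "max_vm")
#> # A tibble: 6 × 9
#>   phase                        group       control insert decrease_pct
#> 1 phase1_thermal               enamel         842.  702.          16.7
#> 2 phase1_thermal               dentin         195.   55.2         71.7
#> 3 phase1_thermal               restoration    291.  417.         -43.1
#> 4 phase2_thermal_plus_occlusal enamel         881.  739.          16.2
#> 5 phase2_thermal_plus_occlusal dentin         202.   67.8         66.5
#> 6 phase2_thermal_plus_occlusal restoration    306.  406.         -32.7
```

Read: the insert lowers the shrinkage-phase stress maxima in enamel
(−16.7 %) and dentin (−71.7 %) and keeps doing so after the 2 kN bite
load; the restoration-group maximum *rises* (flagged negative decreases)
because on this idealized geometry the stiff insert attracts load share —
a geometry-dependent quantity discussed in the methods vignette.
Contraction of the confined in-cavity restoration is well below the free
3.7 % and smaller again with the insert:

```r
rep$contraction
#> # A tibble: 4 × 5
#>   scenario method          V0    V1  rate
#> 1 small_c  element       93.3  91.7 1.76
#> 2 small_c  cylinder_fit 132.  131.  1.32
#> 3 small_ic element       93.3  92.4 0.975
#> 4 small_ic cylinder_fit 132.  131.  0.760
```

`autoplot(rep)` draws the group-maxima bar chart; `tidy()`/`glance()`
methods give per-element and one-row summaries of solutions and reports.
A thin command-line front end lives in `inst/cli/toothfea.R`
(`run`, `fixture`, `report` subcommands, YAML/JSON configs).

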