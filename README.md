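# lumbokin

A desk-scale, reduced-order biomechanical model of the human lumbar spine
(L1–sacrum) with kinematic verification against radiological statistics and
an application to L5–S1 disc degeneration.

Finite-element models of the whole lumbar spine reproduce physiological
ranges of motion, but they are heavyweight: meshed anatomy, contact, and
commercial solvers. `lumbokin` condenses each of the five motion segments to
six generalized degrees of freedom while keeping the *nonlinear* ingredients
of spinal mechanics discrete and literal:

- **annulus fibrosus ground substance** — a 6-DOF elastic foundation built
  from the confined modulus of the disc layer;
- **nucleus pulposus** — an incompressible Mooney–Rivlin core
  (C01 = 0.0343 MPa, C10 = 0.1369 MPa, enforced by a volumetric penalty with
  a radial-bulge internal degree of freedom), or a compressible elastic core
  for degenerated/comparison variants;
- **collagen fibre layers** — crossed tension-only families at 35°–80° on
  five concentric layers (E = 360…550 MPa), strained affinely with the disc;
- **ligaments** (ALL, PLL, flavum, inter-/supraspinous, intertransverse,
  capsular, iliolumbar) — bilinear tension-only laws,
  σ(ε) = E₁ε up to the transition strain, then E₁ε_t + E₂(ε − ε_t);
- **facet joints** — unilateral penalty contact with an oblique normal.

The chain is loaded by a 400 N follower preload (compressive force pairs
that track the deformed spinal axis), pure moments (15 N·m, 6 N·m for axial
rotation), and muscle forces. Muscle magnitudes **F**ᵢ, **M**ⱼ ≥ 0 are
calibrated by minimising the total muscle work

W = Σᵢ ∮ **F**ᵢ·d**s**ᵢ + Σⱼ ∫₀^αⱼ **M**ⱼ·d**θ**,

subject to the equilibrium solution matching per-segment rotation targets.
Mobility is measured exactly as on radiographs: perpendicular endplate
reference lines, their lengths and direction cosines (l, m, n), and
plane-specific relative angles versus the sacrum, e.g.
cos α_FE = m_L m_S + n_L n_S in the sagittal plane. A synthetic 25-subject
radiological cohort (per-level normal draws with a shared subject mobility
factor and isotonic monotone correction) provides verification statistics,
and a degenerated L5–S1 disc (stiffer but less confined annulus, compressible
dehydrated nucleus, fibre moduli ÷ 10, height loss, slackened longitudinal
ligaments) quantifies segmental hypermobility.

## Worked example

```r
library(lumbokin)

geom <- build_default_spine()          # parametric L1-sacrum geometry
card <- material_card("healthy")       # packaged constitutive card

# range of motion under a 15 N m flexion moment + 400 N follower preload
range_of_motion("FLX", geometry = geom, cards = card)
#> # A tibble: 5 × 4
#>   vertebra cumulative_deg segmental_deg movement
#>   <chr>             <dbl>         <dbl> <chr>
#> 1 L1                15.0           3.15 FLX
#> 2 L2                11.8           3.17 FLX
#> 3 L3                 8.65          3.17 FLX
#> 4 L4                 5.48          2.91 FLX
#> 5 L5                 2.57          2.57 FLX
```

Cumulative angles grow from the sacrum upward (L5 → L1), and the segmental
rotation is smallest nearest the sacrum — the pure-moment signature of the
caudally stiffer segments. The solver itself is a Newton iteration on the
exact energy gradient:

```r
st <- solve_equilibrium(load_case("FLX"), geom, card)
glance(st)
#> # A tibble: 1 × 7
#>   converged   residual iterations load_steps energy_J movement preload_N
#> 1 TRUE      0.00000216         62          8     77.4 FLX            400
```

Degenerating the L5–S1 disc (material card swap + height loss + ligament
slack) and re-running the same load case:

```r
run_comparison("FLX", geom, card, degeneration_config())
#> # A tibble: 5 × 6
#>   movement vertebra healthy_deg degenerated_deg diff_deg percent
#> 1 FLX      L1             15.0            18.1      3.13    20.9
#> 2 FLX      L2             11.8            14.9      3.13    26.5
#> 3 FLX      L3              8.65           11.8      3.13    36.2
#> 4 FLX      L4              5.48            8.61     3.13    57.0
#> 5 FLX      L5              2.57            5.69     3.13   122.
```

Every level gains the degenerated segment's extra rotation (+3.1°), so the
relative change is largest right above the lesion (L5, +122 %) and dilutes
to +21 % at L1 — the global mobility increase. `calibrate()` reproduces the
published healthy maxima (34.4° flexion, 35.6° extension, 19.3° lateral
bending, 10.0° axial rotation), `generate_cohort()` + `agreement_report()`
check them against the radiological bands, and `degeneration_study()` fits
the two degeneration geometry parameters on flexion only, then predicts the
other three movements. `autoplot()` methods draw the angle profiles and
comparisons; `inst/scripts/lumbokin.R` exposes the same steps as a small
command line (`simulate`, `calibrate`, `degenerate`, `synth-cohort`,
`report`).

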