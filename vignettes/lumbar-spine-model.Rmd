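---
title: "A reduced-order lumbar spine: model, calibration and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced-order lumbar spine: model, calibration and verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lumbokin)
```

## The model

`lumbokin` treats the lumbar spine L1–sacrum as a chain of five motion
segments. Vertebrae are rigid bodies (bone is two to four orders of
magnitude stiffer than the discs and ligaments; the vertebral bone moduli
are carried on the material card as metadata only). Each segment owns six
generalized coordinates — the translation (mm) and rotation vector (rad) of
the upper vertebra relative to the lower, expressed in the disc frame and
acting about the disc centroid — plus one internal scalar, the radial bulge
of the annulus mid-surface. The segment's restoring wrench is the exact
gradient of a scalar energy summing:

* **Annulus ground substance.** A diagonal 6-DOF foundation for the elastic
  layer bonded between the endplates. Axial and bending terms use the
  confined (oedometric) modulus `M = E(1-nu)/((1+nu)(1-2nu))`; shear and
  torsion use `G`. Two homogenization efficiencies (defaults 0.5 for bending
  and torsion) correct the elliptic-plate overestimate for a thin layer that
  bulges around a fluid core; they were fixed once so that pure-moment
  segment stiffnesses fall in the published in-vitro range (roughly
  2–4 N·m/deg in bending, 2–5 N·m/deg in torsion before facet contact).
  Note that the confined modulus makes the degenerated annulus
  (E 4.2→6.0 MPa but ν 0.45→0.35) *softer* in the foundation sense
  (M 15.9→9.6 MPa), which is what the observed hypermobility requires.
* **Nucleus pulposus.** A volumetric energy `K/2 (dV/V0)^2 V0` with
  `dV = A_n u_z + S_m b`, where `b` is the bulge and `S_m` the mid-surface
  lateral area. For the healthy Mooney–Rivlin core `K` is an
  incompressibility penalty (2200 MPa, water-like; the converged volume
  error stays below 1e-4); for elastic cores `K = E/(3(1-2nu))`. The small
  nucleus shear modulus (Mooney–Rivlin: `2(C10+C01)` = 0.34 MPa) enters a
  deviatoric foundation term. The bulge is resisted by annulus hoop stretch
  (`k_hoop = E_a V_a / r_m^2`) and by the circumferential component of the
  fibres, and is condensed out of every evaluation by a scalar Newton
  iteration; by the envelope theorem the condensation does not disturb the
  analytic gradient.
* **Fibre layers.** Five concentric crossed ± families from 35°
  (innermost) to 80° (outermost); the outermost material layer carries half
  the area of the doubled layers (sheet counts 2,2,2,2,1). Which end of the
  35–80° range is innermost is not anatomically settled; innermost = 35° is
  fixed here. Fibre strain is affine in the segment coordinates and the
  bulge (rebar assumption): vertical stretch, inter-endplate shear and hoop
  stretch, with tension-only linear response at the layer modulus. Total
  fibre cross-section defaults to 160 mm² per disc, about 18 % of the
  annulus section (mid anatomical range).
* **Ligaments.** Eight families with attachment points at anatomy-book
  offsets (the iliolumbar ligament exists at L5–S1 only). Exact
  attachment-distance kinematics through the bilinear tension-only laws,
  times per-ligament cross-sections. Rest lengths equal neutral distances
  (zero pre-strain) in the healthy spine.
* **Facet joints.** One unilateral penalty contact per side (200 N/mm,
  0.8 mm clearance) with an oblique normal: a circumferential component
  (the left facet engages in right axial rotation and vice versa) and a
  vertical component (posterior apposition in extension). Flexion opens the
  joint. No friction.

**Loading.** The 400 N follower preload is a set of compressive force pairs
along the polyline sacrum → disc centroid → body centroid → …; because each
pair is nearly aligned with the local segment axis, the preload produces
pure compression (preload-only rotations ~1e-7 deg) yet still follows the
deformed axis, which is the defining property of a follower load. Pure
moments act on the topmost vertebra about the movement axis (flexion +x,
lateral bending +y, axial rotation +z; x mediolateral, y posterior,
z cranial; angles in degrees at all interfaces, radians internally). Local
muscles pull a vertebral attachment toward a fixed pelvic anchor; global
muscles are per-vertebra moments about a movement axis.

**Equilibrium.** Total potential = segment energies + preload potential
(`P` × path length) − moment work + muscle-length potentials. A Newton
iteration on the exact analytic gradient (Hessian by finite differences of
that gradient, refreshed adaptively) runs under incremental load stepping —
preload first, then moments/muscles — with automatic step halving on
failure. Convergence demands the residual below 1e-6 N on translations and
1e-6 N·m on rotations. Tension-only and contact laws are C²-regularised
inside the solver only (one-sided quadratic stress blends, width 1e-3
strain and 0.02 mm gap): without this, Newton can cycle across activation
boundaries; with it, the mechanical effect is negligible (stress offsets
below E·w/2) while the public constitutive functions remain exactly
piecewise-linear.

## Measurement

Mobility is measured as on radiographs. Each vertebra carries two
perpendicular reference lines on its superior endplate (frontal:
mediolateral node pair; sagittal: anteroposterior pair). Lengths and
direction cosines (l, m, n) of the deformed lines feed the plane-specific
relative angle: sagittal-line cosine pairs for flexion–extension,
frontal-line pairs for lateral bending (XZ) and axial rotation (XY). The
literal cosine-sum formula equals the in-plane angle only for in-plane
lines, so a plane-projected normalised variant is the default for 3-D
states and the literal variant is kept for validation; the reported angle
is the change of the vertebra-versus-sacrum angle from the neutral
configuration, which is also exactly what the radiographic protocol
measures when the sacrum is fixed. Segmental angles are measured
independently against the adjacent vertebra; the cumulative-equals-sum
bookkeeping is then a genuine consistency check (within 0.05° for in-plane
motion).

## Muscle calibration

For each movement a nonnegative magnitude per muscle is sought so that the
equilibrium solution reproduces per-segment rotation targets, and the total
muscle work W = Σ∮F·ds + Σ∫M·dθ is minimal. Because the system is
conservative, W at fixed achieved targets is nearly invariant across
feasible muscle sets, so the redundancy is resolved by a documented
deterministic tie-break: minimise the sum of squared (scaled) magnitudes in
the Jacobian null space. The solver is a damped Gauss–Newton on the
segmental-angle residuals with bound constraints handled by active-set
elimination, a Broyden-updated Jacobian refreshed on failure, and a
steepest-descent fallback; every candidate evaluation is a full equilibrium
solve (warm-started). The closed-contour work integral of the local muscles
is implemented as an open path integral over the movement trajectory, with
the *final* calibrated magnitudes (the load-stepping ramp is a numerical
continuation device, not part of the work functional).

Targets are configuration, not constants: per-level cumulative targets
follow the radiological per-level pattern rescaled to the model's global
maxima (34.40° flexion, 35.58° extension, 19.33° lateral bending; axial
rotation, which has no radiological arm, uses uniform segmental targets
summing to 9.96°). The per-level patterns are non-monotone in places, which
makes per-level *antagonists* necessary: the muscle sets therefore contain
per-vertebra agonist/antagonist pairs (erector slips against abdominal
flexor moments, ipsi- against contralateral multifidus), consistent with
adjusting the forces and moments on each vertebra. A subtlety worth
recording: psoas-like local slips act on an extended spine mostly as
compression that amplifies the existing curvature, so they cannot serve as
the flexor antagonist in extension — the abdominal wall moments can.

## The synthetic radiological cohort

The generator emulates a 25-subject male cohort (age 27.4 years, range
23–33; weight 78.6 kg, range 72.1–81.7; truncated normal draws) with
per-level cumulative angles drawn from normal distributions at the
packaged radiological means/SDs for flexion, extension and lateral bending.
Levels within a subject share a mobility factor (intraclass correlation
0.5) — independent draws violate anatomical monotonicity too often — and
each profile is corrected by a pool-adjacent-violators fit to be
nonincreasing from L1 to L5 and nonnegative. Landmark records (noisy
endplate line coordinates in a `subject_id, movement, vertebra, plane,
x1..z2` CSV dialect) route the synthetic data through the same
direction-cosine measurement code as the model states; with zero noise the
two paths agree to 1e-6 degrees.

What passing tests do and do not show: the generator reproduces the
first two moments of the reference statistics and their monotone structure,
but it does not simulate radiographic projection geometry, magnification,
observer error beyond additive coordinate noise, or any age/weight effect
on mobility. The monotone correction leaves a small positive bias (~0.3°)
in recovered means where adjacent levels sit closer than one SD (the
extension L2–L3 pair); parameter-recovery assertions therefore use the
well-separated flexion and lateral-bending levels.

## The degeneration study

The degenerated L5–S1 disc swaps in the degenerated card (annulus
E = 6.0 MPa, ν = 0.35; compressible elastic nucleus E = 1.3 MPa, ν = 0.4;
fibre moduli ÷ 10) and adds two geometric effects the tables do not
quantify: disc height loss and longitudinal-ligament slack. Height loss is
applied to the neutral geometry while ligament rest lengths and fibre rest
strains keep their healthy values, so the approach of the vertebrae itself
slackens every structure crossing the level — the loss of ligament tension
follows the loss of disc height. The facet clearance is kept at its
configured value in the degenerate neutral (cartilage remodelling);
letting the full geometric approach close the joint would lock extension,
contrary to the observed extension hypermobility. Both free parameters are
scaled by a single severity `s` (height loss 0.2 s, extra ALL/PLL slack
−0.02 s) and `s` is fitted once, on flexion only, so that the global
flexion mobility increase matches 19.4 %; extension, lateral bending and
axial rotation are then predictions. Both arms are loaded identically
(pure moments 15/6 N·m with the 400 N preload).

With the packaged defaults the fit lands at s ≈ 0.86 and the study yields
approximately +19.4 % (flexion, fitted), +18 % (extension), +21 %
(lateral bending) and +11 % (axial rotation), positive at every vertebral
level and largest directly above the lesion. The bending-plane predictions
under-shoot the reference values (extension sits at the edge of the
expected band, lateral bending below it): in this reduced model the annulus
foundation coefficient is fixed, so the degenerated segment keeps a hard
bending-stiffness floor, whereas a full continuum disc also loses the
pressure-redistribution stiffness of the nucleus–annulus interaction.
Lateral bending is also the plane with the largest healthy-model/radiology
gap (19.33° versus 23.40 ± 2.39°, outside one SD but within two). This
limitation is reported rather than absorbed into further parameter
adjustment.

## Numerical choices and problem sizes

* Incompressibility penalty 2200 MPa (water-like bulk); volume-change
  tolerance 1e-4.
* Newton residual tolerances 1e-6 N / 1e-6 N·m; load stepping 2 preload + 6
  moment increments, halving to 1/512 on failure; Hessian by forward
  differences of the analytic gradient (h = 1e-6), Levenberg damping and
  backtracking line search; rotation steps capped at 0.15 rad.
* Calibration: per-segment fit tolerance 0.05° (acceptance tolerance
  0.25°), at most 60 outer iterations; variable scalings 200 N (forces) and
  10 N·m (moments).
* Fibre sampling: 12 points per layer per family (120 per disc); halving
  the sampling changes segment moments by well under 1 %.
* Severity fit by `uniroot` to 0.005 in `s`.
* Degenerate-input handling: coincident reference nodes raise a degenerate
  -line error; zero-length ligaments cannot arise from validated configs;
  cosines are clamped at |cos| ≤ 1 with an error beyond 1 + 1e-9.
* Typical sizes: full verification (four calibrations) ~20 s on one CPU;
  the degeneration study with the severity fit ~1 min; the synthetic-cohort
  recovery checks use n = 10,000 subjects.

## Known limitations

Rigid vertebrae (no intra-vertebral strain or stress fields); no
viscoelasticity, poroelasticity or strain-rate effects; facet contact is a
point penalty without friction or cartilage thickness; muscle geometry is
literature-informed configuration, not subject-specific; moment loads use
the neutral-frame axis mapping (exact for single-axis movements, first-order
for coupled 3-D motion); and the degeneration study models a single
degenerated state, not a Thompson-grade continuum (severity sweeps are
exposed but have no reference values).
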