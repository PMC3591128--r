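# Default parametric lumbar geometry (mm, degrees). All vectors run caudal to
# cranial: [L5-S1, L4-L5, L3-L4, L2-L3, L1-L2]. Values are anatomy-book
# magnitudes; every dimension is a named parameter so sensitivity studies are
# possible.
levels: [L5-S1, L4-L5, L3-L4, L2-L3, L1-L2]
vertebrae: [L5, L4, L3, L2, L1]
body_height: 28
disc_heights: [11.0, 11.5, 11.5, 10.5, 9.5]
ellipse_a_ml: 25          # mediolateral semi-axis of the disc cross-section
ellipse_b_ap: 18          # anteroposterior semi-axis
level_scale: [1.08, 1.04, 1.00, 0.96, 0.92]   # linear endplate scale, larger caudally
nucleus_area_fraction: 0.36
disc_tilt_deg: [25, 18, 12, 7, 3]   # endplate inclination (lordosis), caudal -> cranial
annulus_mid_scale: 0.8    # mid-surface radius as fraction of outer radius
# Homogenization efficiencies of the annulus ground-substance foundation: a
# bonded elastic plate overestimates the bending/torsion stiffness of a thin
# bulging layer around a fluid core; the factors are chosen once so that
# pure-moment segment stiffnesses sit in the published in-vitro range
# (~2-4 N m/deg in bending, ~2-5 N m/deg in torsion pre-contact).
foundation_bending_efficiency: 0.5
foundation_torsion_efficiency: 0.5
fiber:
  total_area: 160                      # mm^2 summed over layers, one disc (reference scale);
                                       # ~18% of the annulus section, mid anatomical range
  layer_weights: [2, 2, 2, 2, 1]       # proportional to sheet counts per material layer
  orientations_deg: [35, 46.25, 57.5, 68.75, 80]   # innermost -> outermost
  layer_radial_scale: [0.66, 0.73, 0.81, 0.89, 0.96]
  n_samples: 12                        # sample points per layer per +/- family
ligaments:
  # ml, ap in the disc frame (ml mediolateral, +ap posterior), cs =
  # cross-section mm^2 per strand; bilateral ligaments get both sides.
  ALL: {ml: 0,  ap: -18, cs: 38, bilateral: no}
  PLL: {ml: 0,  ap: 16,  cs: 14, bilateral: no}
  LF:  {ml: 0,  ap: 35,  cs: 50, bilateral: no, z_margin: 2}
  ISL: {ml: 0,  ap: 50,  cs: 35, bilateral: no}
  SSL: {ml: 0,  ap: 62,  cs: 25, bilateral: no}
  ITL: {ml: 32, ap: 0,   cs: 5,  bilateral: yes}
  CL:  {ml: 15, ap: 35,  cs: 40, bilateral: yes}
ligament_z_margin: 3      # attachment offset beyond the disc faces, mm
iliolumbar:
  cs: 30
  origin: [48, 5, -10]    # on the sacral ala, relative to the L5-S1 disc face
  insertion: [30, 5, 3]   # on the L5 transverse process side
facets:
  ml: 15
  ap: 35
  gap: 0.8                # mm joint clearance along the contact normal
  penalty: 200            # N/mm unilateral contact stiffness
  weight_circumferential: 0.92
  weight_vertical: 0.39
endplate:
  frontal_halfspan: 20    # mediolateral reference-node offset
  sagittal_halfspan: 15   # anteroposterior reference-node offset
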