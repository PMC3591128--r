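# Muscle sets per movement. Local muscles pull a vertebral attachment point
# toward a fixed pelvic/femoral anchor (bilateral slips share one magnitude);
# global muscles act as moments about the given axis on a given vertebra (and
# hence load every segment between it and the sacrum); a leading "-" on the
# axis marks an antagonist/contralateral muscle, whose magnitude is still
# nonnegative. Per-vertebra agonist/antagonist pairs let the calibration
# adjust the forces and moments on each vertebra independently, which the
# non-monotone radiological per-level patterns require. Coordinates in mm:
# anchor relative to the sacral endplate centre, attach relative to the
# vertebral body centroid.
FLX:
  - {name: psoas_L1, type: local, vertebra: L1, anchor: [35, -50, -90], attach: [20, -5, 0], bilateral: yes}
  - {name: psoas_L2, type: local, vertebra: L2, anchor: [35, -50, -90], attach: [20, -5, 0], bilateral: yes}
  - {name: psoas_L3, type: local, vertebra: L3, anchor: [35, -50, -90], attach: [20, -5, 0], bilateral: yes}
  - {name: psoas_L4, type: local, vertebra: L4, anchor: [35, -50, -90], attach: [20, -5, 0], bilateral: yes}
  - {name: psoas_L5, type: local, vertebra: L5, anchor: [35, -50, -90], attach: [20, -5, 0], bilateral: yes}
  - {name: rectus,     type: global, vertebra: L1, axis: FLX}
  - {name: erector_L1, type: global, vertebra: L1, axis: EXT}
  - {name: erector_L2, type: global, vertebra: L2, axis: EXT}
  - {name: erector_L3, type: global, vertebra: L3, axis: EXT}
  - {name: erector_L4, type: global, vertebra: L4, axis: EXT}
  - {name: erector_L5, type: global, vertebra: L5, axis: EXT}
EXT:
  # per-level abdominal (rectus/oblique wall) flexor moments act as the
  # antagonists of the erector slips; the psoas slips stay available as the
  # local muscle of the sagittal movements
  - {name: erector_L1, type: global, vertebra: L1, axis: EXT}
  - {name: erector_L2, type: global, vertebra: L2, axis: EXT}
  - {name: erector_L3, type: global, vertebra: L3, axis: EXT}
  - {name: erector_L4, type: global, vertebra: L4, axis: EXT}
  - {name: erector_L5, type: global, vertebra: L5, axis: EXT}
  - {name: rectus_L1, type: global, vertebra: L1, axis: FLX}
  - {name: rectus_L2, type: global, vertebra: L2, axis: FLX}
  - {name: rectus_L3, type: global, vertebra: L3, axis: FLX}
  - {name: rectus_L4, type: global, vertebra: L4, axis: FLX}
  - {name: rectus_L5, type: global, vertebra: L5, axis: FLX}
  - {name: psoas_L3, type: local, vertebra: L3, anchor: [35, -50, -90], attach: [20, -5, 0], bilateral: yes}
LB:
  - {name: oblique,         type: global, vertebra: L1, axis: LB}
  - {name: multifidus_L1_r, type: global, vertebra: L1, axis: LB}
  - {name: multifidus_L2_r, type: global, vertebra: L2, axis: LB}
  - {name: multifidus_L3_r, type: global, vertebra: L3, axis: LB}
  - {name: multifidus_L4_r, type: global, vertebra: L4, axis: LB}
  - {name: multifidus_L5_r, type: global, vertebra: L5, axis: LB}
  - {name: multifidus_L1_l, type: global, vertebra: L1, axis: -LB}
  - {name: multifidus_L2_l, type: global, vertebra: L2, axis: -LB}
  - {name: multifidus_L3_l, type: global, vertebra: L3, axis: -LB}
  - {name: multifidus_L4_l, type: global, vertebra: L4, axis: -LB}
  - {name: multifidus_L5_l, type: global, vertebra: L5, axis: -LB}
AR:
  - {name: oblique,         type: global, vertebra: L1, axis: AR}
  - {name: multifidus_L1_r, type: global, vertebra: L1, axis: AR}
  - {name: multifidus_L2_r, type: global, vertebra: L2, axis: AR}
  - {name: multifidus_L3_r, type: global, vertebra: L3, axis: AR}
  - {name: multifidus_L4_r, type: global, vertebra: L4, axis: AR}
  - {name: multifidus_L5_r, type: global, vertebra: L5, axis: AR}
  - {name: multifidus_L1_l, type: global, vertebra: L1, axis: -AR}
  - {name: multifidus_L2_l, type: global, vertebra: L2, axis: -AR}
  - {name: multifidus_L3_l, type: global, vertebra: L3, axis: -AR}
  - {name: multifidus_L4_l, type: global, vertebra: L4, axis: -AR}
  - {name: multifidus_L5_l, type: global, vertebra: L5, axis: -AR}
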