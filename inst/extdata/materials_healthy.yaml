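# Healthy lumbar spine material card.
# Bone rows are metadata in the reduced model: vertebrae are treated as rigid
# bodies (bone is 2-4 orders of magnitude stiffer than discs and ligaments).
name: healthy
bone:
  outer_vertebral_endplates:        {E: 12000, nu: 0.3}
  intermediate_vertebral_endplates: {E: 6000,  nu: 0.3}
  centre_vertebral_endplates:       {E: 2000,  nu: 0.3}
  walls_vertebral_body:             {E: 12000, nu: 0.3}
  cancellous_bone:                  {E: 100,   nu: 0.2}
  posterior_vertebra:               {E: 3000,  nu: 0.3}
cartilage: {E: 50, nu: 0.4}
annulus: {E: 4.2, nu: 0.45}
nucleus:
  model: mooney_rivlin
  C01: 0.0343          # MPa
  C10: 0.1369          # MPa
  incompressible: true
  penalty_bulk: 2200   # MPa, volumetric penalty enforcing incompressibility
fiber_layers:
  E: [360, 408, 455, 503, 550]   # MPa, layer 1 (innermost) .. 5 (outermost)
  nu: 0.3
ligaments:
  # E1 (MPa), transition strain (dimensionless), E2 (MPa); tension-only bilinear
  ALL: {E1: 7.8,  transition_strain: 0.12,  E2: 20.0}
  PLL: {E1: 10.0, transition_strain: 0.11,  E2: 50.0}
  LF:  {E1: 15.0, transition_strain: 0.062, E2: 19.0}
  ITL: {E1: 10.0, transition_strain: 0.18,  E2: 59.0}
  CL:  {E1: 7.5,  transition_strain: 0.25,  E2: 33.0}
  ISL: {E1: 8.0,  transition_strain: 0.20,  E2: 15.0}
  SSL: {E1: 10.0, transition_strain: 0.14,  E2: 12.0}
  ILL: {E1: 7.8,  transition_strain: 0.12,  E2: 20.0}
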