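# Degenerated-disc material card (applied at one level, default L5-S1).
# Differs from the healthy card only in the disc constituents: stiffer but less
# confined annulus ground substance, a compressible elastic nucleus (dehydrated),
# and fibre layer moduli reduced to one tenth.
name: degenerated
bone:
  outer_vertebral_endplates:        {E: 12000, nu: 0.3}
  intermediate_vertebral_endplates: {E: 6000,  nu: 0.3}
  centre_vertebral_endplates:       {E: 2000,  nu: 0.3}
  walls_vertebral_body:             {E: 12000, nu: 0.3}
  cancellous_bone:                  {E: 100,   nu: 0.2}
  posterior_vertebra:               {E: 3000,  nu: 0.3}
cartilage: {E: 50, nu: 0.4}
annulus: {E: 6.0, nu: 0.35}
nucleus:
  model: elastic
  E: 1.3               # MPa, compressible
  nu: 0.4
fiber_layers:
  E: [36.0, 40.8, 45.5, 50.3, 55.0]
  nu: 0.3
ligaments:
  ALL: {E1: 7.8,  transition_strain: 0.12,  E2: 20.0}
  PLL: {E1: 10.0, transition_strain: 0.11,  E2: 50.0}
  LF:  {E1: 15.0, transition_strain: 0.062, E2: 19.0}
  ITL: {E1: 10.0, transition_strain: 0.18,  E2: 59.0}
  CL:  {E1: 7.5,  transition_strain: 0.25,  E2: 33.0}
  ISL: {E1: 8.0,  transition_strain: 0.20,  E2: 15.0}
  SSL: {E1: 10.0, transition_strain: 0.14,  E2: 12.0}
  ILL: {E1: 7.8,  transition_strain: 0.12,  E2: 20.0}
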