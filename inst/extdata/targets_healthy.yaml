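# Healthy-model calibration targets: cumulative vertebra-vs-sacrum rotations
# (degrees, movement-positive). Per-level shape follows the radiological
# per-level pattern, rescaled so that L1 matches the model's global maximum for
# each movement. Axial rotation has no radiological arm; segmental targets are
# uniform across levels (no noticeable per-level difference in torsion).
FLX: {L1: 34.40, L2: 30.661, L3: 25.116, L4: 18.335, L5: 9.821}
EXT: {L1: 35.58, L2: 31.391, L3: 29.122, L4: 22.278, L5: 11.630}
LB:  {L1: 19.33, L2: 16.587, L3: 13.316, L4: 7.806,  L5: 3.478}
AR:  {L1: 9.96,  L2: 7.968,  L3: 5.976,  L4: 3.984,  L5: 1.992}
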