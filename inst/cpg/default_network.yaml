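tau:
- 0.0306084
- 0.0306084
- 0.0306084
- 0.0306084
- 0.0306084
- 0.0306084
- 0.0306084
- 0.0306084
- 0.0306084
- 0.0306084
- 0.0306084
- 0.0306084
- 0.0306084
- 0.0306084
beta: 1.8365425
W:
- 0.0000000 -2.3790514 -0.6860897 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000
  0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000
- -2.3790514 0.0000000 0.0000000 -0.6860897 0.0000000 0.0000000 0.0000000 0.0000000
  0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000
- -0.6860897 0.0000000 0.0000000 -2.3790514 0.0000000 0.0000000 0.0000000 0.0000000
  0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000
- 0.0000000 -0.6860897 -2.3790514 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000
  0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000
- 0.2591522 0.0000000 0.0000000 0.0000000 0.0000000 -1.8440486 0.0000000 0.0000000
  0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000
- 0.000000 0.000000 0.000000 0.000000 -1.844049 0.000000 0.000000 0.000000 0.000000
  0.000000 0.000000 0.000000 0.000000 0.000000
- 0.0000000 0.0000000 0.2591522 0.0000000 0.0000000 0.0000000 0.0000000 -1.8440486
  0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000
- 0.000000 0.000000 0.000000 0.000000 0.000000 0.000000 -1.844049 0.000000 0.000000
  0.000000 0.000000 0.000000 0.000000 0.000000
- 0.2866568 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000
  0.0000000 -1.8440486 0.0000000 0.0000000 0.0000000 0.0000000
- 0.000000 0.000000 0.000000 0.000000 0.000000 0.000000 0.000000 0.000000 -1.844049
  0.000000 0.000000 0.000000 0.000000 0.000000
- 0.0000000 0.0000000 0.2866568 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000
  0.0000000 0.0000000 0.0000000 -1.8440486 0.0000000 0.0000000
- 0.000000 0.000000 0.000000 0.000000 0.000000 0.000000 0.000000 0.000000 0.000000
  0.000000 -1.844049 0.000000 0.000000 0.000000
- 0.000000 0.000000 0.000000 0.000000 0.000000 0.000000 0.000000 0.000000 0.000000
  0.000000 0.000000 0.000000 0.000000 -3.751406
- 0.000000 0.000000 0.000000 0.000000 0.000000 0.000000 0.000000 0.000000 0.000000
  0.000000 0.000000 0.000000 -3.751406 0.000000
fb_gains:
  hip_stretch: 6.5098803
  hip_contra_contact: 3.668006
  hip_own_contact: 0.7720831
  pelvis_posture: 44.4612835
  knee_swing_flex: 0.1903023
  knee_load: 153.3455501
  knee_terminal_swing: 4.505858
  ankle_swing_dorsi: 2.2474842
  ankle_pushoff: 17.5634435
  ankle_stance_tonic: 2.4117495
  trunk_lean: 3.9992562
  trunk_rate: 11.3170648
  pelvis_rate: 9.5456531
  pelvis_ref: 0.0297745
  trunk_ref: 0.22546
  knee_preswing: 2.2249449
  hip_stretch_rate: 0.0828448
  capture_gain: 0.3341806
  ankle_pitch: 9.0440408
torque_gain:
- 1.3160838
- 2.2825426
- 2.2825426
- 0.2184323
- 0.2184323
- 0.8928522
- 0.8928522
load_ref: 206.0
literal_coupling: no
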