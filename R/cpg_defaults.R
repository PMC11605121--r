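# Calibrated oscillator network constants (generated by the calibration
# run; see the methods vignette for what was calibrated and why).

# connection weights, feedback gains, time constants, torque unit
# constants shared by all three gait models
sg_network_constants <- function() {
  W <- matrix(c(
    0, -2.379, -0.6861, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
    -2.379, 0, 0, -0.6861, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
    -0.6861, 0, 0, -2.379, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
    0, -0.6861, -2.379, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
    0.2592, 0, 0, 0, 0, -1.844, 0, 0, 0, 0, 0, 0, 0, 0,
    0, 0, 0, 0, -1.844, 0, 0, 0, 0, 0, 0, 0, 0, 0,
    0, 0, 0.2592, 0, 0, 0, 0, -1.844, 0, 0, 0, 0, 0, 0,
    0, 0, 0, 0, 0, 0, -1.844, 0, 0, 0, 0, 0, 0, 0,
    0.2867, 0, 0, 0, 0, 0, 0, 0, 0, -1.844, 0, 0, 0, 0,
    0, 0, 0, 0, 0, 0, 0, 0, -1.844, 0, 0, 0, 0, 0,
    0, 0, 0.2867, 0, 0, 0, 0, 0, 0, 0, 0, -1.844, 0, 0,
    0, 0, 0, 0, 0, 0, 0, 0, 0, 0, -1.844, 0, 0, 0,
    0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, -3.751,
    0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, -3.751, 0
  ), nrow = 14, byrow = TRUE)
  list(
    tau = rep(0.03061, 14),
    beta = 1.837,
    W = W,
    fb_gains = c(
      hip_stretch = 6.51,
      hip_contra_contact = 3.668,
      hip_own_contact = 0.7721,
      pelvis_posture = 44.46,
      knee_swing_flex = 0.1903,
      knee_load = 153.3,
      knee_terminal_swing = 4.506,
      ankle_swing_dorsi = 2.247,
      ankle_pushoff = 17.56,
      ankle_stance_tonic = 2.412,
      trunk_lean = 3.999,
      trunk_rate = 11.32,
      pelvis_rate = 9.546,
      pelvis_ref = 0.02977,
      trunk_ref = 0.2255,
      knee_preswing = 2.225,
      hip_stretch_rate = 0.08284,
      capture_gain = 0.3342,
      ankle_pitch = 9.044
    ),
    torque_gain = c(1.316, 2.283, 2.283, 0.2184, 0.2184, 0.8929, 0.8929),
    load_ref = 206,
    literal_coupling = FALSE
  )
}
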