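#' Default oscillator network constants
#'
#' The fourteen neurons form seven flexor/extensor pairs, one per joint
#' (right/left hip, knee, ankle, and the trunk joint).  Neuron order:
#' hipF_R, hipE_R, hipF_L, hipE_L, kneeF_R, kneeE_R, kneeF_L, kneeE_L,
#' ankF_R, ankE_R, ankF_L, ankE_L, trunkF, trunkE.
#'
#' The connection weights `W` implement mutual inhibition within each pair,
#' mutual inhibition between the contralateral hip flexors and between the
#' contralateral hip extensors (anti-phase alternation), and modest
#' ipsilateral excitation from the hip flexor to the same-side knee flexor
#' and dorsiflexor (swing synergy).  The diagonal is zero.  The remaining
#' constants (absolute time constants `tau`, adaptation coefficient `beta`,
#' sensory-feedback gains, the torque unit constant, and the load
#' normalisation) are the package's musculoskeletal calibration: they are
#' shared by all three gait models and were frozen after calibrating the
#' young-adult configuration against its reference gait means.
#'
#' @return list with `tau` (s, 14), `beta`, `W` (14 x 14), `fb_gains`,
#'   `torque_gain` (N m per unit transfer), `load_ref` (N),
#'   `literal_coupling` (logical; keep the printed self-indexed coupling
#'   reading of the oscillator equations for comparison runs).
#' @export
cpg_network_default <- function() {
  sg_network_constants()
}

#' Assemble full oscillator parameters for a gait model
#'
#' Merges the Table-style gait model values (`u0`, `tau/tau'` ratio, transfer
#' coefficients, noise percentage) into the network constants.  The
#' adaptation time constants are derived from the model's ratio:
#' `tau' = tau / ratio`.
#'
#' @param model a [gait_model()] object or model name.
#' @param network network constants, see [cpg_network_default()].
#' @return list of class `sg_cpg_parameters` with everything the dynamics
#'   core needs: `tau`, `tau_prime`, `beta`, `W`, `literal_coupling`, `p`,
#'   `torque_gain`, `fb_gains`, `load_ref`, plus `u0`, `noise_pct`, `model`.
#' @export
cpg_parameters <- function(model = "young", network = cpg_network_default()) {
  if (is.character(model)) model <- gait_model(model)
  stopifnot(inherits(model, "sg_gait_model"))
  stopifnot(all(network$tau > 0), model$tau_ratio > 0)
  params <- list(
    model = model$name,
    tau = network$tau,
    tau_prime = network$tau / model$tau_ratio,
    beta = network$beta,
    W = network$W,
    literal_coupling = isTRUE(network$literal_coupling),
    p = model$p,
    torque_gain = network$torque_gain,
    fb_gains = unname(network$fb_gains),
    load_ref = network$load_ref,
    fb_scale = 1.0,
    u0 = model$u0,
    noise_pct = model$noise_pct
  )
  class(params) <- "sg_cpg_parameters"
  params
}

#' Half-wave rectification of neuron states
#'
#' The neuron output nonlinearity: `f(u) = max(0, u)`.
#'
#' @param u numeric vector.
#' @return numeric vector, elementwise `max(0, u)`.
#' @export
rectify <- function(u) sg_rectify(as.numeric(u))

#' Time derivatives of the oscillator states
#'
#' Evaluates the coupled leaky-neuron equations with adaptation: the inner
#' state `u_i` decays with time constant `tau_i`, is inhibited by the
#' rectified adaptation state `beta * f(v_i)`, receives the weighted coupling
#' `sum_j w_ij f(u_j)`, the (noisy) steady input, and sensory feedback `S_i`;
#' the adaptation state `v_i` tracks `f(u_i)` with time constant `tau'_i`.
#'
#' @param u,v_adapt numeric(14) inner and adaptation states.
#' @param params an [cpg_parameters()] object.
#' @param feedback numeric(14) sensory feedback values `S_i`.
#' @param u0_noisy scalar steady input for this evaluation.
#' @return list with `du` and `dv`, each numeric(14).
#' @export
neuron_derivatives <- function(u, v_adapt, params, feedback = rep(0, 14),
                               u0_noisy = params$u0) {
  d <- sg_neuron_derivatives(as.numeric(u), as.numeric(v_adapt),
                             unclass(params), as.numeric(feedback), u0_noisy)
  lapply(d, as.numeric)
}

#' Joint torques from neuron outputs
#'
#' Maps the fourteen rectified neuron outputs through the eighteen transfer
#' channels onto the seven joint torques (trunk, right/left hip, knee,
#' ankle).  Channels are flexor-minus-extensor and linear in the outputs;
#' several channels are gated by the ipsilateral or contralateral foot load
#' (`hR`, `hL` in \[0, 1\]), mirroring stance/swing muscle synergies.
#'
#' @param outputs numeric(14) rectified neuron outputs.
#' @param params an [cpg_parameters()] object (uses `p` and `torque_gain`).
#' @param hR,hL right/left normalized foot loads in \[0, 1\].
#' @return numeric(7) active joint torques, N m, order trunk, hip R, hip L,
#'   knee R, knee L, ankle R, ankle L.
#' @export
active_torques <- function(outputs, params, hR = 0, hL = 0,
                           theta = rep(0, 8)) {
  stopifnot(all(outputs >= 0))
  as.numeric(sg_active_torques(as.numeric(outputs), unclass(params), hR, hL,
                               as.numeric(theta)))
}

#' Default joint-limit specification for the passive torques
#'
#' Relative joint angles (distal minus proximal segment angle, rad) outside
#' these ranges engage a stiff viscoelastic stop; inside them the passive
#' torque is zero.  Order: trunk, hip R, hip L, knee R, knee L, ankle R,
#' ankle L.  The knee limit at 0 rad prevents hyperextension.
#'
#' @param k_stop stop stiffness, N m / rad.
#' @param b_stop stop damping, N m s / rad.
#' @return list with `limits` (7 x 2), `k_stop`, `b_stop`.
#' @export
passive_spec_default <- function(k_stop = 500, b_stop = 50) {
  limits <- rbind(
    trunk = c(-0.15, 0.15),
    hip_R = c(-0.50, 1.20),
    hip_L = c(-0.50, 1.20),
    knee_R = c(-2.20, 0.00),
    knee_L = c(-2.20, 0.00),
    ankle_R = c(-0.80, 0.60),
    ankle_L = c(-0.80, 0.60)
  )
  list(limits = unname(limits), k_stop = k_stop, b_stop = b_stop)
}

#' Passive joint-limit torques
#'
#' Viscoelastic stops: zero inside the neutral range and a stiff restoring
#' torque plus damping beyond the joint limits.
#'
#' @param theta numeric(8) segment angles, rad.
#' @param omega numeric(8) segment angular velocities, rad/s.
#' @param passive a [passive_spec_default()] list.
#' @param anthro an [build_anthropometry()] object (for the joint pairing).
#' @return numeric(7) passive joint torques, N m.
#' @export
passive_torques <- function(theta, omega = rep(0, 8),
                            passive = passive_spec_default(),
                            anthro = build_anthropometry()) {
  jp <- joint_pairs(anthro)
  as.numeric(sg_passive_torques(as.numeric(theta), as.numeric(omega), passive,
                                jp))
}

joint_pairs <- function(anthro) {
  matrix(as.integer(anthro$joints[, 1:2]), ncol = 2)
}

#' Sensory feedback to the fourteen neurons
#'
#' Posture- and contact-dependent signals: thigh-angle stretch responses and
#' pelvis-posture correction at the hips, load and terminal-swing responses
#' at the knees, swing dorsiflexion and stance push-off drive at the ankles,
#' and upright-lean correction at the trunk.  Left and right are exact
#' mirror images.
#'
#' @param state list with `q`, `v` (redundant-coordinate state).
#' @param loads list or vector with right/left normalized foot loads
#'   (`hR`, `hL` in \[0, 1\]); contact-gated components vanish when a foot is
#'   airborne.
#' @param model a walker model list from [walker_model()].
#' @return numeric(14) feedback values `S_i`.
#' @export
sensory_feedback <- function(state, loads, model) {
  hR <- loads[[1]]; hL <- loads[[2]]
  as.numeric(sg_sensory_feedback(model, state$q, state$v, hR, hL))
}

#' Write/read the oscillator network constants as a plain-text parameter file
#'
#' The network (weights, gains, torque channel constants) is stored as YAML
#' so that every run's parameter provenance can be archived and re-loaded.
#'
#' @param network list as from [cpg_network_default()].
#' @param path file path.
#' @return `read_cpg_network()` returns the network list.
#' @export
write_cpg_network <- function(network, path) {
  out <- network
  out$W <- apply(network$W, 1, function(r) paste(format(r, trim = TRUE), collapse = " "))
  out$fb_gains <- as.list(network$fb_gains)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_cpg_network
#' @export
read_cpg_network <- function(path) {
  raw <- yaml::read_yaml(path)
  W <- t(vapply(raw$W, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]]),
                numeric(14)))
  raw$W <- W
  raw$fb_gains <- unlist(raw$fb_gains)
  raw$tau <- as.numeric(raw$tau)
  raw
}
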