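#' Simulation configuration
#'
#' Every option defaults to the study protocol: friction switch at 5 m, fall
#' classification window 5 to 15 m, a fall at hip height below 0.70 m, slips
#' at stance-foot speed above 0.3 m/s (held at least 10 ms), gait events from
#' a 1 N vertical ground-force threshold with 10 ms debounce.
#'
#' @param dt integrator step, s (fixed-step 4th-order Runge-Kutta).
#' @param record_dt trajectory sampling interval, s.
#' @param t_max wall limit of simulated time, s.
#' @param x_stop stop once the whole-body CoM passes this distance, m.
#' @param switch_x friction switch position, m.
#' @param window fall classification window (m from start), length 2.
#' @param fall_hip_height hip height defining a fall, m.
#' @param slip_speed stance-foot speed defining a slip, m/s.
#' @param slip_hold minimum duration the slip condition must hold, s.
#' @param force_threshold vertical force defining a loaded foot, N.
#' @param event_debounce contact-event debounce, s.
#' @param v0 initial forward CoM velocity, m/s; `NA` scales the default
#'   1 m/s push with the model's tonic drive (`u0 / 7.08`), so weaker-driven
#'   models start with a proportionally gentler push.
#' @param baumgarte_alpha,baumgarte_beta2 constraint stabilization gains
#'   (velocity and position terms).
#' @param proj_tol post-step constraint projection tolerance, m.
#' @param hip_stop hard stop once the hip descends below this height, m
#'   (well past the fall threshold, so the fall frame is always recorded).
#' @param g gravitational acceleration, m/s^2.
#' @return list of class `sg_config`.
#' @export
sim_config <- function(dt = 2e-4, record_dt = 1e-3, t_max = 60, x_stop = 15,
                       switch_x = 5, window = c(5, 15),
                       fall_hip_height = 0.70, slip_speed = 0.3,
                       slip_hold = 0.010, force_threshold = 1,
                       event_debounce = 0.010, v0 = NA,
                       baumgarte_alpha = 100, baumgarte_beta2 = 2500,
                       proj_tol = 1e-10, hip_stop = 0.45, g = 9.81) {
  stopifnot(dt > 0, record_dt >= dt, t_max > 0)
  structure(as.list(environment()), class = "sg_config")
}

#' Assemble the full walker model for the dynamics core
#'
#' @param params an [cpg_parameters()] object.
#' @param ground an [ground_model()] object.
#' @param anthro an [build_anthropometry()] object.
#' @param passive a [passive_spec_default()] list.
#' @param g gravitational acceleration, m/s^2.
#' @return model list consumed by the compiled core.
#' @export
walker_model <- function(params = cpg_parameters("young"),
                         ground = ground_model(),
                         anthro = build_anthropometry(),
                         passive = passive_spec_default(), g = 9.81) {
  list(
    mech = mech_list(anthro),
    contacts = list(points = unname(anthro$contacts)),
    ground = unclass(ground),
    cpg = unclass(params),
    passive = passive,
    joint_pairs = joint_pairs(anthro),
    g = g,
    hip_seg = 1L,
    hip_local = c(0, -0.5 * anthro$segments$length[2]),
    anthro = anthro
  )
}

# frozen near-standing initial posture with a small forward push; the first
# metres of every run are treated as transient
initial_state <- function(anthro, v0 = 1.0) {
  # straight-kneed split stance, both feet flat on the ground
  angles <- c(-0.03, -0.03, 0.18, -0.18, 0.18, -0.18, 0.00, 0.00)
  pose <- kinematic_pose(anthro, angles, pelvis_xy = c(0, 0.95),
                         settle_feet = TRUE)
  pose$v[1:8] <- v0
  u <- rep(0.1, 14)
  u[c(3, 2)] <- 1.0  # kick rear-leg (left) hip flexor / right hip extensor
  list(q = pose$q, v = pose$v, u = u, v_adapt = rep(0, 14),
       anchor_x = rep(0, 4), in_contact = rep(0L, 4), t = 0)
}

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate one walking trial
#'
#' Integrates the coupled mechanical and neural dynamics with a fixed-step
#' 4th-order Runge-Kutta scheme; fully deterministic given `(model, mu_s,
#' seed)`.  White noise on the steady input `u0` is drawn once per
#' integration step from a stream seeded by `seed`.
#'
#' @param model a [gait_model()] object or model name.
#' @param mu_s static coefficient of friction applied from
#'   `config$switch_x` onward, or `NA` to leave friction unset for the whole
#'   run.
#' @param seed integer seed for the noise stream.
#' @param config an [sim_config()] object.
#' @param network oscillator network constants, see [cpg_network_default()].
#' @param anthro an [build_anthropometry()] object.
#' @param init optional initial state (as from `integrate_step()` chaining);
#'   default is the frozen near-standing posture.
#' @return A trajectory tibble of class `sg_trajectory`: one row per recorded
#'   sample with the full segment state, contact forces, neuron outputs, and
#'   derived gait columns (hip, CoM, toe/heel/ankle positions, per-foot
#'   loads).  Attributes carry the run metadata (`model`, `mu_s`, `seed`,
#'   `status`, `config`).
#' @export
simulate_walk <- function(model = "young", mu_s = NA, seed = 1,
                          config = sim_config(), network = cpg_network_default(),
                          anthro = build_anthropometry(), init = NULL) {
  if (is.character(model)) model <- gait_model(model)
  params <- cpg_parameters(model, network)
  ground <- ground_model(friction = friction_switch(mu_s, config$switch_x))
  wm <- walker_model(params, ground, anthro,
                     passive_spec_default(), config$g)
  if (is.na(config$v0)) config$v0 <- model$u0 / 7.08
  if (is.null(init)) init <- initial_state(anthro, config$v0)
  n_steps <- ceiling(config$t_max / config$dt)
  u0_per_step <- with_local_seed(seed, noisy_u0(model, n_steps))
  record_every <- max(1L, as.integer(round(config$record_dt / config$dt)))
  res <- sg_run_walker(wm, init$q, init$v, init$u, init$v_adapt,
                       init$anchor_x, as.integer(init$in_contact),
                       u0_per_step, init$t, config$dt, n_steps, record_every,
                       config$x_stop, config$hip_stop, config$t_max,
                       config$baumgarte_alpha, config$baumgarte_beta2,
                       config$proj_tol)
  traj <- trajectory_tibble(res$trajectory, anthro)
  res$state <- lapply(res$state, as.numeric)
  status <- c("completed", "fell", "timeout", "diverged")[res$status + 1]
  attr(traj, "model") <- model$name
  attr(traj, "mu_s") <- mu_s
  attr(traj, "seed") <- seed
  attr(traj, "status") <- status
  attr(traj, "config") <- config
  attr(traj, "final_state") <- res$state
  class(traj) <- c("sg_trajectory", class(traj))
  traj
}

#' Advance the coupled state by one or more fixed steps
#'
#' Low-level single-step interface to the integrator; deterministic given the
#' state and the supplied steady-input values.
#'
#' @param state full state list (`q`, `v`, `u`, `v_adapt`, `anchor_x`,
#'   `in_contact`, `t`).
#' @param wm a [walker_model()] list.
#' @param dt step size, s.
#' @param n_steps number of steps.
#' @param u0_per_step steady input per step (recycled); defaults to the
#'   model's noiseless `u0`.
#' @param config an [sim_config()] object (stabilization settings).
#' @return list with the advanced `state` and the recorded `trajectory`.
#' @export
integrate_step <- function(state, wm, dt = 2e-4, n_steps = 1,
                           u0_per_step = NULL, config = sim_config(dt = dt)) {
  stopifnot(dt > 0)
  if (is.null(u0_per_step)) u0_per_step <- wm$cpg$u0
  res <- sg_run_walker(wm, state$q, state$v, state$u, state$v_adapt,
                       state$anchor_x, as.integer(state$in_contact),
                       u0_per_step, state$t, dt, n_steps, 1L,
                       Inf, -Inf, Inf,
                       config$baumgarte_alpha, config$baumgarte_beta2,
                       config$proj_tol)
  if (res$status == 3) {
    abort(sprintf("simulation diverged at t = %.4f s", res$state$t))
  }
  res$state <- lapply(res$state, as.numeric)
  list(state = res$state,
       trajectory = trajectory_tibble(res$trajectory, wm$anthro))
}

#' Accelerations and joint constraint forces of the walker
#'
#' Solves the constrained equations of motion at one instant: given the
#' body state, joint torques, and ground forces, returns the segment
#' accelerations together with the pin-joint constraint forces.  The force
#' pair at each joint is equal and opposite by construction.
#'
#' @param state list with `q`, `v` (length-24 each).
#' @param active_torque,passive_torque numeric(7) joint torques, N m.
#' @param ground_forces 4 x 2 matrix of contact-point forces (rows: right
#'   heel, right toe, left heel, left toe; columns Fx, Fy), N.
#' @param anthro an [build_anthropometry()] object.
#' @param pin optional world pin: list with `seg` (1-based segment id),
#'   `local` (length-2 offset on the segment), `world` (length-2 target
#'   point) — used to anchor the walker for hanging-chain analyses.
#' @param g gravitational acceleration, m/s^2.
#' @param baumgarte_alpha,baumgarte_beta2 stabilization gains.
#' @return list with `qdd` (24), `joint_forces` (tibble: joint, Fx, Fy),
#'   `lambda`, `rcond`, `residual`.
#' @export
compute_accelerations <- function(state, active_torque = rep(0, 7),
                                  passive_torque = rep(0, 7),
                                  ground_forces = matrix(0, 4, 2),
                                  anthro = build_anthropometry(), pin = NULL,
                                  g = 9.81, baumgarte_alpha = 0,
                                  baumgarte_beta2 = 0) {
  q <- state$q; v <- state$v
  mech <- mech_list(anthro)
  if (!is.null(pin)) {
    mech$joints <- rbind(
      mech$joints,
      c(-1, pin$seg - 1, pin$world[1], pin$world[2], pin$local[1], pin$local[2])
    )
  }
  f <- generalized_forces_r(q, anthro, active_torque + passive_torque,
                            ground_forces, g)
  out <- sg_compute_accelerations(mech, q, v, f, baumgarte_alpha,
                                  baumgarte_beta2)
  nj <- nrow(anthro$joints)
  out$qdd <- as.numeric(out$qdd)
  out$residual <- as.numeric(out$residual)
  lam <- as.numeric(out$lambda)
  joint_forces <- tibble(
    joint = c("trunk", "hip_R", "hip_L", "knee_R", "knee_L",
              "ankle_R", "ankle_L"),
    Fx = lam[seq(1, 2 * nj, by = 2)][1:7],
    Fy = lam[seq(2, 2 * nj, by = 2)][1:7]
  )
  list(qdd = out$qdd, joint_forces = joint_forces, lambda = lam,
       rcond = out$rcond, residual = out$residual)
}

# gravity + contact-point forces + joint torques mapped to the redundant
# generalized coordinates
generalized_forces_r <- function(q, anthro, torques, ground_forces, g) {
  f <- numeric(24)
  m <- anthro$segments$mass
  f[9:16] <- -m * g
  for (k in seq_len(nrow(anthro$contacts))) {
    s <- anthro$contacts[k, 1] + 1
    cc <- anthro$contacts[k, 2:3]
    th <- q[16 + s]
    r <- c(cc[1] * cos(th) - cc[2] * sin(th), cc[1] * sin(th) + cc[2] * cos(th))
    f[s] <- f[s] + ground_forces[k, 1]
    f[8 + s] <- f[8 + s] + ground_forces[k, 2]
    f[16 + s] <- f[16 + s] + r[1] * ground_forces[k, 2] - r[2] * ground_forces[k, 1]
  }
  jp <- anthro$joints[, 1:2] + 1
  for (j in seq_len(nrow(jp))) {
    f[16 + jp[j, 2]] <- f[16 + jp[j, 2]] + torques[j]
    f[16 + jp[j, 1]] <- f[16 + jp[j, 1]] - torques[j]
  }
  f
}

# ---------------------------------------------------------------------------
# trajectory construction

seg_suffix <- c("hat", "pelvis", "thigh_r", "thigh_l", "shank_r", "shank_l",
                "foot_r", "foot_l")
pt_suffix <- c("heel_r", "toe_r", "heel_l", "toe_l")

trajectory_tibble <- function(mat, anthro) {
  cn <- c("t",
          paste0("x_", seg_suffix), paste0("y_", seg_suffix),
          paste0("th_", seg_suffix),
          paste0("vx_", seg_suffix), paste0("vy_", seg_suffix),
          paste0("om_", seg_suffix),
          as.vector(rbind(paste0("fgx_", pt_suffix), paste0("fgy_", pt_suffix))),
          as.vector(rbind(paste0("contact_", pt_suffix),
                          paste0("anchor_", pt_suffix))),
          paste0("y_n", 1:14))
  colnames(mat) <- cn
  tr <- as_tibble(mat)
  derive_gait_columns(tr, anthro)
}

# world position of a local point on a segment, vectorized over rows
point_world <- function(tr, seg, local) {
  th <- tr[[paste0("th_", seg)]]
  list(
    x = tr[[paste0("x_", seg)]] + local[1] * cos(th) - local[2] * sin(th),
    y = tr[[paste0("y_", seg)]] + local[1] * sin(th) + local[2] * cos(th)
  )
}

derive_gait_columns <- function(tr, anthro) {
  m <- anthro$segments$mass
  mtot <- sum(m)
  xs <- as.matrix(tr[paste0("x_", seg_suffix)])
  ys <- as.matrix(tr[paste0("y_", seg_suffix)])
  vxs <- as.matrix(tr[paste0("vx_", seg_suffix)])
  vys <- as.matrix(tr[paste0("vy_", seg_suffix)])
  tr$com_x <- as.vector(xs %*% m) / mtot
  tr$com_y <- as.vector(ys %*% m) / mtot
  tr$com_vx <- as.vector(vxs %*% m) / mtot
  tr$com_vy <- as.vector(vys %*% m) / mtot
  hip <- point_world(tr, "pelvis", c(0, -0.5 * anthro$segments$length[2]))
  tr$hip_x <- hip$x
  tr$hip_y <- hip$y
  ft <- anthro$foot
  for (side in c("r", "l")) {
    seg <- paste0("foot_", side)
    toe <- point_world(tr, seg, ft$toe)
    heel <- point_world(tr, seg, ft$heel)
    ank <- point_world(tr, seg, ft$ankle)
    tr[[paste0("toe_x_", side)]] <- toe$x
    tr[[paste0("toe_y_", side)]] <- toe$y
    tr[[paste0("heel_x_", side)]] <- heel$x
    tr[[paste0("heel_y_", side)]] <- heel$y
    tr[[paste0("ankle_x_", side)]] <- ank$x
    tr[[paste0("ankle_y_", side)]] <- ank$y
    tr[[paste0("foot_vx_", side)]] <- tr[[paste0("vx_", seg)]]
    tr[[paste0("fgy_", side)]] <- tr[[paste0("fgy_heel_", side)]] +
      tr[[paste0("fgy_toe_", side)]]
  }
  tr
}

#' @export
print.sg_trajectory <- function(x, ...) {
  cat("<sg_trajectory> model =", attr(x, "model") %||% "?",
      " mu_s =", format(attr(x, "mu_s")),
      " seed =", format(attr(x, "seed")),
      " status =", attr(x, "status") %||% "?", "\n")
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
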