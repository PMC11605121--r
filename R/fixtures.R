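# Kinematic gait fixtures with analytic ground truth.  These emulate the
# statistical structure of sagittal-plane gait traces (periodic strides with
# prescribed length, speed, clearances, duty factor, and per-stride noise)
# so the metrics and classification stages can be tested without the
# dynamics engine.  Foot paths are sinusoidal in swing and constant in
# stance, so the programmed extrema are exact.

#' Specification of a kinematic walker fixture
#'
#' @param stride_length nominal stride length, m.
#' @param speed nominal walking speed, m/s.
#' @param min_toe_clearance programmed minimum toe clearance at mid-swing, m.
#' @param max_heel_clearance programmed maximum heel clearance at mid-swing, m.
#' @param duty_factor fraction of the gait cycle each foot spends in stance,
#'   in (0.5, 0.8).
#' @param n_strides number of (right-foot) strides.
#' @param noise_sd per-stride multiplicative noise SD (fraction of the
#'   nominal value), applied independently to stride length and clearances.
#' @param seed RNG seed for the per-stride noise.
#' @param rcof peak traction ratio programmed into the stance force traces.
#' @param hip_height constant hip height of the non-falling walker, m.
#' @param total_mass supported mass (sets the vertical force scale), kg.
#' @param dt sample interval, s.
#' @return list of class `sg_fixture_spec`.
#' @export
fixture_spec <- function(stride_length = 1.4, speed = 1.25,
                         min_toe_clearance = 0.020, max_heel_clearance = 0.25,
                         duty_factor = 0.62, n_strides = 12, noise_sd = 0,
                         seed = 1, rcof = 0.2, hip_height = 0.92,
                         total_mass = 70, dt = 0.002) {
  stopifnot(duty_factor > 0.5, duty_factor < 0.8, stride_length > 0,
            speed > 0, min_toe_clearance > 0, max_heel_clearance > 0,
            noise_sd >= 0)
  structure(as.list(environment()), class = "sg_fixture_spec")
}

# swing paths: toe height has its exact minimum (= programmed clearance) at
# mid-swing between two lift humps; heel height peaks at mid-swing
toe_height <- function(s, c_min, h_lift = 0.10) {
  c_min * sin(pi * s)^2 + h_lift * sin(2 * pi * s)^2
}
heel_height <- function(s, h_max) h_max * sin(pi * s)^2
swing_progress <- function(s) s - sin(2 * pi * s) / (2 * pi)

# piecewise stance/swing horizontal position and height of one foot's
# reference point, given touchdown times td (length K+1) and positions X
foot_path <- function(t, td, X, duty, Tcyc, c_min_k, h_max_k, foot_len) {
  n <- length(t)
  toe_x <- numeric(n); toe_y <- numeric(n); heel_y <- numeric(n)
  k <- findInterval(t, td)
  k[k < 1] <- 1
  k[k > length(X) - 1] <- length(X) - 1
  t_td <- td[k]
  s_end <- t_td + duty * Tcyc
  in_stance <- t <= s_end | k >= length(X) - 0 # guarded below
  swing_len <- (1 - duty) * Tcyc
  s <- (t - s_end) / swing_len
  s[s < 0] <- 0; s[s > 1] <- 1
  stance <- t <= s_end
  toe_x <- X[k] + (X[k + 1] - X[k]) * ifelse(stance, 0, swing_progress(s))
  toe_y <- ifelse(stance, 0, toe_height(s, c_min_k[k]))
  heel_y <- ifelse(stance, 0, heel_height(s, h_max_k[k]))
  loaded <- stance & t >= td[1]
  list(toe_x = toe_x, toe_y = toe_y, heel_x = toe_x - foot_len,
       heel_y = heel_y, loaded = loaded,
       stance_progress = ifelse(loaded, (t - t_td) / (duty * Tcyc), NA_real_))
}

#' Generate a kinematic walker fixture
#'
#' Builds a trajectory tibble in the simulator's analysis schema (toe, heel,
#' ankle, hip, CoM traces and square-wave ground forces consistent with the
#' duty factor) with programmed per-stride stride lengths and clearances,
#' together with a ground-truth record of every per-stride value.
#'
#' @param spec an [fixture_spec()] object.
#' @return list of class `sg_fixture`: `trajectory` (tibble), `truth`
#'   (per-stride tibble: `stride`, `stride_length`, `stride_time`, `speed`,
#'   `min_toe_clearance`, `max_heel_clearance`), and `spec`.
#' @export
make_kinematic_walker <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "sg_fixture_spec"))
  Tcyc <- spec$stride_length / spec$speed
  K <- spec$n_strides
  draws <- with_local_seed(spec$seed, matrix(rnorm(3 * (K + 2)), ncol = 3))
  sl_k <- spec$stride_length * (1 + spec$noise_sd * draws[, 1])
  c_k <- spec$min_toe_clearance * pmax(0.1, 1 + spec$noise_sd * draws[, 2])
  h_k <- spec$max_heel_clearance * pmax(0.1, 1 + spec$noise_sd * draws[, 3])

  td_r <- (0:(K + 1)) * Tcyc
  X_r <- c(0, cumsum(sl_k[1:(K + 1)]))
  td_l <- td_r[-length(td_r)] + Tcyc / 2
  X_l <- (X_r[-length(X_r)] + X_r[-1]) / 2

  t <- seq(0, (K + 0.98) * Tcyc, by = spec$dt)
  fr <- foot_path(t, td_r, X_r, spec$duty_factor, Tcyc, c_k, h_k,
                  0.25)
  fl <- foot_path(t, td_l, X_l, spec$duty_factor, Tcyc, c_k, h_k,
                  0.25)

  W <- spec$total_mass * 9.81
  n_loaded <- pmax(1, fr$loaded + fl$loaded)
  fgy_r <- ifelse(fr$loaded, W / n_loaded, 0)
  fgy_l <- ifelse(fl$loaded, W / n_loaded, 0)
  shear <- function(sp, fgy) {
    ifelse(is.na(sp), 0, spec$rcof * fgy * sin(pi * pmin(1, pmax(0, sp))))
  }
  fgx_r <- shear(fr$stance_progress, fgy_r)
  fgx_l <- shear(fl$stance_progress, fgy_l)

  grad <- function(x) c(diff(x) / spec$dt, 0)
  ankle_x_r <- fr$toe_x - 0.15
  ankle_x_l <- fl$toe_x - 0.15
  com_x <- (ankle_x_r + ankle_x_l) / 2
  tr <- tibble(
    t = t,
    toe_x_r = fr$toe_x, toe_y_r = fr$toe_y,
    heel_x_r = fr$heel_x, heel_y_r = fr$heel_y,
    toe_x_l = fl$toe_x, toe_y_l = fl$toe_y,
    heel_x_l = fl$heel_x, heel_y_l = fl$heel_y,
    ankle_x_r = ankle_x_r, ankle_y_r = 0.07 + fr$heel_y,
    ankle_x_l = ankle_x_l, ankle_y_l = 0.07 + fl$heel_y,
    foot_vx_r = grad((fr$toe_x + fr$heel_x) / 2),
    foot_vx_l = grad((fl$toe_x + fl$heel_x) / 2),
    com_x = com_x, com_y = spec$hip_height + 0.05,
    com_vx = grad(com_x), com_vy = 0,
    hip_x = com_x, hip_y = spec$hip_height,
    fgx_heel_r = fgx_r / 2, fgy_heel_r = fgy_r / 2,
    fgx_toe_r = fgx_r / 2, fgy_toe_r = fgy_r / 2,
    fgx_heel_l = fgx_l / 2, fgy_heel_l = fgy_l / 2,
    fgx_toe_l = fgx_l / 2, fgy_toe_l = fgy_l / 2,
    fgy_r = fgy_r, fgy_l = fgy_l
  )
  truth <- tibble(
    stride = 1:K,
    stride_length = sl_k[1:K],
    stride_time = rep(Tcyc, K),
    speed = sl_k[1:K] / Tcyc,
    min_toe_clearance = c_k[1:K],
    max_heel_clearance = h_k[1:K]
  )
  out <- list(trajectory = tr, truth = truth, spec = spec)
  class(out) <- "sg_fixture"
  out
}

#' Scripted fall fixtures for the outcome classifier
#'
#' Constructs a trace whose label is known by construction: `slip_fall`
#' ramps a loaded stance foot above the slip speed threshold and then drops
#' the hip below the fall height; `trip_fall` freezes the feet (stance-foot
#' speed below threshold) while the CoM runs beyond the anterior
#' base-of-support border and the hip drops; `no_fall` keeps the hip high
#' throughout.
#'
#' @param kind one of `"slip_fall"`, `"trip_fall"`, `"no_fall"`.
#' @param seed RNG seed for the underlying walker's per-stride noise.
#' @param fall_step right-foot step index at which the scripted event starts.
#' @param spec base walker spec; the default covers the 5-15 m window.
#' @return list of class `sg_fixture` with `trajectory`, `expected` (the
#'   construction label), and `spec`.
#' @export
make_fall_fixture <- function(kind = c("slip_fall", "trip_fall", "no_fall"),
                              seed = 1, fall_step = 6,
                              spec = fixture_spec(n_strides = 12,
                                                  noise_sd = 0.03,
                                                  seed = seed)) {
  kind <- match.arg(kind)
  spec$seed <- seed
  fx <- make_kinematic_walker(spec)
  tr <- fx$trajectory
  if (kind == "no_fall") {
    out <- list(trajectory = tr, expected = "no_fall", spec = spec)
    class(out) <- "sg_fixture"
    return(out)
  }
  Tcyc <- spec$stride_length / spec$speed
  t_f <- fall_step * Tcyc + 0.02
  dt <- spec$dt
  if (kind == "slip_fall") {
    # loaded right foot accelerates forward past the slip threshold, then
    # the hip collapses
    keep <- tr$t <= t_f + 0.60
    tr <- tr[keep, ]
    after <- tr$t > t_f
    ramp_v <- 0.6 * pmin(1, (tr$t - t_f) / 0.05)
    disp <- cumsum(ifelse(after, ramp_v * dt, 0))
    for (cl in c("toe_x_r", "heel_x_r", "ankle_x_r")) {
      tr[[cl]] <- tr[[cl]] + disp
    }
    tr$foot_vx_r <- ifelse(after, ramp_v, tr$foot_vx_r)
    W <- spec$total_mass * 9.81
    tr$fgy_heel_r[after] <- W / 4
    tr$fgy_toe_r[after] <- W / 4
    tr$fgy_r[after] <- W / 2
    drop <- pmin(1, pmax(0, (tr$t - (t_f + 0.20)) / 0.30))
    tr$hip_y <- spec$hip_height - drop * 0.40
    tr$com_vx <- ifelse(after, -0.2, tr$com_vx)  # backward imbalance
  } else {
    # feet freeze (stance speed ~ 0) while the body keeps moving forward
    keep <- tr$t <= t_f + 0.80
    tr <- tr[keep, ]
    after <- tr$t > t_f
    i_f <- which(after)[1]
    frozen <- c("toe_x_r", "toe_y_r", "heel_x_r", "heel_y_r",
                "toe_x_l", "toe_y_l", "heel_x_l", "heel_y_l",
                "ankle_x_r", "ankle_y_r", "ankle_x_l", "ankle_y_l")
    for (cl in frozen) tr[[cl]][after] <- tr[[cl]][i_f]
    tr$foot_vx_r[after] <- 0
    tr$foot_vx_l[after] <- 0
    W <- spec$total_mass * 9.81
    for (cl in c("fgy_heel_r", "fgy_toe_r", "fgy_heel_l", "fgy_toe_l")) {
      tr[[cl]][after] <- W / 4
    }
    tr$fgy_r[after] <- W / 2
    tr$fgy_l[after] <- W / 2
    tr$com_x[after] <- tr$com_x[i_f] + 1.4 * (tr$t[after] - t_f)
    tr$com_vx[after] <- 1.4
    tr$hip_x[after] <- tr$com_x[after]
    drop <- pmin(1, pmax(0, (tr$t - (t_f + 0.35)) / 0.30))
    tr$hip_y <- spec$hip_height - drop * 0.40
  }
  out <- list(trajectory = tr, expected = kind, spec = spec)
  class(out) <- "sg_fixture"
  out
}
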