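#' Build the segment parameter set for the eight-segment walker
#'
#' Partitions a total body mass and standing height into the eight planar
#' segments of the walker (head-arms-trunk, pelvis, and left/right thighs,
#' shanks, and feet) using a fixed, documented proportional convention based
#' on standard body-segment-parameter tables (Winter-style mass fractions and
#' radii of gyration).  Segment lengths are chosen so that the standing model
#' height equals `total_height` exactly: ankle height + shank + thigh +
#' pelvis + HAT sum to the full stature.
#'
#' Segment angles are measured counterclockwise from the upward vertical;
#' x points along the direction of travel and y is up.
#'
#' @param total_mass total body mass in kg (default 70).
#' @param total_height standing height in m (default 1.8).
#' @return An object of class `sg_anthropometry`: a list with
#'   \describe{
#'     \item{segments}{tibble with one row per segment: `segment`, `mass`
#'       (kg), `length` (m), `com_offset` (m, distance of the center of mass
#'       from the proximal end), `inertia` (kg m^2 about the CoM).}
#'     \item{joints}{matrix describing the seven pin joints (0-based segment
#'       ids and local attachment offsets) consumed by the dynamics core.}
#'     \item{contacts}{matrix of the four ground-contact points (right/left
#'       heel and toe) as local offsets on the foot segments.}
#'     \item{foot}{heel/toe/ankle geometry of the foot segment.}
#'   }
#' @examples
#' a <- build_anthropometry(70, 1.8)
#' sum(a$segments$mass)  # 70
#' @export
build_anthropometry <- function(total_mass = 70, total_height = 1.8) {
  if (!is.numeric(total_mass) || length(total_mass) != 1 || !is.finite(total_mass) ||
      total_mass <= 0) {
    abort("`total_mass` must be a single positive number.")
  }
  if (!is.numeric(total_height) || length(total_height) != 1 || !is.finite(total_height) ||
      total_height <= 0) {
    abort("`total_height` must be a single positive number.")
  }
  H <- total_height
  m <- total_mass

  # mass fractions; HAT absorbs the remainder so the partition sums exactly
  f_pelvis <- 0.142
  f_thigh  <- 0.100
  f_shank  <- 0.0465
  f_foot   <- 0.0145
  f_hat    <- 1 - f_pelvis - 2 * (f_thigh + f_shank + f_foot)

  # length fractions of stature; the vertical stack is exactly H
  l_ankle  <- 0.039 * H   # ankle joint height above ground
  l_shank  <- 0.246 * H
  l_thigh  <- 0.245 * H
  l_pelvis <- 0.070 * H
  l_hat    <- H - l_ankle - l_shank - l_thigh - l_pelvis
  l_foot   <- 0.152 * H   # heel-to-toe length

  seg_names <- c("HAT", "pelvis", "thigh_R", "thigh_L",
                 "shank_R", "shank_L", "foot_R", "foot_L")
  mass <- m * c(f_hat, f_pelvis, f_thigh, f_thigh, f_shank, f_shank,
                f_foot, f_foot)
  len <- c(l_hat, l_pelvis, l_thigh, l_thigh, l_shank, l_shank,
           l_foot, l_foot)
  # CoM offset from the proximal end (HAT/pelvis proximal = lower end;
  # thigh/shank proximal = upper end); radii of gyration about the CoM
  com_frac <- c(0.45, 0.50, 0.433, 0.433, 0.433, 0.433, 0.50, 0.50)
  rg_frac  <- c(0.496, 0.310, 0.323, 0.323, 0.302, 0.302, 0.475, 0.475)
  com_off <- com_frac * len
  inertia <- mass * (rg_frac * len)^2

  segments <- tibble(
    segment = seg_names, mass = mass, length = len,
    com_offset = com_off, inertia = inertia
  )

  # foot geometry: ankle sits l_ankle above the sole; the heel is 22% of the
  # foot length behind the ankle, the toe the remaining 78% ahead; the foot
  # CoM is midway between heel and toe, halfway up to the ankle
  heel_back <- 0.22 * l_foot
  toe_fwd <- l_foot - heel_back
  # local offsets relative to the foot CoM (foot frame = world frame when flat)
  com_ahead_of_ankle <- (toe_fwd - heel_back) / 2
  foot <- list(
    length = l_foot, ankle_height = l_ankle,
    ankle = c(-com_ahead_of_ankle, l_ankle / 2),
    heel  = c(-l_foot / 2, -l_ankle / 2),
    toe   = c(l_foot / 2, -l_ankle / 2)
  )

  # attachment offsets in each segment's local frame (y along the segment,
  # positive toward the proximal/upper end)
  hat_low   <- c(0, -(com_frac[1] * l_hat))
  pel_top   <- c(0, (1 - com_frac[2]) * l_pelvis)
  pel_low   <- c(0, -com_frac[2] * l_pelvis)
  thigh_top <- c(0, com_frac[3] * l_thigh)
  thigh_low <- c(0, -(1 - com_frac[3]) * l_thigh)
  shank_top <- c(0, com_frac[5] * l_shank)
  shank_low <- c(0, -(1 - com_frac[5]) * l_shank)

  # joints: segA (proximal side), segB (distal side), local offsets; 0-based
  # ids for the dynamics core.  Order: trunk, hip R, hip L, knee R, knee L,
  # ankle R, ankle L.  Joint torques act +T on segB, -T on segA.
  joints <- rbind(
    c(1, 0, pel_top, hat_low),     # trunk: pelvis top - HAT bottom
    c(1, 2, pel_low, thigh_top),   # hip R
    c(1, 3, pel_low, thigh_top),   # hip L
    c(2, 4, thigh_low, shank_top), # knee R
    c(3, 5, thigh_low, shank_top), # knee L
    c(4, 6, shank_low, foot$ankle),# ankle R
    c(5, 7, shank_low, foot$ankle) # ankle L
  )
  colnames(joints) <- c("segA", "segB", "cAx", "cAy", "cBx", "cBy")

  contacts <- rbind(
    c(6, foot$heel), # right heel
    c(6, foot$toe),  # right toe
    c(7, foot$heel), # left heel
    c(7, foot$toe)   # left toe
  )
  colnames(contacts) <- c("seg", "cx", "cy")

  structure(
    list(segments = segments, joints = joints, contacts = contacts,
         foot = foot, total_mass = m, total_height = H),
    class = "sg_anthropometry"
  )
}

#' @export
print.sg_anthropometry <- function(x, ...) {
  cat("<sg_anthropometry> ", x$total_mass, " kg, ", x$total_height, " m\n", sep = "")
  print(x$segments)
  invisible(x)
}

# mechanism list consumed by the compiled core
mech_list <- function(anthro) {
  list(mass = anthro$segments$mass,
       inertia = anthro$segments$inertia,
       joints = unname(anthro$joints))
}

#' Pose the walker from joint-space angles
#'
#' Forward kinematics: given the eight segment angles (counterclockwise from
#' vertical) and the pelvis CoM position/velocity, returns the full
#' redundant-coordinate state with all seven joints exactly coincident.
#'
#' @param anthro an [build_anthropometry()] object.
#' @param angles numeric(8), segment angles in radians, in segment order
#'   (HAT, pelvis, thigh R, thigh L, shank R, shank L, foot R, foot L).
#' @param pelvis_xy pelvis CoM position, m.
#' @param pelvis_vxy pelvis CoM velocity, m/s.
#' @param rates numeric(8) segment angular velocities, rad/s.
#' @param settle_feet if `TRUE`, shift the whole body vertically so the lowest
#'   contact point touches the ground (y = 0).
#' @return list with `q`, `v` (length-24 state vectors, layout x(8), y(8),
#'   theta(8)).
#' @export
kinematic_pose <- function(anthro, angles, pelvis_xy = c(0, 0.96),
                           pelvis_vxy = c(0, 0), rates = rep(0, 8),
                           settle_feet = FALSE) {
  stopifnot(length(angles) == 8, length(rates) == 8)
  rot <- function(th, c2) {
    c(c2[1] * cos(th) - c2[2] * sin(th), c2[1] * sin(th) + c2[2] * cos(th))
  }
  drot <- function(th, c2) {
    c(-c2[1] * sin(th) - c2[2] * cos(th), c2[1] * cos(th) - c2[2] * sin(th))
  }
  pos <- matrix(NA_real_, 8, 2)
  vel <- matrix(NA_real_, 8, 2)
  pos[2, ] <- pelvis_xy
  vel[2, ] <- pelvis_vxy
  J <- anthro$joints
  # resolve joints outward from the pelvis; joint row: segA attaches at cA,
  # segB at cB, so com_B = com_A + R(thA) cA - R(thB) cB (and vice versa)
  resolved <- c(FALSE, TRUE, rep(FALSE, 6))
  repeat {
    progressed <- FALSE
    for (j in seq_len(nrow(J))) {
      a <- J[j, 1] + 1; b <- J[j, 2] + 1
      cA <- J[j, 3:4]; cB <- J[j, 5:6]
      if (resolved[a] && !resolved[b]) {
        pj <- pos[a, ] + rot(angles[a], cA)
        vj <- vel[a, ] + rates[a] * drot(angles[a], cA)
        pos[b, ] <- pj - rot(angles[b], cB)
        vel[b, ] <- vj - rates[b] * drot(angles[b], cB)
        resolved[b] <- TRUE; progressed <- TRUE
      } else if (resolved[b] && !resolved[a]) {
        pj <- pos[b, ] + rot(angles[b], cB)
        vj <- vel[b, ] + rates[b] * drot(angles[b], cB)
        pos[a, ] <- pj - rot(angles[a], cA)
        vel[a, ] <- vj - rates[a] * drot(angles[a], cA)
        resolved[a] <- TRUE; progressed <- TRUE
      }
    }
    if (all(resolved) || !progressed) break
  }
  if (!all(resolved)) abort("kinematic tree could not be resolved")
  if (settle_feet) {
    low <- min(vapply(seq_len(nrow(anthro$contacts)), function(k) {
      s <- anthro$contacts[k, 1] + 1
      (pos[s, ] + rot(angles[s], anthro$contacts[k, 2:3]))[2]
    }, numeric(1)))
    pos[, 2] <- pos[, 2] - low
  }
  list(q = c(pos[, 1], pos[, 2], angles), v = c(vel[, 1], vel[, 2], rates))
}

#' Whole-body center of mass
#'
#' Mass-weighted mean of the segment CoM positions and velocities.
#'
#' @param state a list with `q` and `v` (as from [kinematic_pose()] or the
#'   integrator), or a trajectory tibble row set (see [simulate_walk()]).
#' @param anthro an [build_anthropometry()] object.
#' @return list with `position` and `velocity`, each length-2 (x, y).
#' @export
whole_body_com <- function(state, anthro) {
  m <- anthro$segments$mass
  q <- state$q; v <- state$v
  list(
    position = c(sum(m * q[1:8]), sum(m * q[9:16])) / sum(m),
    velocity = c(sum(m * v[1:8]), sum(m * v[9:16])) / sum(m)
  )
}
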