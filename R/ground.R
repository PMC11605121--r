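#' Ground contact model
#'
#' Spring-damper penalty contact at four points (right/left heel and toe).
#' Horizontal and vertical forces follow independent spring-damper laws
#' anchored at the touchdown position, smoothed near the surface by a ramp
#' indicator over the first centimetre of penetration; vertical damping acts
#' only against downward motion and the vertical force is never negative.
#' The horizontal force is capped by the static coefficient of friction
#' where one is set (see [friction_cap()]).
#'
#' @param k_gx,k_gy horizontal/vertical spring stiffness, N/m.
#' @param b_gx,b_gy horizontal/vertical damping, N s/m.
#' @param friction a friction schedule: tibble/data.frame with columns
#'   `x_start` (m) and `mu_s` (dimensionless, `NA` = unset, i.e. no cap),
#'   piecewise-constant from each `x_start` onward.  Default: unset
#'   everywhere.
#' @return list of class `sg_ground` with the constants and schedule in the
#'   form the dynamics core consumes (`mu_x`, `mu_val`).
#' @export
ground_model <- function(k_gx = 27000, k_gy = 18000, b_gx = 2250, b_gy = 1000,
                         friction = NULL) {
  stopifnot(k_gx > 0, k_gy > 0, b_gx > 0, b_gy > 0)
  if (is.null(friction)) {
    friction <- tibble(x_start = -Inf, mu_s = NA_real_)
  }
  friction <- as_tibble(friction)
  stopifnot(all(c("x_start", "mu_s") %in% names(friction)))
  ok <- is.na(friction$mu_s) | (friction$mu_s >= 0.05 & friction$mu_s <= 2.0)
  if (!all(ok)) abort("`mu_s` values must lie in [0.05, 2.0] (or NA for unset)")
  friction <- arrange(friction, .data$x_start)
  structure(
    list(k_gx = k_gx, k_gy = k_gy, b_gx = b_gx, b_gy = b_gy,
         friction = friction,
         mu_x = friction$x_start, mu_val = friction$mu_s),
    class = "sg_ground"
  )
}

#' Friction schedule with a single switch point
#'
#' Friction unset before `switch_x` and equal to `mu_s` from `switch_x`
#' onward — the sweep protocol's floor: the cap engages once the walker
#' passes the switch point.
#'
#' @param mu_s static coefficient of friction (or `NA` to leave unset).
#' @param switch_x switch position, m.
#' @return friction schedule tibble for [ground_model()].
#' @export
friction_switch <- function(mu_s, switch_x = 5) {
  if (is.na(mu_s)) return(tibble(x_start = -Inf, mu_s = NA_real_))
  tibble(x_start = c(-Inf, switch_x), mu_s = c(NA_real_, mu_s))
}

#' Smooth contact indicator
#'
#' Ramp indicator used by the contact force laws: 0 for negative arguments,
#' `100 x` on \[0, 0.01\], and 1 beyond 0.01 (argument in metres of
#' penetration).
#'
#' @param x numeric vector, m.
#' @return numeric vector in \[0, 1\].
#' @export
smooth_indicator <- function(x) sg_indicator(as.numeric(x))

#' Ground reaction force at one contact point
#'
#' @param point list or vector with the point kinematics: `x`, `y`, `vx`,
#'   `vy` (m, m/s).
#' @param anchor_x horizontal rest (anchor) position of the contact episode, m.
#' @param ground an [ground_model()] object.
#' @param in_contact logical; if `FALSE` both forces are zero.
#' @param apply_cap apply the friction cap from the ground's schedule
#'   (evaluated at the anchor position).
#' @return list with `F_gx`, `F_gy` (N) and the `indicator` value.
#' @export
ground_reaction <- function(point, anchor_x, ground = ground_model(),
                            in_contact = TRUE, apply_cap = FALSE) {
  pt <- as.numeric(unlist(point[c("x", "y", "vx", "vy")]))
  sg_ground_reaction(pt[1], pt[2], pt[3], pt[4], anchor_x,
                     unclass(ground), in_contact, apply_cap)
}

#' Cap the horizontal ground force by static friction
#'
#' Coulomb cap with sign preservation: where a coefficient is set and
#' `|F_gx| > mu_s * F_gy`, the horizontal force is clipped to
#' `sign(F_gx) * mu_s * F_gy`; with the coefficient unset (`NA`) the force
#' passes through unchanged.
#'
#' @param F_gx,F_gy horizontal/vertical forces, N (`F_gy >= 0`).
#' @param mu_s static coefficient(s) of friction, `NA` = unset.
#' @return capped horizontal force(s), N.
#' @export
friction_cap <- function(F_gx, F_gy, mu_s) {
  stopifnot(all(F_gy >= 0))
  sg_friction_cap(as.numeric(F_gx), as.numeric(F_gy), as.numeric(mu_s))
}

#' Update contact anchors from the current body state
#'
#' Implements the anchor-resetting rule: on a touchdown transition the
#' anchor is set to the touchdown horizontal position; during continuous
#' contact it is unchanged; on lift-off the contact flag is cleared.
#'
#' @param contacts tibble with one row per contact point: `in_contact`
#'   (logical), `anchor_x` (m).
#' @param points tibble with current point positions `x`, `y` (m).
#' @return updated `contacts` tibble.
#' @export
update_anchors <- function(contacts, points) {
  stopifnot(nrow(contacts) == nrow(points))
  below <- points$y < 0
  touchdown <- below & !contacts$in_contact
  liftoff <- !below & contacts$in_contact
  contacts$anchor_x[touchdown] <- points$x[touchdown]
  contacts$in_contact[touchdown] <- TRUE
  contacts$in_contact[liftoff] <- FALSE
  contacts
}
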