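# Analysis of walking trajectories: gait events, stride metrics, foot
# clearances, traction ratios, and the margin of stability.  All functions
# take the trajectory tibble first and return tibbles, so they chain with
# the pipe, and they work identically on simulator output and on kinematic
# fixtures (shared column schema).

debounce_runs <- function(x, k) {
  if (k <= 1 || length(x) == 0) return(x)
  r <- rle(x)
  r$values[r$lengths < k & r$values] <- FALSE
  x <- inverse.rle(r)
  r <- rle(x)
  if (length(r$lengths) > 2) {
    inner <- 2:(length(r$lengths) - 1)
    r$values[inner][r$lengths[inner] < k & !r$values[inner]] <- TRUE
  }
  inverse.rle(r)
}

sample_dt <- function(traj) {
  if (nrow(traj) < 2) return(NA_real_)
  stats::median(diff(traj$t))
}

#' Per-sample stance flags and gait phase labels
#'
#' A foot counts as loaded when its total vertical ground force exceeds the
#' threshold, debounced so isolated crossings shorter than the debounce
#' window are ignored.
#'
#' @param traj trajectory tibble (simulator output or fixture).
#' @param force_threshold vertical force defining a loaded foot, N.
#' @param debounce debounce window, s.
#' @return tibble with `t`, `stance_r`, `stance_l`, and `phase`
#'   (`double_support`, `single_support_R`, `single_support_L`, `flight`).
#' @export
gait_phases <- function(traj, force_threshold = 1, debounce = 0.010) {
  dt <- sample_dt(traj)
  k <- if (is.na(dt)) 1L else max(1L, as.integer(round(debounce / dt)))
  sr <- debounce_runs(traj$fgy_r > force_threshold, k)
  sl <- debounce_runs(traj$fgy_l > force_threshold, k)
  tibble(
    t = traj$t, stance_r = sr, stance_l = sl,
    phase = dplyr::case_when(
      sr & sl ~ "double_support",
      sr ~ "single_support_R",
      sl ~ "single_support_L",
      TRUE ~ "flight"
    )
  )
}

#' Detect touchdown and lift-off events
#'
#' Events are threshold crossings of the per-foot vertical ground force
#' (above `force_threshold`, debounced).  A standing trial with no
#' transitions yields an empty event table.
#'
#' @inheritParams gait_phases
#' @return tibble with `foot` ("R"/"L"), `event` ("touchdown"/"liftoff"),
#'   `t`, and the sample `index`.
#' @export
detect_gait_events <- function(traj, force_threshold = 1, debounce = 0.010) {
  if (!all(c("fgy_r", "fgy_l", "t") %in% names(traj)) || nrow(traj) < 2) {
    abort("insufficient data: trajectory lacks force traces or samples")
  }
  ph <- gait_phases(traj, force_threshold, debounce)
  one_foot <- function(st, foot) {
    d <- diff(as.integer(st))
    idx_td <- which(d == 1) + 1L
    idx_lo <- which(d == -1) + 1L
    bind_rows(
      tibble(foot = foot, event = "touchdown", t = traj$t[idx_td],
             index = idx_td),
      tibble(foot = foot, event = "liftoff", t = traj$t[idx_lo],
             index = idx_lo)
    )
  }
  ev <- bind_rows(one_foot(ph$stance_r, "R"), one_foot(ph$stance_l, "L"))
  arrange(ev, .data$t)
}

#' Per-stride gait metrics
#'
#' Strides are delimited by consecutive right-foot touchdowns.  Stride
#' length is the horizontal displacement of the right toe between
#' touchdowns; walking speed is stride length over stride time; cadence is
#' the reciprocal of the stride time (strides/s).
#'
#' @param traj trajectory tibble.
#' @param events event table from [detect_gait_events()]; computed if `NULL`.
#' @return tibble with one row per stride: `stride`, `t_start`, `t_end`,
#'   `x_start`, `stride_length` (m), `stride_time` (s), `speed` (m/s),
#'   `cadence` (strides/s).
#' @export
stride_metrics <- function(traj, events = NULL) {
  if (is.null(events)) events <- detect_gait_events(traj)
  td <- filter(events, .data$foot == "R", .data$event == "touchdown")
  if (nrow(td) < 2) {
    abort("insufficient data: fewer than 2 right-foot touchdowns")
  }
  toe_x <- traj$toe_x_r[td$index]
  # collapse bounce touchdowns: a repeat footfall within 5 cm of the previous
  # one is the same stride boundary, not a new stride
  keep <- c(TRUE, diff(toe_x) > 0.05)
  if (sum(keep) < 2) {
    abort("insufficient data: fewer than 2 distinct right-foot touchdowns")
  }
  td <- td[keep, ]
  toe_x <- toe_x[keep]
  len <- diff(toe_x)
  if (any(len <= 0)) {
    abort("non-advancing stride displacement; trajectory is degenerate or reversed")
  }
  dt <- diff(td$t)
  tibble(
    stride = seq_along(len),
    t_start = td$t[-nrow(td)], t_end = td$t[-1],
    x_start = toe_x[-length(toe_x)],
    stride_length = len, stride_time = dt,
    speed = len / dt, cadence = 1 / dt
  )
}

# swing windows (liftoff to next touchdown) per foot
swing_windows <- function(events, foot) {
  e <- filter(events, .data$foot == !!foot)
  lo <- filter(e, .data$event == "liftoff")
  td <- filter(e, .data$event == "touchdown")
  if (nrow(lo) == 0) return(tibble())
  out <- purrr::map_dfr(seq_len(nrow(lo)), function(i) {
    nxt <- td$t[td$t > lo$t[i]]
    if (length(nxt) == 0) return(tibble())
    tibble(foot = foot, swing = i, t_liftoff = lo$t[i], t_touchdown = nxt[1])
  })
  out
}

#' Foot clearance during mid-swing
#'
#' For each swing phase, the minimum toe height and the maximum heel height
#' above the floor within the mid-swing window (the middle tercile of the
#' swing phase by time).
#'
#' @param traj trajectory tibble.
#' @param events event table; computed if `NULL`.
#' @param feet which feet to analyse.
#' @return tibble with `foot`, `swing`, `t_liftoff`, `t_touchdown`,
#'   `min_toe_clearance` (m), `max_heel_clearance` (m).
#' @export
clearance_metrics <- function(traj, events = NULL, feet = c("R", "L")) {
  if (is.null(events)) events <- detect_gait_events(traj)
  sw <- bind_rows(lapply(feet, function(f) swing_windows(events, f)))
  if (nrow(sw) == 0) {
    abort("insufficient data: no complete swing phase found")
  }
  purrr::map_dfr(seq_len(nrow(sw)), function(i) {
    f <- tolower(sw$foot[i])
    t0 <- sw$t_liftoff[i]; t1 <- sw$t_touchdown[i]
    lo <- t0 + (t1 - t0) / 3
    hi <- t0 + 2 * (t1 - t0) / 3
    mid <- traj$t >= lo & traj$t <= hi
    if (!any(mid)) return(tibble())
    tibble(
      foot = sw$foot[i], swing = sw$swing[i],
      t_liftoff = t0, t_touchdown = t1,
      min_toe_clearance = min(traj[[paste0("toe_y_", f)]][mid]),
      max_heel_clearance = max(traj[[paste0("heel_y_", f)]][mid])
    )
  })
}

#' Summary of gait variables over consecutive stable strides
#'
#' Mean and coefficient of variation (CV, %) of stride length, walking
#' speed, and the maximum and minimum foot clearance over `n` consecutive
#' strides, plus the stride length / foot clearance ratio (SL_FC).  The CV
#' uses the sample standard deviation (n - 1 denominator).  Strides starting
#' before `min_start_x` are treated as start-up transient and skipped.
#'
#' @param strides per-stride table from [stride_metrics()].
#' @param clearances per-swing table from [clearance_metrics()] (right-foot
#'   swings are matched to strides by time).
#' @param n number of consecutive strides summarised.
#' @param min_start_x transient cutoff, m.
#' @param sl_fc_clearance which clearance enters SL_FC; the maximum (heel)
#'   clearance is the default, which makes the ratio largest for the
#'   clearance-impaired faller gait.
#' @return tibble of class `sg_gait_summary` with `variable`, `mean`,
#'   `cv_pct`; attributes `sl_fc`, `n`, `strides_used`.
#' @export
summarize_gait <- function(strides, clearances, n = 10, min_start_x = 2,
                           sl_fc_clearance = c("max", "min")) {
  sl_fc_clearance <- match.arg(sl_fc_clearance)
  ok <- which(strides$x_start >= min_start_x)
  if (length(ok) < n) {
    abort(sprintf("insufficient data: %d stable strides available, %d required",
                  length(ok), n))
  }
  # "stable gait": among all windows of n consecutive eligible strides, use
  # the one with the smallest stride-time variability
  starts <- ok[ok + n - 1 <= max(ok)]
  starts <- starts[vapply(starts, function(s) all((s:(s + n - 1)) %in% ok),
                          TRUE)]
  if (!length(starts)) starts <- ok[1]
  win_cv <- vapply(starts, function(s) {
    stats::sd(strides$stride_time[s:(s + n - 1)])
  }, numeric(1))
  s0 <- starts[which.min(win_cv)]
  use <- strides[s0:(s0 + n - 1), ]
  cl <- filter(clearances, .data$foot == "R",
               .data$t_liftoff >= min(use$t_start),
               .data$t_touchdown <= max(use$t_end) + 1e-9)
  if (nrow(cl) > n) cl <- cl[seq_len(n), ]
  if (nrow(cl) < 2) abort("insufficient data: too few swing phases in window")
  cv <- function(x) 100 * sd(x) / mean(x)
  out <- tibble(
    variable = c("stride_length", "walking_speed",
                 "max_foot_clearance", "min_foot_clearance"),
    mean = c(mean(use$stride_length), mean(use$speed),
             mean(cl$max_heel_clearance), mean(cl$min_toe_clearance)),
    cv_pct = c(cv(use$stride_length), cv(use$speed),
               cv(cl$max_heel_clearance), cv(cl$min_toe_clearance))
  )
  clr <- if (sl_fc_clearance == "max") mean(cl$max_heel_clearance) else
    mean(cl$min_toe_clearance)
  attr(out, "sl_fc") <- mean(use$stride_length) / clr
  attr(out, "n") <- n
  attr(out, "strides_used") <- use$stride
  class(out) <- c("sg_gait_summary", class(out))
  out
}

# base-of-support borders per sample from loaded-foot toe/heel positions
bos_borders <- function(traj, phases) {
  n <- nrow(traj)
  ant <- rep(NA_real_, n); post <- rep(NA_real_, n)
  sr <- phases$stance_r; sl <- phases$stance_l
  both <- sr & sl
  ant[both] <- pmax(traj$toe_x_r[both], traj$toe_x_l[both])
  post[both] <- pmin(traj$heel_x_r[both], traj$heel_x_l[both])
  onlyr <- sr & !sl
  ant[onlyr] <- traj$toe_x_r[onlyr]; post[onlyr] <- traj$heel_x_r[onlyr]
  onlyl <- sl & !sr
  ant[onlyl] <- traj$toe_x_l[onlyl]; post[onlyl] <- traj$heel_x_l[onlyl]
  # during flight, carry the last supporting borders forward
  filled <- function(z) {
    idx <- which(!is.na(z))
    if (length(idx) == 0) return(z)
    approx(idx, z[idx], xout = seq_along(z), method = "constant", rule = 2)$y
  }
  list(anterior = filled(ant), posterior = filled(post))
}

#' Margin of stability from the extrapolated center of mass
#'
#' The extrapolated CoM is `XCoM = X + V / sqrt(g / l)` with `X`, `V` the
#' horizontal CoM position and velocity and `l` the effective pendulum
#' length.  The anterior margin is the distance from the XCoM forward to the
#' anterior base-of-support border (the toe of the leading/standing foot);
#' the posterior margin is the distance backward to the posterior border
#' (the heel of the trailing/standing foot).  Both are positive when the
#' XCoM lies inside the base of support and negative outside it.
#'
#' By default `l` is recomputed per step as the distance from the stance
#' ankle to the whole-body CoM at mid-stance; a fixed scalar can be given
#' instead.  Steps are delimited by consecutive touchdowns of either foot.
#'
#' @param traj trajectory tibble.
#' @param events event table; computed if `NULL`.
#' @param l effective pendulum length, m; `NULL` for the per-step convention.
#' @param g gravitational acceleration, m/s^2.
#' @return tibble of class `sg_mos`: per sample `t`, `step`, `l`, `xcom`,
#'   `bos_anterior`, `bos_posterior`, `mos_anterior`, `mos_posterior`;
#'   attribute `step_minima` holds the per-step minima of both margins.
#' @export
compute_mos <- function(traj, events = NULL, l = NULL, g = 9.81) {
  stopifnot(is.null(l) || l > 0)
  if (is.null(events)) events <- detect_gait_events(traj)
  phases <- gait_phases(traj)
  bos <- bos_borders(traj, phases)
  td <- filter(events, .data$event == "touchdown")
  step <- if (nrow(td) > 0) findInterval(traj$t, td$t) else rep(0L, nrow(traj))
  if (is.null(l)) {
    lvec <- rep(leg_length_default(traj), nrow(traj))
    if (nrow(td) > 0) {
      for (i in seq_len(nrow(td))) {
        t0 <- td$t[i]
        t1 <- if (i < nrow(td)) td$t[i + 1] else max(traj$t)
        mid <- which.min(abs(traj$t - (t0 + t1) / 2))
        f <- tolower(td$foot[i])
        li <- sqrt((traj$com_x[mid] - traj[[paste0("ankle_x_", f)]][mid])^2 +
                     (traj$com_y[mid] - traj[[paste0("ankle_y_", f)]][mid])^2)
        lvec[step == i] <- li
      }
    }
  } else {
    lvec <- rep(l, nrow(traj))
  }
  xcom <- traj$com_x + traj$com_vx / sqrt(g / lvec)
  out <- tibble(
    t = traj$t, step = step, l = lvec, xcom = xcom,
    bos_anterior = bos$anterior, bos_posterior = bos$posterior,
    mos_anterior = bos$anterior - xcom,
    mos_posterior = xcom - bos$posterior
  )
  safe_min <- function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)
  minima <- out %>%
    filter(.data$step > 0) %>%
    group_by(.data$step) %>%
    summarise(min_mos_anterior = safe_min(.data$mos_anterior),
              min_mos_posterior = safe_min(.data$mos_posterior),
              .groups = "drop")
  attr(out, "step_minima") <- minima
  class(out) <- c("sg_mos", class(out))
  out
}

# fallback pendulum length: CoM height above the lower ankle
leg_length_default <- function(traj) {
  if (all(c("ankle_y_r", "com_y") %in% names(traj))) {
    mean(traj$com_y - pmin(traj$ankle_y_r, traj$ankle_y_l), na.rm = TRUE)
  } else 1.0
}

#' Per-step minima of the margin of stability
#'
#' @param mos an [compute_mos()] result.
#' @return tibble with `step`, `min_mos_anterior`, `min_mos_posterior`.
#' @export
mos_step_minima <- function(mos) attr(mos, "step_minima")

#' Traction-coefficient maxima per stance
#'
#' The traction coefficient is the instantaneous ratio `|F_gx| / F_gy` at a
#' contact point; samples with `F_gy` at or below `force_threshold` are
#' excluded (the ratio is undefined at contact onset).  Its maximum over a
#' stance episode is the required coefficient of friction of that stance.
#'
#' @param traj trajectory tibble.
#' @param force_threshold minimum vertical force for a valid ratio, N.
#' @param mu_s optional friction coefficient; when given, each stance is
#'   flagged if its maximum reached the cap (within 1e-6).
#' @return tibble with `point`, `stance`, `t_start`, `t_end`, `max_ratio`,
#'   `reached_mu`.
#' @export
traction_series <- function(traj, force_threshold = 1, mu_s = NULL) {
  if (is.null(mu_s)) mu_s <- attr(traj, "mu_s")
  dt <- sample_dt(traj)
  k <- if (is.na(dt)) 1L else max(1L, as.integer(round(0.010 / dt)))
  purrr::map_dfr(pt_suffix, function(pt) {
    fy <- traj[[paste0("fgy_", pt)]]
    fx <- traj[[paste0("fgx_", pt)]]
    loaded <- debounce_runs(fy > force_threshold, k)
    if (!any(loaded)) return(tibble())
    r <- rle(loaded)
    ends <- cumsum(r$lengths)
    starts <- c(1L, utils::head(ends, -1) + 1L)
    runs <- which(r$values)
    purrr::map_dfr(seq_along(runs), function(j) {
      i0 <- starts[runs[j]]; i1 <- ends[runs[j]]
      sel <- i0:i1
      valid <- fy[sel] > force_threshold
      ratio <- abs(fx[sel][valid]) / fy[sel][valid]
      mx <- if (length(ratio)) max(ratio) else NA_real_
      tibble(point = pt, stance = j, t_start = traj$t[i0], t_end = traj$t[i1],
             max_ratio = mx,
             reached_mu = if (!is.null(mu_s) && !is.na(mu_s) && !is.na(mx))
               mx >= mu_s - 1e-6 else NA)
    })
  })
}
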