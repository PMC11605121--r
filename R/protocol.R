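# The friction-sweep experiment: trials over the mu_s grid with the
# friction switch at 5 m, automated outcome classification over the
# 5-15 m window, and threshold extraction.

#' The static-friction grid of the sweep protocol
#'
#' Increments of 0.05 from 0.05 to 0.50 and of 0.1 from 0.60 to 2.00;
#' 25 values in total, strictly increasing.
#'
#' @return numeric vector of mu_s values.
#' @export
mu_grid <- function() {
  c((1:10) * 0.05, (6:20) * 0.10)
}

#' Classify a trial outcome from its trajectory
#'
#' A fall is a hip height (midpoint of the hip joint centers) below
#' `fall_hip_height` within the classification window.  A slip is a loaded
#' (stance) foot whose horizontal CoM speed exceeds `slip_speed` for at
#' least `slip_hold` seconds.  A fall preceded by a slip within the window
#' is slip-induced; a fall without one is trip-induced, with the fall
#' direction (from the extrapolated CoM against the base-of-support borders
#' at the fall instant, ties broken by the CoM velocity sign) recorded as an
#' annotation.
#'
#' @param traj trajectory tibble.
#' @param config an [sim_config()] object (thresholds and window); defaults
#'   to the trajectory's own config attribute or the protocol defaults.
#' @return list of class `sg_outcome`: `outcome` (`"no_fall"`,
#'   `"slip_fall"`, `"trip_fall"`), `fall_t`, `fall_x`, `direction`,
#'   `slip_detected`, `slip_t`, `direction_consistent`.
#' @export
classify_outcome <- function(traj, config = NULL) {
  if (is.null(config)) config <- attr(traj, "config") %||% sim_config()
  w <- config$window
  inwin <- traj$com_x > w[1] & traj$com_x <= w[2]
  if (!any(inwin)) {
    abort("insufficient data: trajectory never enters the classification window")
  }
  dt <- sample_dt(traj)
  k <- max(1L, as.integer(round(config$slip_hold / dt)))

  fallen <- inwin & traj$hip_y < config$fall_hip_height
  i_fall <- if (any(fallen)) which(fallen)[1] else NA_integer_
  status <- attr(traj, "status")
  covered <- max(traj$com_x) >= w[2] ||
    (!is.null(status) && status %in% c("completed", "fell"))
  if (is.na(i_fall) && !covered) {
    abort("insufficient data: trajectory ends before the window without a fall")
  }
  t_end <- if (is.na(i_fall)) Inf else traj$t[i_fall]

  # slip: stance-foot horizontal speed above threshold, sustained; located
  # by the slipping foot itself (a foot planted beyond the friction switch
  # can slip while the CoM is still just short of the window)
  slip_t <- NA_real_
  for (side in c("r", "l")) {
    loaded <- traj[[paste0("fgy_", side)]] > config$force_threshold
    fast <- abs(traj[[paste0("foot_vx_", side)]]) > config$slip_speed
    at_site <- traj[[paste0("toe_x_", side)]] > w[1] & traj$com_x <= w[2]
    cond <- debounce_runs(loaded & fast & at_site & traj$t <= t_end, k)
    if (any(cond)) {
      tt <- traj$t[which(cond)[1]]
      if (is.na(slip_t) || tt < slip_t) slip_t <- tt
    }
  }
  slip_detected <- !is.na(slip_t)

  if (is.na(i_fall)) {
    out <- list(outcome = "no_fall", fall_t = NA_real_, fall_x = NA_real_,
                direction = NA_character_, slip_detected = slip_detected,
                slip_t = slip_t, direction_consistent = TRUE)
    class(out) <- "sg_outcome"
    return(out)
  }

  direction <- fall_direction(traj, i_fall, config)
  if (slip_detected) {
    outcome <- "slip_fall"
    consistent <- TRUE
  } else {
    outcome <- "trip_fall"
    consistent <- identical(direction, "forward")
  }
  out <- list(outcome = outcome, fall_t = traj$t[i_fall],
              fall_x = traj$com_x[i_fall], direction = direction,
              slip_detected = slip_detected, slip_t = slip_t,
              direction_consistent = consistent)
  class(out) <- "sg_outcome"
  out
}

# forward/backward at the fall instant: extrapolated CoM against the BOS
# borders; between the borders, the CoM velocity sign decides
fall_direction <- function(traj, i_fall, config) {
  phases <- gait_phases(traj, config$force_threshold, config$event_debounce)
  bos <- bos_borders(traj, phases)
  l <- leg_length_default(traj)
  xcom <- traj$com_x[i_fall] + traj$com_vx[i_fall] / sqrt(config$g / l)
  ant <- bos$anterior[i_fall]; post <- bos$posterior[i_fall]
  if (!is.na(ant) && xcom > ant) "forward"
  else if (!is.na(post) && xcom < post) "backward"
  else if (traj$com_vx[i_fall] >= 0) "forward" else "backward"
}

#' @export
print.sg_outcome <- function(x, ...) {
  cat("<sg_outcome>", x$outcome)
  if (x$outcome != "no_fall") {
    cat(sprintf(" at x = %.2f m, t = %.2f s (%s)", x$fall_x, x$fall_t,
                x$direction))
  }
  cat("\n")
  invisible(x)
}

# deterministic per-trial seed below 2^31, reproducible in isolation
trial_seed <- function(base_seed, model, mu_index, trial) {
  moff <- match(model, c("young", "elderly_nonfaller", "elderly_faller"))
  M <- 2147483647
  h <- (as.double(base_seed) %% M)
  h <- (h * 48271 + 104729 * mu_index + 7919 * trial + 613 * moff) %% M
  as.integer(max(1, h))
}

#' Run one friction trial
#'
#' Simulates the model from the start to the end of the classification
#' window (or a fall), with friction unset before the switch point and
#' `mu_s` applied beyond it, then classifies the outcome and extracts the
#' per-stance traction maxima.  Fully reproducible from
#' `(model, mu_s, seed)`.  A trial whose integration diverges is rerun once
#' at half the step size; if it diverges again it is marked `invalid`
#' (never silently classified as a fall).
#'
#' @param model gait model name or [gait_model()] object.
#' @param mu_s static coefficient of friction in \[0.05, 2\].
#' @param seed integer seed.
#' @param config an [sim_config()] object.
#' @param keep_trajectory retain the full trajectory in the result.
#' @param ... passed to [simulate_walk()].
#' @return list of class `sg_trial`: `result` (one-row tibble with `model`,
#'   `mu_s`, `seed`, `outcome`, `fall_x`, `fall_t`, `max_traction`,
#'   `status`), `outcome` (the [classify_outcome()] object), `traction`,
#'   and optionally `trajectory`.
#' @export
run_trial <- function(model, mu_s, seed, config = sim_config(),
                      keep_trajectory = FALSE, ...) {
  if (is.character(model)) model <- gait_model(model)
  stopifnot(mu_s >= 0.05, mu_s <= 2.0)
  config$x_stop <- max(config$x_stop, config$window[2] + 0.3)
  traj <- simulate_walk(model, mu_s = mu_s, seed = seed, config = config, ...)
  if (identical(attr(traj, "status"), "diverged")) {
    config2 <- config
    config2$dt <- config$dt / 2
    traj <- simulate_walk(model, mu_s = mu_s, seed = seed, config = config2, ...)
    if (identical(attr(traj, "status"), "diverged")) {
      warning(sprintf("trial (%s, mu_s = %.2f, seed = %d) diverged; marked invalid",
                      model$name, mu_s, seed))
      res <- tibble(model = model$name, mu_s = mu_s, seed = seed,
                    outcome = "invalid", fall_x = NA_real_, fall_t = NA_real_,
                    max_traction = NA_real_, status = "diverged")
      out <- list(result = res, outcome = NULL, traction = NULL)
      class(out) <- "sg_trial"
      return(out)
    }
  }
  oc <- tryCatch(classify_outcome(traj, config), error = function(e) NULL)
  if (is.null(oc)) {
    res <- tibble(model = model$name, mu_s = mu_s, seed = seed,
                  outcome = "invalid", fall_x = NA_real_, fall_t = NA_real_,
                  max_traction = NA_real_,
                  status = paste0(attr(traj, "status"), "_prewindow"))
    out <- list(result = res, outcome = NULL, traction = NULL)
    if (keep_trajectory) out$trajectory <- traj
    class(out) <- "sg_trial"
    return(out)
  }
  tr <- traction_series(traj, config$force_threshold, mu_s)
  res <- tibble(
    model = model$name, mu_s = mu_s, seed = seed, outcome = oc$outcome,
    fall_x = oc$fall_x, fall_t = oc$fall_t,
    max_traction = if (nrow(tr)) max(tr$max_ratio, na.rm = TRUE) else NA_real_,
    status = attr(traj, "status")
  )
  out <- list(result = res, outcome = oc, traction = tr)
  if (keep_trajectory) out$trajectory <- traj
  class(out) <- "sg_trial"
  out
}

#' Run a friction sweep
#'
#' Repeats [run_trial()] over a mu_s grid with `trials_per_mu` seeded trials
#' per condition; per-trial seeds are derived deterministically from
#' `base_seed`, the model, and the grid/trial indices, so any single trial
#' can be reproduced in isolation.  Divergent trials are recorded as
#' `invalid` and do not abort the sweep.
#'
#' @param model gait model name or object.
#' @param mu_values mu_s grid; defaults to [mu_grid()].
#' @param trials_per_mu trials per grid value.
#' @param base_seed sweep-level seed.
#' @param config an [sim_config()] object.
#' @param progress print one line per condition.
#' @param ... passed to [run_trial()].
#' @return tibble of class `sg_sweep` with one row per trial (`model`,
#'   `mu_s`, `trial`, `seed`, `outcome`, `fall_x`, `fall_t`,
#'   `max_traction`, `status`); attribute `mu_slip` caches the slip
#'   threshold.
#' @export
run_sweep <- function(model, mu_values = mu_grid(), trials_per_mu = 5,
                      base_seed = 1, config = sim_config(), progress = FALSE,
                      ...) {
  if (is.character(model)) model <- gait_model(model)
  rows <- list()
  for (i in seq_along(mu_values)) {
    for (j in seq_len(trials_per_mu)) {
      seed <- trial_seed(base_seed, model$name, i, j)
      tr <- run_trial(model, mu_values[i], seed, config, ...)
      rows[[length(rows) + 1]] <- mutate(tr$result, trial = j)
    }
    if (progress) {
      message(sprintf("mu_s = %.2f: %s", mu_values[i],
                      paste(vapply(utils::tail(rows, trials_per_mu),
                                   function(r) r$outcome, ""), collapse = " ")))
    }
  }
  out <- bind_rows(rows) %>%
    select("model", "mu_s", "trial", "seed", "outcome", "fall_x", "fall_t",
           "max_traction", "status")
  attr(out, "base_seed") <- base_seed
  attr(out, "mu_slip") <- mu_slip_threshold(out)
  class(out) <- c("sg_sweep", class(out))
  out
}

#' Largest friction coefficient with slip-induced falls
#'
#' @param sweep sweep table from [run_sweep()] (or any table with `mu_s`
#'   and `outcome` columns).
#' @return largest `mu_s` whose trials include at least one slip-induced
#'   fall, or `NA` if there is none.
#' @export
mu_slip_threshold <- function(sweep) {
  mu <- sweep$mu_s[sweep$outcome == "slip_fall"]
  if (length(mu) == 0) NA_real_ else max(mu)
}

#' Smallest friction coefficient with trip-induced falls
#'
#' @inheritParams mu_slip_threshold
#' @return smallest `mu_s` whose trials include at least one trip-induced
#'   fall, or `NA` if there is none.
#' @export
mu_trip_onset <- function(sweep) {
  mu <- sweep$mu_s[sweep$outcome == "trip_fall"]
  if (length(mu) == 0) NA_real_ else min(mu)
}
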