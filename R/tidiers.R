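# broom-style tidiers for the package's result objects

#' Tidy a friction sweep
#'
#' One row per (mu_s, outcome) with trial counts — the long-format summary
#' of the sweep's outcome map.
#'
#' @param x an `sg_sweep` object.
#' @param ... unused.
#' @return a tibble with `model`, `mu_s`, `outcome`, `n`.
#' @export
tidy.sg_sweep <- function(x, ...) {
  as_tibble(x) %>%
    group_by(.data$model, .data$mu_s, .data$outcome) %>%
    summarise(n = dplyr::n(), .groups = "drop")
}

#' Glance at a friction sweep
#'
#' @param x an `sg_sweep` object.
#' @param ... unused.
#' @return one-row tibble with the trial count, fall counts by mechanism,
#'   and the slip/trip friction thresholds.
#' @export
glance.sg_sweep <- function(x, ...) {
  tibble(
    model = x$model[1],
    n_trials = nrow(x),
    n_slip_falls = sum(x$outcome == "slip_fall"),
    n_trip_falls = sum(x$outcome == "trip_fall"),
    n_invalid = sum(x$outcome == "invalid"),
    mu_s_slip = mu_slip_threshold(x),
    mu_s_trip_onset = mu_trip_onset(x)
  )
}

#' Tidy a gait summary
#'
#' @param x an `sg_gait_summary` object.
#' @param ... unused.
#' @return the summary tibble (variable, mean, cv_pct).
#' @export
tidy.sg_gait_summary <- function(x, ...) as_tibble(x)

#' Glance at a gait summary
#'
#' @param x an `sg_gait_summary` object.
#' @param ... unused.
#' @return one-row tibble with the stride count and SL_FC ratio.
#' @export
glance.sg_gait_summary <- function(x, ...) {
  tibble(n_strides = attr(x, "n"), sl_fc = attr(x, "sl_fc"))
}

#' Tidy a margin-of-stability series
#'
#' @param x an `sg_mos` object.
#' @param ... unused.
#' @return per-step minima tibble.
#' @export
tidy.sg_mos <- function(x, ...) mos_step_minima(x)
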