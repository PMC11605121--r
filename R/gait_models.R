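#' Registered gait model parameterizations
#'
#' Three named parameterizations of the oscillator network are registered:
#' a young adult, an elderly non-faller, and an elderly faller.  They differ
#' only in the nonspecific steady input `u0`, the ratio of the neuron time
#' constants `tau/tau'`, the eighteen torque transfer coefficients `p_k`,
#' and the white-noise percentage applied to `u0`.  The elderly non-faller
#' shares the young adult's `p_k` values; the elderly faller has reduced
#' torque transfer, most strongly in the swing-limb channels that generate
#' foot clearance.
#'
#' @param name one of `"young"`, `"elderly_nonfaller"`, `"elderly_faller"`.
#' @return An object of class `sg_gait_model`: list with `name`, `u0`,
#'   `tau_ratio`, `p` (numeric(18)), `noise_pct`.
#' @examples
#' gait_model("young")$u0        # 7.08
#' gait_model("elderly_faller")$p[4]  # 0.86
#' @export
gait_model <- function(name = c("young", "elderly_nonfaller", "elderly_faller")) {
  if (!is.character(name) || length(name) != 1 ||
      !name %in% c("young", "elderly_nonfaller", "elderly_faller")) {
    abort(paste0(
      "unknown gait model `", paste(as.character(name), collapse = ","),
      "`; valid names: young, elderly_nonfaller, elderly_faller"))
  }
  p_young <- c(5.00, 10.00, 4.00, 2.00, 15.00, 4.00, 3.00, 2.00, 15.00,
               8.00, 2.00, 3.00, 2.00, 8.00, 1.50, 12.00, 1.00, 7.00)
  p_faller <- c(4.75, 9.50, 2.66, 0.86, 12.83, 3.42, 2.85, 1.90, 14.25,
                7.60, 1.90, 2.85, 1.90, 3.92, 0.90, 10.26, 0.86, 5.99)
  spec <- switch(name,
    young = list(u0 = 7.08, tau_ratio = 0.036, p = p_young, noise_pct = 8.50),
    elderly_nonfaller = list(u0 = 5.16, tau_ratio = 0.100, p = p_young,
                             noise_pct = 2.00),
    elderly_faller = list(u0 = 5.10, tau_ratio = 0.076, p = p_faller,
                          noise_pct = 0.100)
  )
  structure(c(list(name = name), spec), class = "sg_gait_model")
}

#' @export
print.sg_gait_model <- function(x, ...) {
  cat("<sg_gait_model> ", x$name, ": u0 = ", x$u0, ", tau/tau' = ",
      x$tau_ratio, ", noise = ", x$noise_pct, "%\n", sep = "")
  invisible(x)
}

#' Draw noisy values of the nonspecific steady input
#'
#' White noise is applied multiplicatively: `u0 * (1 + noise_pct/100 * e)`
#' with `e ~ N(0, 1)`, one draw per neural update step, shared across the
#' fourteen neurons.  Draws come from the calling R session's RNG stream, so
#' seeding the session seeds the noise.
#'
#' @param spec a [gait_model()] object.
#' @param n number of draws.
#' @return numeric(n) of noisy `u0` values.
#' @export
noisy_u0 <- function(spec, n = 1) {
  stopifnot(inherits(spec, "sg_gait_model"))
  if (spec$noise_pct == 0) return(rep(spec$u0, n))
  spec$u0 * (1 + (spec$noise_pct / 100) * rnorm(n))
}

#' Reference mean gait variables for the three models
#'
#' The calibration targets of the three gait parameterizations: per-model
#' means and coefficients of variation (over 10 consecutive stable strides)
#' of stride length, walking speed, and maximum/minimum foot clearance.
#'
#' @return tibble with columns `model`, `variable`, `mean`, `cv_pct`.
#'   Units: stride length and maximum foot clearance in m, walking speed in
#'   m/s, minimum foot clearance in m.
#' @export
reference_gait_table <- function() {
  tibble(
    model = rep(c("young", "elderly_nonfaller", "elderly_faller"), each = 4),
    variable = rep(c("stride_length", "walking_speed",
                     "max_foot_clearance", "min_foot_clearance"), 3),
    mean = c(1.47, 1.29, 0.36, 0.0208,
             0.95, 0.75, 0.28, 0.0181,
             0.88, 0.69, 0.15, 0.0146),
    cv_pct = c(1.34, 1.68, 2.2, 6.73,
               0.99, 0.52, 3.6, 23.1,
               7.29, 10.8, 26.0, 45.9)
  )
}

#' Percent reduction of the elderly models' gait means relative to young
#'
#' For each gait variable, computes `100 * (1 - mean_model / mean_young)`
#' rounded to the nearest percent.
#'
#' @param table a table shaped like [reference_gait_table()]; defaults to it.
#' @return tibble with `model`, `variable`, `reduction_pct`.
#' @export
gait_mean_reductions <- function(table = reference_gait_table()) {
  young <- table %>%
    filter(.data$model == "young") %>%
    select("variable", young_mean = "mean")
  table %>%
    filter(.data$model != "young") %>%
    dplyr::left_join(young, by = "variable") %>%
    mutate(reduction_pct = round(100 * (1 - .data$mean / .data$young_mean))) %>%
    select("model", "variable", "reduction_pct")
}
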