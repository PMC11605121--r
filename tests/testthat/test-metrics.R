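fixture_default <- function(...) make_kinematic_walker(fixture_spec(...))

test_that("gait events land on the programmed contact transitions", {
  fx <- fixture_default(noise_sd = 0, n_strides = 6)
  ev <- detect_gait_events(fx$trajectory)
  td <- ev[ev$foot == "R" & ev$event == "touchdown", ]
  Tcyc <- fx$spec$stride_length / fx$spec$speed
  # programmed right touchdowns at multiples of the cycle time (the initial
  # standing contact is not a transition, so the first event is at one cycle)
  expect_lt(max(abs(td$t - Tcyc * seq_len(nrow(td)))), 2.1 * fx$spec$dt)
  # standing still: both feet loaded, no transitions
  still <- fx$trajectory[1:50, ]
  still$fgy_r <- 400; still$fgy_l <- 400
  ph <- gait_phases(still)
  expect_true(all(ph$phase == "double_support"))
  expect_equal(nrow(detect_gait_events(still)), 0)
})

test_that("insufficient trajectories raise errors instead of guessing", {
  fx <- fixture_default(n_strides = 6)
  expect_error(detect_gait_events(fx$trajectory[1, ]), "insufficient")
  one_td <- fx$trajectory[fx$trajectory$t < 0.6, ]
  expect_error(stride_metrics(one_td), "insufficient|touchdowns")
})

test_that("time-reversed trajectories are rejected", {
  fx <- fixture_default(noise_sd = 0, n_strides = 6)
  rev_tr <- fx$trajectory
  rev_tr$toe_x_r <- rev(rev_tr$toe_x_r)
  expect_error(stride_metrics(rev_tr),
               "degenerate|reversed|advancing|distinct")
})

test_that("parameter recovery across random fixture draws stays within 2%", {
  set.seed(21)
  for (i in 1:12) {
    sl <- runif(1, 0.6, 1.6)
    sp <- runif(1, 0.5, 1.5)
    cmin <- runif(1, 0.005, 0.04)
    hmax <- runif(1, 0.1, 0.4)
    fx <- fixture_default(stride_length = sl, speed = sp,
                          min_toe_clearance = cmin, max_heel_clearance = hmax,
                          noise_sd = 0, n_strides = 12, seed = i)
    ev <- detect_gait_events(fx$trajectory)
    st <- stride_metrics(fx$trajectory, ev)
    cl <- clearance_metrics(fx$trajectory, ev, feet = "R")
    expect_equal(mean(st$stride_length), sl, tolerance = 0.02)
    expect_equal(mean(st$speed), sp, tolerance = 0.02)
    expect_equal(mean(cl$min_toe_clearance), cmin, tolerance = 0.02)
    expect_equal(mean(cl$max_heel_clearance), hmax, tolerance = 0.02)
  }
})

test_that("stride arithmetic identities hold per stride", {
  fx <- fixture_default(noise_sd = 0.04, n_strides = 15, seed = 2)
  st <- stride_metrics(fx$trajectory)
  expect_equal(st$speed, st$stride_length / st$stride_time, tolerance = 1e-12)
  expect_equal(st$cadence, 1 / st$stride_time, tolerance = 1e-12)
})

test_that("gait summary computes means, CVs, and SL_FC as documented", {
  fx <- fixture_default(noise_sd = 0, n_strides = 14)
  ev <- detect_gait_events(fx$trajectory)
  st <- stride_metrics(fx$trajectory, ev)
  cl <- clearance_metrics(fx$trajectory, ev, feet = "R")
  sm <- summarize_gait(st, cl, n = 10, min_start_x = 0)
  expect_equal(sm$cv_pct, rep(0, 4), tolerance = 1e-6)
  expect_equal(attr(sm, "sl_fc"),
               sm$mean[sm$variable == "stride_length"] /
                 sm$mean[sm$variable == "max_foot_clearance"],
               tolerance = 1e-12)
  expect_error(summarize_gait(st[1:5, ], cl, n = 10, min_start_x = 0),
               "insufficient")
  # hand-computed CV: alternating 0.9/1.1 has sd/mean = 0.1054 (n-1 form)
  st2 <- st[1:10, ]
  st2$stride_length <- rep(c(0.9, 1.1), 5)
  st2$x_start <- seq_len(10)
  cl2 <- cl[1:10, ]
  sm2 <- summarize_gait(st2, cl2, n = 10, min_start_x = 0)
  expect_equal(sm2$mean[1], 1.0)
  expect_equal(sm2$cv_pct[1], 100 * sd(rep(c(0.9, 1.1), 5)) / 1.0,
               tolerance = 1e-9)
})

test_that("extrapolated-CoM arithmetic matches hand evaluations", {
  # V = 0: XCoM equals X; symmetric borders give equal margins
  tr <- tibble::tibble(
    t = seq(0, 0.2, by = 0.01),
    com_x = 0.5, com_y = 1.0, com_vx = 0,
    toe_x_r = 0.7, heel_x_r = 0.3, toe_y_r = 0, heel_y_r = 0,
    toe_x_l = 0.7, heel_x_l = 0.3, toe_y_l = 0, heel_y_l = 0,
    ankle_x_r = 0.5, ankle_y_r = 0.07, ankle_x_l = 0.5, ankle_y_l = 0.07,
    foot_vx_r = 0, foot_vx_l = 0, hip_x = 0.5, hip_y = 0.95,
    fgx_heel_r = 0, fgy_heel_r = 200, fgx_toe_r = 0, fgy_toe_r = 200,
    fgx_heel_l = 0, fgy_heel_l = 200, fgx_toe_l = 0, fgy_toe_l = 200,
    fgy_r = 400, fgy_l = 400
  )
  mos <- compute_mos(tr, l = 1.0)
  expect_equal(unique(mos$xcom), 0.5)
  expect_equal(unique(mos$mos_anterior), 0.2)
  expect_equal(unique(mos$mos_posterior), 0.2)
  # V = 0.3, g = 9.81, l = 1: XCoM = 0.5 + 0.3/sqrt(9.81) = 0.59578
  tr2 <- tr
  tr2$com_vx <- 0.3
  mos2 <- compute_mos(tr2, l = 1.0)
  expect_equal(unique(mos2$xcom), 0.5 + 0.3 / sqrt(9.81), tolerance = 1e-6)
  expect_equal(unique(mos2$mos_anterior), 0.7 - 0.59578, tolerance = 1e-4)
  # XCoM exactly on the anterior border: zero anterior margin
  tr3 <- tr
  tr3$com_vx <- (0.7 - 0.5) * sqrt(9.81 / 1.0)
  mos3 <- compute_mos(tr3, l = 1.0)
  expect_equal(unique(mos3$mos_anterior), 0, tolerance = 1e-12)
})

test_that("the margin sign rule is equivalent to the XCoM-in-BOS rule", {
  fx <- fixture_default(noise_sd = 0.03, n_strides = 10, seed = 4)
  mos <- compute_mos(fx$trajectory)
  ok <- !is.na(mos$bos_anterior)
  inside <- mos$xcom[ok] <= mos$bos_anterior[ok] &
    mos$xcom[ok] >= mos$bos_posterior[ok]
  both_pos <- mos$mos_anterior[ok] >= 0 & mos$mos_posterior[ok] >= 0
  expect_identical(inside, both_pos)
  expect_identical(mos$mos_anterior[ok] < 0,
                   mos$xcom[ok] > mos$bos_anterior[ok])
})

test_that("traction maxima equal a brute-force scan and respect the filter", {
  fx <- fixture_default(noise_sd = 0, n_strides = 6)
  tr <- traction_series(fx$trajectory)
  # programmed stance shear peaks at the configured ratio
  expect_equal(max(tr$max_ratio), fx$spec$rcof, tolerance = 0.01)
  # brute force on one stance episode of the right heel
  fy <- fx$trajectory$fgy_heel_r
  fxx <- fx$trajectory$fgx_heel_r
  keep <- fy > 1
  expect_equal(max(tr$max_ratio[tr$point == "heel_r"]),
               max(abs(fxx[keep]) / fy[keep]), tolerance = 1e-9)
  # constant-force stance: ratio is exact
  tr_const <- fx$trajectory[1:100, ]
  tr_const$fgx_heel_r <- 20; tr_const$fgy_heel_r <- 100
  tr_const$fgx_toe_r <- 0;  tr_const$fgy_toe_r <- 100
  tr_const$fgy_r <- 200
  out <- traction_series(tr_const)
  expect_equal(out$max_ratio[out$point == "heel_r"], 0.2)
})
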