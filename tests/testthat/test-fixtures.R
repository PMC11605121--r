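test_that("noiseless fixtures reproduce their programmed strides exactly", {
  fx <- make_kinematic_walker(fixture_spec(stride_length = 1.0, speed = 1.25,
                                           noise_sd = 0, n_strides = 8))
  ev <- detect_gait_events(fx$trajectory)
  st <- stride_metrics(fx$trajectory, ev)
  expect_equal(mean(st$stride_length), 1.0, tolerance = 1e-9)
  expect_equal(mean(st$speed), 1.25, tolerance = 0.01)
})

test_that("fixtures are reproducible from their seed", {
  a <- make_kinematic_walker(fixture_spec(noise_sd = 0.05, seed = 42))
  b <- make_kinematic_walker(fixture_spec(noise_sd = 0.05, seed = 42))
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$truth, b$truth)
  c <- make_kinematic_walker(fixture_spec(noise_sd = 0.05, seed = 43))
  expect_false(identical(a$truth, c$truth))
})

test_that("programmed noise level appears in the empirical stride CV", {
  fx <- make_kinematic_walker(fixture_spec(noise_sd = 0.05, n_strides = 200,
                                           seed = 9))
  st <- stride_metrics(fx$trajectory)
  cv <- 100 * sd(st$stride_length) / mean(st$stride_length)
  expect_equal(cv, 5, tolerance = 1)
})

test_that("clearance ground truth is recovered from the mid-swing extrema", {
  spec <- fixture_spec(min_toe_clearance = 0.020, max_heel_clearance = 0.30,
                       noise_sd = 0, n_strides = 8)
  fx <- make_kinematic_walker(spec)
  cl <- clearance_metrics(fx$trajectory, feet = "R")
  expect_equal(mean(cl$min_toe_clearance), 0.020, tolerance = 1e-2)
  expect_equal(mean(cl$max_heel_clearance), 0.30, tolerance = 5e-3)
  # extrema agree with a brute-force scan over all swing samples
  ev <- detect_gait_events(fx$trajectory)
  sw <- slipgait:::swing_windows(ev, "R")
  i <- 3
  mid <- fx$trajectory$t >= sw$t_liftoff[i] + (sw$t_touchdown[i] - sw$t_liftoff[i]) / 3 &
    fx$trajectory$t <= sw$t_liftoff[i] + 2 * (sw$t_touchdown[i] - sw$t_liftoff[i]) / 3
  expect_equal(cl$min_toe_clearance[cl$swing == i],
               min(fx$trajectory$toe_y_r[mid]))
})

test_that("scripted fall fixtures classify to their construction labels", {
  for (seed in 1:5) {
    for (kind in c("slip_fall", "trip_fall", "no_fall")) {
      fx <- make_fall_fixture(kind, seed = seed)
      oc <- classify_outcome(fx$trajectory, sim_config())
      expect_identical(oc$outcome, kind)
    }
  }
})
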