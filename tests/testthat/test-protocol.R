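test_that("the friction grid matches the protocol enumeration", {
  g <- mu_grid()
  expect_equal(length(g), 25)
  expect_equal(g[1], 0.05)
  expect_equal(g[length(g)], 2.00)
  expect_true(all(diff(g) > 0))
  expect_equal(g[1:10], seq(0.05, 0.50, by = 0.05), tolerance = 1e-12)
  expect_equal(g[11:25], seq(0.60, 2.00, by = 0.10), tolerance = 1e-12)
})

test_that("slip threshold extraction equals a brute-force scan", {
  set.seed(8)
  for (i in 1:20) {
    tab <- tibble::tibble(
      mu_s = rep(mu_grid(), each = 5),
      outcome = sample(c("no_fall", "slip_fall", "trip_fall"), 125, TRUE,
                       prob = c(0.7, 0.2, 0.1))
    )
    expected <- suppressWarnings(max(tab$mu_s[tab$outcome == "slip_fall"]))
    got <- mu_slip_threshold(tab)
    if (is.infinite(expected)) expect_true(is.na(got))
    else expect_equal(got, expected)
    t2 <- suppressWarnings(min(tab$mu_s[tab$outcome == "trip_fall"]))
    got2 <- mu_trip_onset(tab)
    if (is.infinite(t2)) expect_true(is.na(got2)) else expect_equal(got2, t2)
  }
  none <- tibble::tibble(mu_s = mu_grid(), outcome = "no_fall")
  expect_true(is.na(mu_slip_threshold(none)))
})

test_that("classifier applies the hip-height and slip-speed definitions", {
  # constructed slip: stance-foot speed 0.5 m/s before a hip drop to 0.60 m
  fx <- make_fall_fixture("slip_fall", seed = 1)
  oc <- classify_outcome(fx$trajectory)
  expect_identical(oc$outcome, "slip_fall")
  expect_true(oc$slip_detected)
  expect_true(oc$fall_x > 5 && oc$fall_x < 15)
  # forward fall with stance-foot speed below threshold
  fx2 <- make_fall_fixture("trip_fall", seed = 2)
  oc2 <- classify_outcome(fx2$trajectory)
  expect_identical(oc2$outcome, "trip_fall")
  expect_identical(oc2$direction, "forward")
  expect_true(oc2$direction_consistent)
  # hip above the threshold throughout
  fx3 <- make_fall_fixture("no_fall", seed = 3)
  oc3 <- classify_outcome(fx3$trajectory)
  expect_identical(oc3$outcome, "no_fall")
  expect_true(is.na(oc3$fall_t))
})

test_that("classification is exclusive and exhaustive over many fixtures", {
  set.seed(31)
  labels <- character(0)
  for (i in 1:10) {
    kind <- sample(c("slip_fall", "trip_fall", "no_fall"), 1)
    oc <- classify_outcome(make_fall_fixture(kind, seed = i)$trajectory)
    expect_true(oc$outcome %in% c("no_fall", "slip_fall", "trip_fall"))
    labels <- c(labels, oc$outcome)
  }
  expect_length(labels, 10)
})

test_that("a trajectory that never reaches the window is rejected", {
  fx <- make_kinematic_walker(fixture_spec(n_strides = 3))
  expect_error(classify_outcome(fx$trajectory), "window")
})

test_that("per-trial seeds are deterministic, distinct, and in range", {
  s1 <- slipgait:::trial_seed(1, "young", 3, 2)
  s2 <- slipgait:::trial_seed(1, "young", 3, 2)
  expect_identical(s1, s2)
  seeds <- outer(1:25, 1:5, Vectorize(function(i, j)
    slipgait:::trial_seed(7, "elderly_faller", i, j)))
  expect_equal(length(unique(as.vector(seeds))), 125)
  expect_true(all(seeds > 0 & seeds < 2^31))
  expect_false(slipgait:::trial_seed(1, "young", 1, 1) ==
                 slipgait:::trial_seed(1, "elderly_faller", 1, 1))
})
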