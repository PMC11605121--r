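test_that("smooth indicator follows the three-branch ramp", {
  expect_equal(smooth_indicator(-0.001), 0)
  expect_equal(smooth_indicator(0.005), 0.5)
  expect_equal(smooth_indicator(0.02), 1)
  expect_equal(smooth_indicator(c(0, 0.01, 0.0025)), c(0, 1, 0.25))
})

test_that("ground reaction matches hand-evaluated spring-damper cases", {
  g <- ground_model()
  # 5 mm penetration, descending at 0.1 m/s, half-ramp indicator
  r <- ground_reaction(list(x = 0, y = -0.005, vx = 0, vy = -0.1),
                       anchor_x = 0, ground = g)
  expect_equal(r$F_gy, (18000 * 0.005 + 1000 * 0.1) * 0.5, tolerance = 1e-9)
  expect_equal(r$F_gx, 0, tolerance = 1e-9)
  # separating point: damping term drops out, full indicator
  r2 <- ground_reaction(list(x = 0, y = -0.02, vx = 0, vy = 0.2),
                        anchor_x = 0, ground = g)
  expect_equal(r2$F_gy, 18000 * 0.02, tolerance = 1e-9)
  # above ground: both forces vanish
  r3 <- ground_reaction(list(x = 0, y = 0.01, vx = -1, vy = -1),
                        anchor_x = 0, ground = g)
  expect_equal(c(r3$F_gx, r3$F_gy), c(0, 0))
  # horizontal spring pulls back toward the anchor
  r4 <- ground_reaction(list(x = 0.1, y = -0.02, vx = 0, vy = 0),
                        anchor_x = 0.08, ground = g)
  expect_equal(r4$F_gx, -27000 * 0.02, tolerance = 1e-9)
})

test_that("friction cap clips with sign preservation and honours unset", {
  expect_equal(friction_cap(10, 100, 0.5), 10)
  expect_equal(friction_cap(0, 50, 0.05), 0)
  expect_equal(friction_cap(-100, 50, 0.5), -25)
  expect_equal(friction_cap(100, 50, 0.5), 25)
  expect_equal(friction_cap(1000, 50, NA), 1000) # unset: any ratio allowed
  expect_error(friction_cap(10, -1, 0.5))
})

test_that("friction schedule is piecewise in x with an unset head", {
  g <- ground_model(friction = friction_switch(0.3, switch_x = 5))
  near <- slipgait:::sg_ground_reaction(1, -0.02, 5, 0, 1, unclass(g), TRUE, TRUE)
  expect_lt(near$F_gx, -0.3 * near$F_gy - 1) # uncapped before the switch
  far <- slipgait:::sg_ground_reaction(6, -0.02, 5, 0, 6, unclass(g), TRUE, TRUE)
  expect_equal(far$F_gx, -0.3 * far$F_gy, tolerance = 1e-9)
})

test_that("anchors reset on touchdown and persist through contact", {
  contacts <- tibble::tibble(in_contact = c(FALSE, TRUE),
                             anchor_x = c(0, 1.5))
  pts <- tibble::tibble(x = c(3.21, 1.9), y = c(-0.001, -0.002))
  up <- update_anchors(contacts, pts)
  expect_true(up$in_contact[1])
  expect_equal(up$anchor_x[1], 3.21)      # new anchor at touchdown position
  expect_equal(up$anchor_x[2], 1.5)       # continuous contact: unchanged
  # touchdown - liftoff - touchdown: second anchor is independent of first
  c2 <- update_anchors(up, tibble::tibble(x = c(3.3, 2.0), y = c(0.01, 0.01)))
  expect_false(any(c2$in_contact))
  c3 <- update_anchors(c2, tibble::tibble(x = c(3.7, 2.4), y = c(-0.001, -0.001)))
  expect_equal(c3$anchor_x, c(3.7, 2.4))
})
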