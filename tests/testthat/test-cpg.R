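test_that("rectification is max(0, u)", {
  expect_equal(rectify(c(-1, 0, 2.5)), c(0, 0, 2.5))
})

test_that("the origin is an equilibrium of the unforced network", {
  params <- cpg_parameters("young")
  d <- neuron_derivatives(rep(0, 14), rep(0, 14), params,
                          feedback = rep(0, 14), u0_noisy = 0)
  expect_equal(d$du, rep(0, 14))
  expect_equal(d$dv, rep(0, 14))
})

test_that("an isolated neuron's fixed point matches an iteration oracle", {
  params <- cpg_parameters("young")
  params$W <- matrix(0, 14, 14)
  u0 <- params$u0
  beta <- params$beta
  # solve u* = u0 - beta f(v*), v* = f(u*) by damped fixed-point iteration
  u <- u0; v <- 0
  for (i in 1:2000) {
    u <- u + 0.1 * (u0 - beta * max(0, v) - u)
    v <- v + 0.1 * (max(0, u) - v)
  }
  d <- neuron_derivatives(rep(u, 14), rep(v, 14), params,
                          feedback = rep(0, 14), u0_noisy = u0)
  expect_equal(max(abs(d$du)), 0, tolerance = 1e-6)
  expect_equal(max(abs(d$dv)), 0, tolerance = 1e-6)
})

# integrate an isolated two-neuron oscillator with the package derivative
integrate_pair <- function(params, t_end, dt = 1e-4, u_init = c(0.5, 0)) {
  u <- c(u_init, rep(0, 12)); v <- rep(0, 14)
  n <- round(t_end / dt)
  out <- numeric(n)
  for (i in seq_len(n)) {
    d1 <- slipgait:::sg_neuron_derivatives(u, v, unclass(params), rep(0, 14),
                                           params$u0)
    u2 <- u + 0.5 * dt * d1$du; v2 <- v + 0.5 * dt * d1$dv
    d2 <- slipgait:::sg_neuron_derivatives(u2, v2, unclass(params), rep(0, 14),
                                           params$u0)
    u <- u + dt * d2$du; v <- v + dt * d2$dv
    out[i] <- max(0, u[1])
  }
  out
}

# an isolated pair with classic oscillation-permitting constants (strong
# mutual inhibition, adaptation coefficient 2.5)
pair_params <- function(tau = 0.02, ratio = 0.036, u0 = 7.08) {
  params <- cpg_parameters("young")
  W <- matrix(0, 14, 14)
  W[1, 2] <- W[2, 1] <- -2
  params$W <- W
  params$beta <- 2.5
  params$tau <- rep(tau, 14)
  params$tau_prime <- rep(tau / ratio, 14)
  params$u0 <- u0
  params
}

osc_period <- function(y, dt = 1e-4) {
  on <- y > 1e-6
  starts <- which(diff(on) == 1)
  if (length(starts) < 3) return(NA_real_)
  mean(diff(starts[-1])) * dt
}

test_that("a mutually inhibiting pair sustains a limit cycle whose period
           matches a fine-step reference integration", {
  params <- pair_params()
  y <- integrate_pair(params, 4)
  expect_gt(osc_period(y), 0)                      # sustained oscillation
  y_fine <- integrate_pair(params, 4, dt = 2.5e-5)
  expect_equal(osc_period(y, 1e-4), osc_period(y_fine, 2.5e-5),
               tolerance = 0.01)
})

test_that("oscillator frequency increases as tau decreases at fixed ratio", {
  periods <- sapply(c(0.015, 0.025, 0.04), function(tau) {
    osc_period(integrate_pair(pair_params(tau = tau), 6))
  })
  expect_true(all(diff(periods) > 0))
})

test_that("network states remain bounded under tonic drive", {
  params <- cpg_parameters("young")
  u <- rep(0.1, 14); v <- rep(0, 14)
  dt <- 2e-3
  peak <- 0
  for (i in seq_len(30000)) { # 60 s
    d <- slipgait:::sg_neuron_derivatives(u, v, unclass(params), rep(0, 14),
                                          params$u0)
    u <- u + dt * d$du; v <- v + dt * d$dv
    peak <- max(peak, max(abs(u)), max(abs(v)))
  }
  expect_true(is.finite(peak))
  expect_lt(peak, 50 * params$u0)
})

test_that("active torques are linear in the outputs and zero at rest", {
  params <- cpg_parameters("young")
  expect_equal(active_torques(rep(0, 14), params), rep(0, 7))
  y <- runif(14, 0, 3)
  t1 <- active_torques(y, params, hR = 0.7, hL = 0.2, theta = rep(0.1, 8))
  t2 <- active_torques(2 * y, params, hR = 0.7, hL = 0.2, theta = rep(0.1, 8))
  expect_equal(t2, 2 * t1, tolerance = 1e-12)
})

test_that("the faller parameterization scales channel 3 by 0.665", {
  young <- cpg_parameters("young")
  faller <- cpg_parameters("elderly_faller")
  expect_equal(faller$p[3] / young$p[3], 0.665, tolerance = 1e-12)
  # channel 3 is the knee flexor base channel: isolate it via the knee flexor
  # neuron with everything else silent
  y <- rep(0, 14); y[5] <- 1
  ty <- active_torques(y, young, hR = 1, hL = 1)
  tf <- active_torques(y, faller, hR = 1, hL = 1)
  expect_equal(tf[4] / ty[4], 0.665, tolerance = 1e-12)
})

test_that("passive torques vanish in the neutral range and oppose excursions", {
  a <- build_anthropometry()
  expect_equal(passive_torques(rep(0, 8), rep(0, 8), anthro = a), rep(0, 7))
  # knee hyperextension: right shank ahead of right thigh beyond the stop
  th <- rep(0, 8); th[5] <- 0.3
  tp <- passive_torques(th, rep(0, 8), anthro = a)
  expect_lt(tp[4], 0) # restoring torque opposes the extension excursion
  th2 <- rep(0, 8); th2[5] <- -2.5
  tp2 <- passive_torques(th2, rep(0, 8), anthro = a)
  expect_gt(tp2[4], 0)
})

test_that("sensory feedback is left-right mirror symmetric", {
  a <- build_anthropometry()
  wm <- walker_model(cpg_parameters("young"), ground_model(), a)
  set.seed(3)
  angles <- rnorm(8, 0, 0.3)
  rates <- rnorm(8, 0, 1)
  pose <- kinematic_pose(a, angles, pelvis_xy = c(0, 0.93), rates = rates)
  # mirrored state: swap left/right segments (thighs, shanks, feet)
  swap <- c(1, 2, 4, 3, 6, 5, 8, 7)
  pose_m <- kinematic_pose(a, angles[swap], pelvis_xy = c(0, 0.93),
                           rates = rates[swap])
  s1 <- sensory_feedback(pose, list(hR = 0.8, hL = 0.1), wm)
  s2 <- sensory_feedback(pose_m, list(hR = 0.1, hL = 0.8), wm)
  nswap <- c(3, 4, 1, 2, 7, 8, 5, 6, 11, 12, 9, 10, 13, 14)
  expect_equal(s2, s1[nswap], tolerance = 1e-12)
})

test_that("contact-gated feedback components vanish with both feet airborne", {
  a <- build_anthropometry()
  wm <- walker_model(cpg_parameters("young"), ground_model(), a)
  pose <- kinematic_pose(a, rep(0, 8), pelvis_xy = c(0, 2))
  s <- sensory_feedback(pose, list(hR = 0, hL = 0), wm)
  # knee servo, push-off, ankle pitch, posture corrections all load-gated:
  # with zero thigh angles and zero loads only the swing terms remain
  expect_equal(s[5], 0)  # knee extensor stance servo
  expect_equal(s[10], 0) # plantarflexor stance drive
  expect_equal(s[12], 0)
})
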