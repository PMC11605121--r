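test_that("the three registered parameterizations carry their frozen values", {
  y <- gait_model("young")
  expect_equal(y$u0, 7.08)
  expect_equal(y$tau_ratio, 0.036)
  expect_equal(y$noise_pct, 8.50)
  nf <- gait_model("elderly_nonfaller")
  expect_equal(c(nf$u0, nf$tau_ratio, nf$noise_pct), c(5.16, 0.100, 2.00))
  f <- gait_model("elderly_faller")
  expect_equal(c(f$u0, f$tau_ratio, f$noise_pct), c(5.10, 0.076, 0.100))
  expect_equal(f$p[4], 0.86)
  expect_equal(f$p[14], 3.92)
  # the non-faller shares the young transfer coefficients exactly
  expect_identical(nf$p, y$p)
  expect_equal(length(y$p), 18)
})

test_that("unknown model names produce an informative error", {
  expect_error(gait_model("nosuch"), "young, elderly_nonfaller, elderly_faller")
})

test_that("parameters mirror the aging narrative ordering", {
  y <- gait_model("young"); nf <- gait_model("elderly_nonfaller")
  f <- gait_model("elderly_faller")
  expect_true(y$u0 > nf$u0 && nf$u0 > f$u0)
  expect_true(all(f$p <= nf$p))
})

test_that("noisy steady input has the advertised spread and determinism", {
  y <- gait_model("young")
  set.seed(123)
  draws <- noisy_u0(y, 1e5)
  expect_equal(sd(draws) / y$u0, 0.085, tolerance = 0.002)
  expect_equal(mean(draws), y$u0, tolerance = 0.01)
  f0 <- gait_model("elderly_faller"); f0$noise_pct <- 0
  expect_equal(noisy_u0(f0, 10), rep(f0$u0, 10))
  set.seed(5); a <- noisy_u0(y, 100)
  set.seed(5); b <- noisy_u0(y, 100)
  expect_identical(a, b)
})

test_that("derived adaptation constants honour the model ratios", {
  for (nm in c("young", "elderly_nonfaller", "elderly_faller")) {
    p <- cpg_parameters(nm)
    expect_equal(p$tau / p$tau_prime, rep(gait_model(nm)$tau_ratio, 14),
                 tolerance = 1e-12)
    expect_true(all(p$tau > 0) && all(p$tau_prime > 0))
    expect_true(all(diag(p$W) == 0))
    expect_true(all(p$p >= 0))
  }
})

test_that("the reference-table reductions reproduce the reported percentages", {
  red <- gait_mean_reductions()
  get <- function(m, v) red$reduction_pct[red$model == m & red$variable == v]
  expect_equal(get("elderly_nonfaller", "stride_length"), 35)
  expect_equal(get("elderly_faller", "stride_length"), 40)
  expect_equal(get("elderly_nonfaller", "walking_speed"), 42)
  expect_equal(get("elderly_faller", "walking_speed"), 47)
  expect_equal(get("elderly_nonfaller", "max_foot_clearance"), 22)
  expect_equal(get("elderly_faller", "max_foot_clearance"), 58)
  expect_equal(get("elderly_nonfaller", "min_foot_clearance"), 13)
  expect_equal(get("elderly_faller", "min_foot_clearance"), 30)
})
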