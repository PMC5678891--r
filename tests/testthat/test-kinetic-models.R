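test_that("exercise component is gated at onset and saturates mono-exponentially", {
  p <- ref_params()
  expect_identical(exercise_component(c(0, 30, 60), p), c(0, 0, 0))
  expect_equal(exercise_component(90, p), 700 * (1 - exp(-1)))
  expect_equal(exercise_component(p$lam + 50 * p$tau1, p), 700,
               tolerance = 1e-6 / 700)
  grid <- exercise_component(seq(0, 2000, by = 5), p)
  expect_true(all(diff(grid) >= 0))
  expect_error(exercise_component(c(10, NA), p), "finite")
  expect_error(exercise_component(Inf, p), "finite")
})

test_that("recovery fraction at one half-time is family-specific", {
  t0 <- 60 + 360
  drop_ <- 400 - 1000
  for (tau2 in c(-0.5, -2, -5)) {
    p <- ref_params(tau2 = tau2)
    expect_equal(recovery_component(t0 + p$t_half, p, "log_logistic"),
                 drop_ / 2)
  }
  p <- ref_params(tau2 = -2)
  expect_equal(recovery_component(t0 + p$t_half, p, "weibull_1"),
               drop_ * exp(-1))
  p2 <- ref_params(tau2 = 2)
  expect_equal(recovery_component(t0 + p2$t_half, p2, "weibull_2"),
               drop_ * (1 - exp(-1)))
  # inactive before the aligned recovery onset
  for (fam in vo2_families()) {
    expect_identical(recovery_component(c(0, 100, t0), p, fam), c(0, 0, 0))
  }
})

test_that("combined curve passes through the three plateaus and is continuous", {
  for (fam in vo2_families()) {
    tau2 <- tau2_sign(fam) * 2
    p <- ref_params(tau2 = tau2)
    t0 <- p$lam_max + 360
    expect_identical(vo2_curve(0, p, fam), p$vo2_rest)
    # exercise plateau
    expect_equal(vo2_curve(t0, p, fam), p$vo2_ss,
                 tolerance = 1e-3 * (p$vo2_ss - p$vo2_rest) / p$vo2_ss)
    # recovery asymptote
    expect_equal(vo2_curve(t0 + 1e3 * p$t_half, p, fam), p$vo2_rec,
                 tolerance = 1e-3)
    # continuity at both phase boundaries
    eps <- 1e-9
    expect_equal(vo2_curve(p$lam + eps, p, fam), vo2_curve(p$lam, p, fam),
                 tolerance = 1e-6)
    expect_equal(vo2_curve(t0 + eps, p, fam), vo2_curve(t0, p, fam),
                 tolerance = 1e-6)
  }
})

test_that("canonical tau2 signs give the 0 -> full-decrease recovery limits", {
  for (fam in vo2_families()) {
    p <- ref_params(tau2 = tau2_sign(fam) * 2)
    t0 <- p$lam_max + 360
    drop_ <- p$vo2_rec - p$vo2_ss
    expect_equal(recovery_component(t0 + 1e-6 * p$t_half, p, fam), 0,
                 tolerance = 1e-6 * abs(drop_))
    expect_equal(recovery_component(t0 + 1e3 * p$t_half, p, fam), drop_,
                 tolerance = 1e-3 * abs(drop_))
  }
})

test_that("family asymmetry orders the decrease at one half-time: w1 < LL < w2", {
  t0 <- 60 + 360
  for (mag in c(0.5, 1, 2, 4)) {
    f_ll <- recovery_component(t0 + 120, ref_params(tau2 = -mag),
                               "log_logistic")
    f_w1 <- recovery_component(t0 + 120, ref_params(tau2 = -mag), "weibull_1")
    f_w2 <- recovery_component(t0 + 120, ref_params(tau2 = mag), "weibull_2")
    # fractions of the (negative) decrease achieved at t0 + t_half
    expect_lt(abs(f_w1), abs(f_ll))
    expect_lt(abs(f_ll), abs(f_w2))
  }
})

test_that("analytic gradient matches central finite differences", {
  for (fam in vo2_families()) {
    p <- ref_params(tau2 = tau2_sign(fam) * 1.8, t_half = 135)
    t <- c(10, 61, 100, 419.5, 421, 480, 555, 700, 1100)
    ana <- vo2_gradient(t, p, fam)
    num <- numeric_gradient(t, p, fam)
    denom <- pmax(abs(num), 1)
    expect_lt(max(abs(ana - num) / denom), 1e-6)
  }
  # boundary conventions
  p <- ref_params()
  g <- vo2_gradient(c(0, 30), p, "log_logistic")
  expect_equal(unname(g[, "vo2_rest"]), c(1, 1))
  g2 <- vo2_gradient(c(100, 420), p, "log_logistic")
  expect_equal(unname(g2[, "t_half"]), c(0, 0))
})

test_that("mean response time is the 63% point of the exercise rise", {
  expect_equal(mean_response_time(ref_params()), 30)
  p <- kinetic_params(300, 1000, 400, tau1 = 45.5, tau2 = -2, t_half = 120,
                      lam = 60)
  expect_equal(mean_response_time(p), 45.5)
  mrt <- mean_response_time(p)
  rise <- vo2_curve(p$lam + mrt, p, "log_logistic") - p$vo2_rest
  expect_equal(rise / (p$vo2_ss - p$vo2_rest), 1 - exp(-1))
})

test_that("parameter-space invariants are enforced", {
  expect_error(kinetic_params(-1, 1000, 400, 30, -2, 120, lam = 60),
               "vo2_rest")
  expect_error(kinetic_params(300, 250, 400, 30, -2, 120, lam = 60),
               "vo2_ss")
  expect_error(kinetic_params(300, 1000, 1200, 30, -2, 120, lam = 60),
               "vo2_rec")
  expect_error(kinetic_params(300, 1000, 400, -5, -2, 120, lam = 60), "tau1")
  expect_error(kinetic_params(300, 1000, 400, 30, -2, -120, lam = 60),
               "t_half")
  expect_error(kinetic_params(300, 1000, 400, 30, -2, 120, lam = 90,
                              lam_max = 60), "lam")
})
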