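mk_inp <- function(phi, s, stage = rep(2L, length(phi))) {
  tibble::tibble(
    patient_id = sprintf("P%02d", seq_along(phi)),
    stage = stage, phi_hat = phi, s_i = s
  )
}

test_that("common-effect pooling matches the inverse-variance closed form", {
  fm <- fit_meta(mk_inp(c(10, 20), c(1, 2)), tau2 = 0)
  expect_equal(fm$estimates$estimate, (10 / 1 + 20 / 4) / (1 / 1 + 1 / 4))
  expect_equal(fm$estimates$se, 1 / sqrt(1.25))
  expect_equal(fm$tau2_hat, 0)
})

test_that("a single patient is returned unchanged by the meta step", {
  expect_message(fm <- fit_meta(mk_inp(10, 1)), "tau")
  expect_equal(fm$estimates$estimate, 10)
  expect_equal(fm$estimates$se, 1)
})

test_that("weighted regression reproduces the hand-worked WLS example", {
  fw <- fit_weighted(mk_inp(c(10, 20), c(1, 1)))
  expect_equal(fw$estimates$estimate, 15)
  expect_equal(fw$sigma2_hat, 50)
  expect_equal(fw$estimates$se, 5)
  expect_equal(fw$df_resid, 1)
})

test_that("equal first-step errors reduce weighted regression to stage means", {
  set.seed(21)
  phi <- stats::rnorm(12, 140, 20)
  stage <- rep(c(2L, 3L, 4L), each = 4)
  fw <- fit_weighted(mk_inp(phi, rep(2.5, 12), stage))
  means <- as.numeric(tapply(phi, stage, mean))
  expect_equal(fw$estimates$estimate, means)
})

test_that("degenerate weighted designs are rejected", {
  expect_error(fit_weighted(mk_inp(c(10, 20), c(1, 1), c(2L, 3L))),
               "degrees of freedom")
})

test_that("huge heterogeneity drives the meta estimate to unweighted means", {
  set.seed(22)
  phi <- stats::rnorm(15, 140, 25)
  stage <- rep(c(2L, 3L, 4L), each = 5)
  s_i <- stats::runif(15, 2, 20)
  fm <- fit_meta(mk_inp(phi, s_i, stage), tau2 = 1e10)
  means <- as.numeric(tapply(phi, stage, mean))
  expect_equal(fm$estimates$estimate, means, tolerance = 1e-4)
})

test_that("rescaling all first-step errors moves meta but not weighted estimates", {
  set.seed(23)
  phi <- stats::rnorm(18, 140, 25)
  stage <- rep(c(2L, 3L, 4L), each = 6)
  s_i <- stats::runif(18, 2, 25)
  w1 <- fit_weighted(mk_inp(phi, s_i, stage))
  w2 <- fit_weighted(mk_inp(phi, 3 * s_i, stage))
  expect_equal(w1$estimates$estimate, w2$estimates$estimate)
  m1 <- fit_meta(mk_inp(phi, s_i, stage))
  m2 <- fit_meta(mk_inp(phi, 3 * s_i, stage))
  expect_gt(max(abs(m1$estimates$estimate - m2$estimates$estimate)), 1e-6)
})

test_that("with tau2 = 0 forced, meta and weighted point estimates coincide", {
  set.seed(24)
  phi <- stats::rnorm(12, 140, 20)
  stage <- rep(c(2L, 3L, 4L), each = 4)
  s_i <- stats::runif(12, 2, 20)
  fm <- fit_meta(mk_inp(phi, s_i, stage), tau2 = 0)
  fw <- fit_weighted(mk_inp(phi, s_i, stage))
  expect_equal(fm$estimates$estimate, fw$estimates$estimate)
})

test_that("DerSimonian-Laird heterogeneity matches the closed form", {
  set.seed(25)
  phi <- stats::rnorm(20, 140, 25)
  s_i <- stats::runif(20, 5, 15)
  fm <- fit_meta(mk_inp(phi, s_i), method = "DL")
  # closed-form oracle for a single group
  w <- 1 / s_i^2
  theta_fe <- sum(w * phi) / sum(w)
  q <- sum(w * (phi - theta_fe)^2)
  tau2_dl <- max(0, (q - (20 - 1)) / (sum(w) - sum(w^2) / sum(w)))
  expect_equal(fm$tau2_hat, tau2_dl, tolerance = 1e-8)
})

test_that("the meta step recovers stage means and heterogeneity from its own model", {
  truth <- c(`2` = 128, `3` = 131, `4` = 164)
  tau <- 25
  set.seed(26)
  one_rep <- function() {
    stage <- rep(c(2L, 3L, 4L), times = c(21, 30, 10))
    s_i <- stats::runif(61, 5, 15)
    phi <- truth[as.character(stage)] + stats::rnorm(61, 0, tau) +
      stats::rnorm(61, 0, s_i)
    fit_meta(mk_inp(phi, s_i, stage))
  }
  fm <- one_rep()
  z <- (fm$estimates$estimate - truth) / fm$estimates$se
  expect_true(all(abs(z) < 3))
  tau2_hats <- replicate(50, one_rep()$tau2_hat)
  expect_gt(stats::median(tau2_hats), tau^2 / 2)
  expect_lt(stats::median(tau2_hats), tau^2 * 2)
})

test_that("weighted-regression shrinkage tendency is measurable across replicates", {
  # soft property: the shrink-towards-the-mean tendency of the weighted
  # estimates is logged, not asserted as a hard bound
  set.seed(27)
  truth <- c(`2` = 128, `3` = 133, `4` = 168)
  narrower <- replicate(25, {
    stage <- rep(c(2L, 3L, 4L), times = c(21, 30, 10))
    s_i <- stats::runif(61, 3, 30)
    phi <- truth[as.character(stage)] + stats::rnorm(61, 0, 25) +
      stats::rnorm(61, 0, s_i)
    inp <- mk_inp(phi, s_i, stage)
    diff(range(fit_weighted(inp)$estimates$estimate)) <=
      diff(range(fit_meta(inp)$estimates$estimate))
  })
  expect_true(is.finite(mean(narrower)))
  succeed(sprintf("weighted spread <= meta spread in %.0f%% of replicates",
                  100 * mean(narrower)))
})
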