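#' Random-effects meta-analysis of per-patient estimates
#'
#' Second step of the meta-analytic strategy: the per-patient estimates
#' `phi_hat` (with first-step standard errors `s_i`, treated as known
#' within-patient SDs — no residual error is estimated) are pooled under the
#' model `phi_hat_i = theta_stage(i) + A_i + e_i`, with patient random
#' effects `A_i ~ N(0, tau^2)` and `e_i ~ N(0, s_i^2)`. Stage enters as a
#' moderator without intercept, so the coefficients are per-stage means.
#' Fitted with [metafor::rma()]; `tau^2` by REML (ML available), inference on
#' the normal (z) reference.
#'
#' @param inp Tibble from [meta_input()]: `phi_hat`, `s_i`, `stage` (and
#'   `patient_id`).
#' @param family Curve family label carried into the result.
#' @param param Focal parameter label (default `"t_half"`).
#' @param method `"REML"` (default), `"ML"`, or `"DL"`
#'   (DerSimonian-Laird).
#' @param tau2 Optionally fix the heterogeneity variance (e.g. `0` for a
#'   common-effect fit); when the number of patients equals the number of
#'   stages `tau2` is inestimable and is fixed at 0 with a message.
#' @return Object of class `vo2_summary` with `estimates` (a
#'   [stage_estimates()]), `tau2_hat`, `loglik`, `aic`, `m`.
#' @export
fit_meta <- function(inp, family = NA_character_, param = "t_half",
                     method = c("REML", "ML", "DL"), tau2 = NULL) {
  method <- match.arg(method)
  stopifnot(all(c("phi_hat", "s_i", "stage") %in% names(inp)),
            all(inp$s_i > 0))
  m <- nrow(inp)
  stage_f <- factor(inp$stage)
  q <- nlevels(stage_f)
  if (is.null(tau2) && m == q) {
    message("as many patients as stages: fixing tau^2 = 0")
    tau2 <- 0
  }
  # single-level factors cannot be dummy-coded; an intercept-only model is
  # the same per-stage-mean fit when only one stage is present
  args <- list(
    yi = inp$phi_hat, sei = inp$s_i,
    mods = if (q > 1) ~ 0 + stage_f else ~1,
    method = method
  )
  if (!is.null(tau2)) args$tau2 <- tau2
  fit <- do.call(metafor::rma, args)

  cf <- as.numeric(fit$beta)
  se <- fit$se
  stages <- as.integer(levels(stage_f))
  est <- stage_estimates(
    stage = stages, estimate = cf, se = se,
    vcov = as.matrix(stats::vcov(fit)),
    method = "meta", family = family, param = param, reference = "z"
  )
  ll_col <- if (method == "REML") "REML" else "ML"
  structure(
    list(
      method = "meta", family = family, param = param,
      estimates = est,
      tau2_hat = fit$tau2,
      loglik = fit$fit.stats["ll", ll_col],
      aic = fit$fit.stats["AIC", ll_col],
      m = m, q = q,
      fit = fit
    ),
    class = "vo2_summary"
  )
}

#' Weighted regression of per-patient estimates
#'
#' Variant of the two-step pooling in which the residual errors are
#' `e_i ~ N(0, sigma^2 s_i^2)`: the known first-step variances act as
#' weights, and a multiplicative residual scale `sigma^2` is estimated from
#' the data. Weighted least squares of `phi_hat` on stage dummies (no
#' intercept) with weights `1/s_i^2`;
#' `sigma^2 = weighted RSS / (m - q)`; inference on the t reference with
#' `m - q` degrees of freedom.
#'
#' @inheritParams fit_meta
#' @return Object of class `vo2_summary` with `sigma2_hat`, `df_resid`.
#' @export
fit_weighted <- function(inp, family = NA_character_, param = "t_half") {
  stopifnot(all(c("phi_hat", "s_i", "stage") %in% names(inp)),
            all(inp$s_i > 0))
  m <- nrow(inp)
  stage_f <- factor(inp$stage)
  q <- nlevels(stage_f)
  if (m <= q) stop("no residual degrees of freedom (m <= number of stages)")
  dat <- data.frame(phi_hat = inp$phi_hat, stage_f = stage_f,
                    w = 1 / inp$s_i^2)
  fit <- if (q > 1) {
    stats::lm(phi_hat ~ 0 + stage_f, data = dat, weights = w)
  } else {
    stats::lm(phi_hat ~ 1, data = dat, weights = w)
  }
  sm <- summary(fit)
  cf <- sm$coefficients
  stages <- as.integer(levels(stage_f))
  est <- stage_estimates(
    stage = stages, estimate = unname(cf[, 1]), se = unname(cf[, 2]),
    vcov = stats::vcov(fit),
    method = "weighted", family = family, param = param,
    reference = "t", df = m - q
  )
  structure(
    list(
      method = "weighted", family = family, param = param,
      estimates = est,
      sigma2_hat = sm$sigma^2,
      loglik = as.numeric(stats::logLik(fit)),
      aic = stats::AIC(fit),
      m = m, q = q, df_resid = m - q,
      fit = fit
    ),
    class = "vo2_summary"
  )
}

#' @export
print.vo2_summary <- function(x, ...) {
  lab <- if (x$method == "meta") {
    sprintf("tau^2 = %.2f", x$tau2_hat)
  } else {
    sprintf("sigma^2 = %.2f, df = %d", x$sigma2_hat, x$df_resid)
  }
  cat("Two-step ", x$method, " summary of ", x$param,
      " (", x$family, "; ", lab, ")\n", sep = "")
  print(tidy(x$estimates))
  cat("  m =", x$m, " logLik =", round(x$loglik, 2),
      " AIC =", round(x$aic, 2), "\n")
  invisible(x)
}

#' @method tidy vo2_summary
#' @export
tidy.vo2_summary <- function(x, ...) tidy(x$estimates)

#' @method glance vo2_summary
#' @export
glance.vo2_summary <- function(x, ...) {
  tibble::tibble(
    method = x$method, family = x$family,
    tau2 = x$tau2_hat %||% NA_real_,
    sigma2 = x$sigma2_hat %||% NA_real_,
    logLik = x$loglik, AIC = x$aic,
    m = x$m, df.residual = x$df_resid %||% NA_integer_
  )
}
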