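# Vectorized curve + gradient where each observation carries its own
# parameter values (the calling convention of nlme/gnls model functions).
# Series are assumed aligned: exercise onset at lam_max, recovery onset at
# lam_max + 360.
curve_vec <- function(time, lam_max, vo2_rest, vo2_ss, vo2_rec,
                      tau1, tau2, t_half, family) {
  n <- length(time)
  t0 <- lam_max + 360
  val <- rep(vo2_rest, length.out = n)
  g <- matrix(0, n, 6, dimnames = list(NULL, param_names()))
  g[, "vo2_rest"] <- 1

  ex <- time > lam_max
  u <- (time[ex] - lam_max[ex]) / tau1[ex]
  E <- 1 - exp(-u)
  span <- (vo2_ss - vo2_rest)[ex]
  val[ex] <- val[ex] + span * E
  g[ex, "vo2_rest"] <- 1 - E
  g[ex, "vo2_ss"] <- E
  g[ex, "tau1"] <- -span * u * exp(-u) / tau1[ex]

  rc <- time > t0
  if (any(rc)) {
    x <- (time[rc] - t0[rc]) / t_half[rc]
    L <- log(x)
    z <- exp(tau2[rc] * L)
    frac <- recovery_fraction(z, family)
    dgdz <- recovery_fraction_dz(z, family)
    dgdz[!is.finite(z)] <- 0
    zL <- z * L
    zL[!is.finite(z)] <- 0
    drop_ <- (vo2_rec - vo2_ss)[rc]
    val[rc] <- val[rc] + drop_ * frac
    g[rc, "vo2_ss"] <- g[rc, "vo2_ss"] - frac
    g[rc, "vo2_rec"] <- frac
    g[rc, "tau2"] <- drop_ * dgdz * zL
    g[rc, "t_half"] <- -drop_ * dgdz * z * tau2[rc] / t_half[rc]
  }
  attr(val, "gradient") <- g
  val
}

#' Curve evaluator used inside mixed-model formulas
#'
#' Same curve as [vo2_curve()] but with per-observation parameter vectors and
#' a `"gradient"` attribute, as `nlme`/`gnls` model formulas require.
#'
#' @param time,lam_max Aligned time and cohort resting maximum (s).
#' @param vo2_rest,vo2_ss,vo2_rec,tau1,tau2,t_half Parameter vectors.
#' @param family One of [vo2_families()].
#' @return Numeric vector with a gradient attribute.
#' @keywords internal
#' @export
vo2_nlme_model <- function(time, lam_max, vo2_rest, vo2_ss, vo2_rec,
                           tau1, tau2, t_half,
                           family = "log_logistic") {
  recycle <- function(x) rep(x, length.out = length(time))
  curve_vec(time, recycle(lam_max), recycle(vo2_rest), recycle(vo2_ss),
            recycle(vo2_rec), recycle(tau1), recycle(tau2),
            recycle(t_half), match_family(family))
}

default_random_params <- function() c("vo2_ss", "vo2_rec", "tau2", "t_half")

# Stage-specific starting values: per-stage medians of individual fits.
nlme_start_values <- function(data, family, fits = NULL) {
  if (is.null(fits)) fits <- fit_cohort(data, family)
  tab <- tidy_cohort_fits(fits) |>
    dplyr::filter(.data$family == !!family) |>
    dplyr::group_by(.data$stage, .data$term) |>
    dplyr::summarise(estimate = stats::median(.data$estimate),
                     .groups = "drop")
  stages <- sort(unique(data$stage))
  start <- matrix(NA_real_, 6, length(stages),
                  dimnames = list(param_names(), as.character(stages)))
  for (i in seq_len(nrow(tab))) {
    start[tab$term[i], as.character(tab$stage[i])] <- tab$estimate[i]
  }
  # fall back to cohort-wide medians for any stage with no converged fit
  overall <- apply(start, 1, stats::median, na.rm = TRUE)
  for (j in seq_len(ncol(start))) {
    miss <- is.na(start[, j])
    start[miss, j] <- overall[miss]
  }
  start
}

nlme_model_formula <- function(family) {
  stats::as.formula(sprintf(
    "vo2 ~ vo2_nlme_model(time, lam_max, vo2_rest, vo2_ss, vo2_rec, tau1, tau2, t_half, \"%s\")",
    family
  ), env = asNamespace("vo2kinetics"))
}

#' Fit a nonlinear mixed-effects model to the whole cohort
#'
#' One fixed effect per curve parameter per GOLD stage (dummy coding without
#' intercept, so coefficients are stage means: 18 fixed effects for three
#' stages) and Gaussian patient-level random effects on the four recovery
#' parameters (`vo2_ss`, `vo2_rec`, `tau2`, `t_half`), with i.i.d. residual
#' errors. Estimated by the alternating-linearization (Lindstrom-Bates)
#' scheme of [nlme::nlme()]. The random-effect covariance `G` is diagonal by
#' default; `g_structure = "full"` fits an unstructured covariance.
#' `random_params = character(0)` drops the random effects entirely, reducing
#' the model to pooled per-stage nonlinear least squares (via
#' [nlme::gnls()]).
#'
#' Non-convergence is a first-class outcome (`converged = FALSE` with the
#' error message), not a silent result: subgroup fits at small sample sizes
#' are expected to fail sometimes.
#'
#' @param data Binned, aligned cohort tibble (`patient_id`, `stage`, `time`,
#'   `vo2`, `lam_max`).
#' @param family One of [vo2_families()].
#' @param random_params Parameters carrying random effects.
#' @param g_structure `"diagonal"` (default) or `"full"`.
#' @param start Optional 6 x n_stage start matrix (rows = parameters); by
#'   default derived from per-patient fit medians, or from `fits` if given.
#' @param fits Optional [fit_cohort()] result to derive starts from.
#' @param max_iter Maximum outer iterations (default 200).
#' @param tol Relative convergence tolerance (default 1e-6).
#' @return Object of class `vo2_nlme`: `beta` (tidy fixed-effect table),
#'   `vcov`, `G_hat`, `sigma2`, `loglik`, `aic` (with
#'   `K = n fixed + n G parameters + 1`), `n_patients`, `converged`.
#' @export
fit_nlme <- function(data, family,
                     random_params = default_random_params(),
                     g_structure = c("diagonal", "full"),
                     start = NULL, fits = NULL,
                     max_iter = 200, tol = 1e-6) {
  family <- match_family(family)
  g_structure <- match.arg(g_structure)
  check_cohort(data, c("patient_id", "stage", "time", "vo2", "lam_max"))
  stopifnot(all(random_params %in% default_random_params()))

  dat <- data |>
    dplyr::mutate(stage_f = factor(.data$stage)) |>
    as.data.frame()
  stages <- levels(dat$stage_f)
  if (is.null(start)) start <- nlme_start_values(data, family, fits)
  start <- start[param_names(), as.character(stages), drop = FALSE]
  start_vec <- as.numeric(t(start))  # param-major, stage within param

  model_f <- nlme_model_formula(family)
  # single-level factors cannot be dummy-coded; with one stage the
  # intercept-only coding fits the same per-stage means
  fixed_rhs <- if (length(stages) > 1) "~ stage_f - 1" else "~ 1"
  fixed_f <- stats::as.formula(
    paste(paste(param_names(), collapse = " + "), fixed_rhs)
  )

  fit <- if (length(random_params) == 0) {
    params_f <- lapply(param_names(), function(p) {
      stats::as.formula(paste(p, fixed_rhs))
    })
    tryCatch(
      nlme::gnls(model_f, data = dat, params = params_f, start = start_vec,
                 control = nlme::gnlsControl(maxIter = max_iter,
                                             nlsMaxIter = 50,
                                             tolerance = tol,
                                             returnObject = FALSE)),
      error = function(e) e
    )
  } else {
    random_f <- stats::as.formula(
      paste(paste(random_params, collapse = " + "), "~ 1")
    )
    random_pd <- if (g_structure == "diagonal") {
      nlme::pdDiag(random_f)
    } else {
      nlme::pdSymm(random_f)
    }
    tryCatch(
      nlme::nlme(model_f, data = dat, fixed = fixed_f,
                 random = list(patient_id = random_pd),
                 groups = ~patient_id,
                 start = list(fixed = start_vec),
                 method = "ML",
                 control = nlme::nlmeControl(maxIter = max_iter,
                                             pnlsMaxIter = 25,
                                             msMaxIter = 200,
                                             tolerance = tol,
                                             returnObject = FALSE)),
      error = function(e) e
    )
  }

  if (inherits(fit, "error")) {
    return(structure(
      list(family = family, converged = FALSE,
           message = conditionMessage(fit),
           n_patients = dplyr::n_distinct(data$patient_id),
           random_params = random_params),
      class = "vo2_nlme"
    ))
  }

  cf <- if (inherits(fit, "gnls")) stats::coef(fit) else nlme::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  beta <- if (length(stages) > 1) {
    tibble::tibble(
      term = names(cf),
      parameter = sub("\\.stage_f.*$", "", names(cf)),
      stage = as.integer(sub("^.*\\.stage_f", "", names(cf))),
      estimate = unname(cf),
      std.error = sqrt(diag(V))
    )
  } else {
    tibble::tibble(
      term = names(cf),
      parameter = sub("\\.\\(Intercept\\)$", "", names(cf)),
      stage = as.integer(stages[1]),
      estimate = unname(cf),
      std.error = sqrt(diag(V))
    )
  }

  G_hat <- if (length(random_params) > 0) {
    # reStruct stores the covariance relative to sigma^2
    as.matrix(fit$modelStruct$reStruct[[1]]) * fit$sigma^2
  } else {
    matrix(0, 0, 0)
  }
  n_g <- if (length(random_params) == 0) 0 else if (g_structure == "diagonal") {
    length(random_params)
  } else {
    length(random_params) * (length(random_params) + 1) / 2
  }
  ll <- as.numeric(stats::logLik(fit))
  k <- length(cf) + n_g + 1

  structure(
    list(
      family = family,
      random_params = random_params,
      g_structure = if (length(random_params) > 0) g_structure else NULL,
      beta = beta, vcov = V,
      G_hat = G_hat,
      sigma2 = fit$sigma^2,
      loglik = ll, aic = -2 * ll + 2 * k, k = k,
      n_patients = dplyr::n_distinct(data$patient_id),
      n_obs = nrow(dat),
      converged = TRUE,
      fit = fit
    ),
    class = "vo2_nlme"
  )
}

#' @export
print.vo2_nlme <- function(x, ...) {
  cat("Nonlinear mixed-effects VO2 kinetics fit (", x$family, ")\n", sep = "")
  if (!isTRUE(x$converged)) {
    cat("  NOT CONVERGED:", x$message, "\n")
    return(invisible(x))
  }
  cat("  patients:", x$n_patients, " obs:", x$n_obs,
      " logLik:", round(x$loglik, 1), " AIC:", round(x$aic, 1), "\n")
  print(x$beta, n = nrow(x$beta))
  invisible(x)
}

#' @method tidy vo2_nlme
#' @export
tidy.vo2_nlme <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    return(tibble::tibble(term = character(), estimate = numeric(),
                          std.error = numeric()))
  }
  x$beta
}

#' @method glance vo2_nlme
#' @export
glance.vo2_nlme <- function(x, ...) {
  tibble::tibble(
    sigma = if (isTRUE(x$converged)) sqrt(x$sigma2) else NA_real_,
    logLik = if (isTRUE(x$converged)) x$loglik else NA_real_,
    AIC = if (isTRUE(x$converged)) x$aic else NA_real_,
    nobs = x$n_obs %||% NA_integer_,
    n.patients = x$n_patients,
    converged = isTRUE(x$converged)
  )
}

#' Per-stage estimates of one parameter from a mixed-effects fit
#'
#' Extracts the stage-specific fixed effects for `param` with Wald standard
#' errors and z-based p-values for the null of a zero mean.
#'
#' @param fit A converged [fit_nlme()] result.
#' @param param Parameter name (default `"t_half"`).
#' @return A `stage_estimates` object (see [stage_estimates()]).
#' @export
nlme_stage_estimates <- function(fit, param = "t_half") {
  stopifnot(inherits(fit, "vo2_nlme"))
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  if (!param %in% param_names()) stop("unknown parameter: ", param)
  rows <- which(fit$beta$parameter == param)
  stage_estimates(
    stage = fit$beta$stage[rows],
    estimate = fit$beta$estimate[rows],
    se = fit$beta$std.error[rows],
    vcov = fit$vcov[rows, rows, drop = FALSE],
    method = "mixed", family = fit$family, param = param,
    reference = "z"
  )
}
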