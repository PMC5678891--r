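#' @importFrom rlang .data
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

# Effective exercise onset for a (possibly aligned) series: after alignment
# every patient's exercise starts at lam_max.
series_lams <- function(data) {
  lam <- if ("lam" %in% names(data)) data$lam[1] else NULL
  lam_max <- if ("lam_max" %in% names(data)) data$lam_max[1] else lam
  if (is.null(lam_max)) stop("series carries neither lam nor lam_max")
  list(onset = lam_max, lam_max = lam_max)
}

#' Data-driven starting values for one patient
#'
#' Plateau parameters from phase means (rest bins; last 60 s of exercise;
#' last 60 s of the trace), `tau1 = 30` s, `t_half` from the first crossing
#' of the smoothed trace below the midpoint between exercise and recovery
#' plateaus (fallback 120 s), and `tau2` at +/-2 per the family's canonical
#' sign.
#'
#' @param data One patient's binned (optionally aligned) tibble with `time`,
#'   `vo2` and `lam`/`lam_max`.
#' @param family One of [vo2_families()].
#' @return A [kinetic_params()] object.
#' @export
auto_init <- function(data, family) {
  family <- match_family(family)
  lams <- series_lams(data)
  onset <- lams$onset
  t0 <- lams$lam_max + 360
  t <- data$time
  y <- data$vo2

  rest <- y[t <= onset]
  vo2_rest <- if (length(rest) > 0) mean(rest) else min(y)
  ss <- y[t > t0 - 60 & t <= t0]
  vo2_ss <- if (length(ss) > 0) mean(ss) else max(y)
  rec <- y[t > max(t) - 60]
  vo2_rec <- mean(rec)

  # smoothed post-recovery trace; first crossing of the half level
  post <- which(t > t0)
  t_half <- 120
  if (length(post) >= 3) {
    ys <- stats::filter(y[post], rep(1 / 3, 3), sides = 2)
    ys[is.na(ys)] <- y[post][is.na(ys)]
    half_level <- (vo2_ss + vo2_rec) / 2
    hit <- which(ys <= half_level)
    if (length(hit) > 0) t_half <- t[post][hit[1]] - t0
  }
  if (!is.finite(t_half) || t_half <= 0) t_half <- 120

  # keep the init inside the parameter space even for degenerate traces
  eps <- max(1, 0.01 * abs(vo2_ss))
  if (vo2_rest <= 0) vo2_rest <- eps
  if (vo2_ss <= vo2_rest) vo2_ss <- vo2_rest + eps
  if (vo2_rec >= vo2_ss) vo2_rec <- vo2_ss - eps

  kinetic_params(
    vo2_rest = vo2_rest, vo2_ss = vo2_ss, vo2_rec = vo2_rec,
    tau1 = 30, tau2 = tau2_sign(family) * 2, t_half = t_half,
    lam = onset, lam_max = lams$lam_max
  )
}

params_from_theta <- function(theta, onset, lam_max) {
  structure(
    c(as.list(theta),
      list(lam = onset, lam_max = lam_max)),
    names = c(param_names(), "lam", "lam_max"),
    class = "kinetic_params"
  )
}

rss_of <- function(theta, t, y, onset, lam_max, family) {
  p <- params_from_theta(theta, onset, lam_max)
  sum((y - vo2_curve(t, p, family))^2)
}

#' Fit one curve family to one patient's series by least squares
#'
#' Minimizes the residual sum of squares over the six free parameters
#' (`lam`/`lam_max` stay fixed) with a Levenberg-Marquardt search using the
#' analytic Jacobian from [vo2_gradient()]. On failure the search restarts
#' from up to three jittered versions of the starting values. The Gaussian
#' log-likelihood uses `sigma^2 = RSS/n`; the parameter covariance is
#' `(J'J)^-1 * RSS/(n - 6)` (small-sample bias correction), and
#' `AIC = -2 logLik + 2K` with `K = 7` (six curve parameters plus the
#' residual variance).
#'
#' @param data One patient's binned, aligned tibble: `time`, `vo2`, and
#'   `lam`/`lam_max` (plus `patient_id`, `stage` carried into the result).
#' @param family One of [vo2_families()].
#' @param init Optional [kinetic_params()] starting values; default
#'   [auto_init()].
#' @param max_restarts Jittered restarts on failure (default 3).
#' @return Object of class `vo2_fit`: estimates, standard errors, covariance,
#'   log-likelihood, AIC and an honest `converged` flag (non-convergence is
#'   reported, never silently hidden).
#' @export
fit_patient <- function(data, family, init = NULL, max_restarts = 3) {
  family <- match_family(family)
  check_cohort(data, c("time", "vo2"))
  lams <- series_lams(data)
  t <- data$time
  y <- data$vo2
  n <- length(t)
  t0 <- lams$lam_max + 360
  if (n < 10) stop("need at least 10 observations")
  if (!any(t > t0)) stop("no post-exercise data: recovery phase missing")

  if (is.null(init)) init <- auto_init(data, family)
  theta0 <- unlist(unclass(init))[param_names()]
  lower <- c(-Inf, -Inf, -Inf, 1e-6, -Inf, 1e-6)

  resid_fn <- function(theta) {
    y - vo2_curve(t, params_from_theta(theta, lams$onset, lams$lam_max), family)
  }
  jac_fn <- function(theta) {
    -vo2_gradient(t, params_from_theta(theta, lams$onset, lams$lam_max), family)
  }

  # convergence is judged from the returned info code, not from warnings
  attempt <- function(start) {
    tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = start, lower = lower,
        fn = resid_fn, jac = jac_fn,
        control = minpack.lm::nls.lm.control(
          ftol = 1e-8, ptol = 1e-10, maxiter = 500
        )
      )),
      error = function(e) NULL
    )
  }

  fit <- attempt(theta0)
  ok <- function(f) !is.null(f) && f$info %in% 1:4
  restarts <- 0
  while (!ok(fit) && restarts < max_restarts) {
    restarts <- restarts + 1
    jitter <- theta0 * stats::runif(6, 0.8, 1.2)
    jitter <- pmax(jitter, lower + 1e-6)
    fit2 <- attempt(jitter)
    if (ok(fit2) && (!ok(fit) || fit2$deviance < fit$deviance)) fit <- fit2
  }
  if (is.null(fit)) {
    return(structure(
      list(
        patient_id = if ("patient_id" %in% names(data)) data$patient_id[1] else NA,
        stage = if ("stage" %in% names(data)) data$stage[1] else NA,
        family = family, converged = FALSE, n_obs = n,
        message = "optimizer failed from all starts"
      ),
      class = "vo2_fit"
    ))
  }

  theta <- fit$par
  rss <- fit$deviance
  sigma2 <- rss / n
  loglik <- -n / 2 * (log(2 * pi) + log(sigma2) + 1)
  J <- vo2_gradient(t, params_from_theta(theta, lams$onset, lams$lam_max),
                    family)
  jtj <- crossprod(J)
  cov <- tryCatch(solve(jtj) * rss / (n - 6), error = function(e) {
    s <- svd(jtj)
    pos <- s$d > max(s$d) * 1e-12
    (s$v[, pos, drop = FALSE] %*%
       (t(s$u[, pos, drop = FALSE]) / s$d[pos])) * rss / (n - 6)
  })
  dimnames(cov) <- list(param_names(), param_names())
  se <- sqrt(pmax(diag(cov), 0))

  structure(
    list(
      patient_id = if ("patient_id" %in% names(data)) data$patient_id[1] else NA,
      stage = if ("stage" %in% names(data)) data$stage[1] else NA,
      family = family,
      estimates = params_from_theta(theta, lams$onset, lams$lam_max),
      se = se, cov = cov,
      rss = rss, sigma2 = sigma2, loglik = loglik,
      aic = -2 * loglik + 2 * 7,
      n_obs = n, n_restarts = restarts,
      converged = fit$info %in% 1:4,
      init = init
    ),
    class = "vo2_fit"
  )
}

#' @export
print.vo2_fit <- function(x, ...) {
  cat("VO2 kinetics fit (", x$family, "), patient ", x$patient_id, "\n",
      sep = "")
  if (!isTRUE(x$converged)) {
    cat("  NOT CONVERGED:", x$message %||% "see diagnostics", "\n")
    return(invisible(x))
  }
  print(tidy(x), n = 6)
  cat("  n =", x$n_obs, " logLik =", round(x$loglik, 2),
      " AIC =", round(x$aic, 2), "\n")
  invisible(x)
}

#' @method tidy vo2_fit
#' @export
tidy.vo2_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    return(tibble::tibble(term = character(), estimate = numeric(),
                          std.error = numeric()))
  }
  est <- unlist(unclass(x$estimates))[param_names()]
  tibble::tibble(term = param_names(), estimate = unname(est),
                 std.error = unname(x$se[param_names()]))
}

#' @method glance vo2_fit
#' @export
glance.vo2_fit <- function(x, ...) {
  tibble::tibble(
    sigma = if (isTRUE(x$converged)) sqrt(x$sigma2) else NA_real_,
    logLik = x$loglik %||% NA_real_,
    AIC = x$aic %||% NA_real_,
    nobs = x$n_obs,
    df.residual = x$n_obs - 6,
    converged = isTRUE(x$converged)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit every patient under one or more curve families
#'
#' The first step of the two-step summarization strategies: each patient's
#' series is fitted separately under each requested family.
#'
#' @param data Binned, aligned cohort tibble.
#' @param families Character subset of [vo2_families()].
#' @param ... Passed to [fit_patient()].
#' @return Tibble, one row per patient x family, with a `fit` list-column and
#'   unpacked `converged`, `loglik`, `aic`, `n_obs`.
#' @export
fit_cohort <- function(data, families = vo2_families(), ...) {
  check_cohort(data)
  families <- vapply(families, match_family, character(1))
  split_data <- data |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_split()
  purrr::map(split_data, function(d) {
    purrr::map(families, function(fam) {
      f <- fit_patient(d, fam, ...)
      tibble::tibble(
        patient_id = d$patient_id[1],
        stage = if ("stage" %in% names(d)) d$stage[1] else NA_integer_,
        family = fam,
        converged = isTRUE(f$converged),
        loglik = f$loglik %||% NA_real_,
        aic = f$aic %||% NA_real_,
        n_obs = f$n_obs,
        fit = list(f)
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
}

#' Long table of per-patient estimates and standard errors
#'
#' One row per patient x family x parameter; the tidy interchange format the
#' second-step summaries (and the CSV writers) consume.
#'
#' @param fits Result of [fit_cohort()].
#' @return Tibble with `patient_id`, `stage`, `family`, `term`, `estimate`,
#'   `std.error`.
#' @export
tidy_cohort_fits <- function(fits) {
  fits |>
    dplyr::mutate(coef = purrr::map(.data$fit, tidy)) |>
    dplyr::select("patient_id", "stage", "family", "coef") |>
    tidyr::unnest("coef")
}

#' Extract one parameter's per-patient estimates for pooling
#'
#' @param fits Result of [fit_cohort()] (or its [tidy_cohort_fits()] table).
#' @param family Curve family to extract.
#' @param param Focal parameter (default `"t_half"`, the recovery half-time).
#' @return Tibble `patient_id`, `stage`, `phi_hat`, `s_i` with one row per
#'   converged patient fit.
#' @export
meta_input <- function(fits, family, param = "t_half") {
  family <- match_family(family)
  tab <- if ("term" %in% names(fits)) fits else tidy_cohort_fits(fits)
  out <- tab |>
    dplyr::filter(.data$family == !!family, .data$term == param) |>
    dplyr::transmute(
      patient_id = .data$patient_id, stage = .data$stage,
      phi_hat = .data$estimate, s_i = .data$std.error
    ) |>
    dplyr::filter(is.finite(.data$phi_hat), is.finite(.data$s_i),
                  .data$s_i > 0)
  if (nrow(out) == 0) stop("no usable per-patient estimates for ", param)
  out
}
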