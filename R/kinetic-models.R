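#' Curve families for the recovery phase
#'
#' The combined exercise + recovery curve shares a mono-exponential exercise
#' rise across families; the families differ only in the shape of the
#' post-exercise recovery sigmoid:
#'
#' * `"log_logistic"` — symmetric sigmoid; at `t_half` after recovery onset
#'   exactly half the recovery decrease has occurred, irrespective of the
#'   steepness `tau2`.
#' * `"weibull_1"` — asymmetric, inflection early in recovery (steep initial
#'   drop); the fraction recovered at `t_half` is `exp(-1)`.
#' * `"weibull_2"` — asymmetric, inflection late in recovery; the fraction
#'   recovered at `t_half` is `1 - exp(-1)`.
#'
#' @return Character vector of the three family names.
#' @export
vo2_families <- function() c("log_logistic", "weibull_1", "weibull_2")

match_family <- function(family) {
  match.arg(family, vo2_families())
}

#' Canonical sign of the recovery steepness parameter
#'
#' The direction of each recovery sigmoid is set by the sign of `tau2`:
#' negative for `log_logistic` and `weibull_1`, positive for `weibull_2`.
#' These are fitting conventions (used for initialization), not hard
#' constraints.
#'
#' @param family One of [vo2_families()].
#' @return `-1` or `+1`.
#' @export
tau2_sign <- function(family) {
  family <- match_family(family)
  if (family == "weibull_2") 1 else -1
}

#' Kinetic curve parameters
#'
#' Bundles the six estimable curve parameters together with the fixed
#' resting-phase lengths. Time is in seconds and oxygen uptake in mL/min
#' throughout the package.
#'
#' @param vo2_rest Resting oxygen uptake plateau (mL/min), > 0.
#' @param vo2_ss Steady-state uptake during walking (mL/min), > `vo2_rest`.
#' @param vo2_rec Post-exercise recovery plateau (mL/min), < `vo2_ss`.
#' @param tau1 Time constant of the mono-exponential exercise rise (s), > 0.
#'   Equals the mean response time (time to ~63% of the exercise span).
#' @param tau2 Dimensionless steepness of the recovery sigmoid; sign sets the
#'   curve direction per family (see [tau2_sign()]).
#' @param t_half Scale of the recovery sigmoid, `T1/2VO2` (s), > 0. For the
#'   log-logistic family it is exactly the time after recovery onset at which
#'   half the recovery decrease is reached.
#' @param lam Individual resting-phase length \eqn{\lambda_i} (s); fixed by
#'   the experimenter, never estimated.
#' @param lam_max Cohort maximum resting length \eqn{\lambda_{max}} (s); the
#'   recovery onset is at `lam_max + 360` (the walk lasts 360 s).
#' @return An object of class `kinetic_params` (a named list).
#' @export
kinetic_params <- function(vo2_rest, vo2_ss, vo2_rec, tau1, tau2, t_half,
                           lam, lam_max = lam) {
  p <- list(
    vo2_rest = vo2_rest, vo2_ss = vo2_ss, vo2_rec = vo2_rec,
    tau1 = tau1, tau2 = tau2, t_half = t_half,
    lam = lam, lam_max = lam_max
  )
  stopifnot(
    vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
           logical(1))
  )
  if (p$vo2_rest <= 0) stop("vo2_rest must be positive")
  if (p$vo2_ss <= p$vo2_rest) stop("vo2_ss must exceed vo2_rest")
  if (p$vo2_rec >= p$vo2_ss) stop("vo2_rec must be below vo2_ss")
  if (p$tau1 <= 0) stop("tau1 must be positive")
  if (p$t_half <= 0) stop("t_half must be positive")
  if (p$lam < 0 || p$lam > p$lam_max) stop("need 0 <= lam <= lam_max")
  structure(p, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("VO2 kinetic parameters (time s, VO2 mL/min):\n")
  print(unlist(unclass(x)))
  invisible(x)
}

param_names <- function() {
  c("vo2_rest", "vo2_ss", "vo2_rec", "tau1", "tau2", "t_half")
}

check_time <- function(t) {
  if (!is.numeric(t) || anyNA(t) || any(!is.finite(t))) {
    stop("time values must be finite numbers")
  }
  invisible(t)
}

#' Mono-exponential exercise component
#'
#' Rise of oxygen uptake above rest once walking starts at `t = lam`:
#' `(vo2_ss - vo2_rest) * (1 - exp(-(t - lam)/tau1))` for `t > lam`, and 0
#' before the onset. Monotone nondecreasing; tends to the exercise span as
#' `t` grows.
#'
#' @param t Time (s), vectorized.
#' @param p A [kinetic_params()] object.
#' @return Numeric vector (mL/min).
#' @export
exercise_component <- function(t, p) {
  check_time(t)
  span <- p$vo2_ss - p$vo2_rest
  out <- numeric(length(t))
  on <- t > p$lam
  out[on] <- span * (1 - exp(-(t[on] - p$lam) / p$tau1))
  out
}

# Recovery fraction g(x; tau2) with x = (t - t0)/t_half, plus dg/dz where
# z = x^tau2. Shared by evaluation and the analytic gradient.
recovery_fraction <- function(z, family) {
  switch(family,
    log_logistic = 1 / (1 + z),
    weibull_1 = exp(-z),
    weibull_2 = 1 - exp(-z)
  )
}

recovery_fraction_dz <- function(z, family) {
  switch(family,
    log_logistic = -1 / (1 + z)^2,
    weibull_1 = -exp(-z),
    weibull_2 = exp(-z)
  )
}

#' Sigmoid recovery component
#'
#' Post-exercise decrease of oxygen uptake from the exercise steady state
#' towards the recovery plateau. Recovery onset is the cohort-aligned time
#' `t0 = lam_max + 360`; the component is 0 for `t <= t0` and
#' `(vo2_rec - vo2_ss) * g((t - t0)/t_half)` afterwards, where the fraction
#' `g` depends on the family and on `tau2` through `z = x^tau2`.
#'
#' @inheritParams exercise_component
#' @param family One of [vo2_families()].
#' @return Numeric vector (mL/min).
#' @export
recovery_component <- function(t, p, family) {
  family <- match_family(family)
  check_time(t)
  if (p$t_half <= 0) stop("t_half must be positive")
  t0 <- p$lam_max + 360
  drop_ <- p$vo2_rec - p$vo2_ss
  out <- numeric(length(t))
  on <- t > t0
  if (any(on)) {
    x <- (t[on] - t0) / p$t_half
    z <- exp(p$tau2 * log(x))
    out[on] <- drop_ * recovery_fraction(z, family)
  }
  out
}

#' Evaluate the combined exercise + recovery curve
#'
#' `vo2_rest + exercise_component + recovery_component`: the resting plateau,
#' the mono-exponential rise after walking starts, and the sigmoid decrease
#' after walking ends.
#'
#' @inheritParams recovery_component
#' @return Numeric vector of predicted oxygen uptake (mL/min).
#' @export
vo2_curve <- function(t, p, family) {
  p$vo2_rest + exercise_component(t, p) + recovery_component(t, p, family)
}

#' Analytic gradient of the curve in its six estimable parameters
#'
#' Partial derivatives of [vo2_curve()] with respect to
#' `vo2_rest, vo2_ss, vo2_rec, tau1, tau2, t_half` (in that order), needed
#' for least-squares Jacobians and Wald standard errors.
#'
#' @inheritParams recovery_component
#' @return Matrix `length(t)` x 6 with named columns.
#' @export
vo2_gradient <- function(t, p, family) {
  family <- match_family(family)
  check_time(t)
  n <- length(t)
  g <- matrix(0, n, 6, dimnames = list(NULL, param_names()))
  t0 <- p$lam_max + 360
  drop_ <- p$vo2_rec - p$vo2_ss
  span <- p$vo2_ss - p$vo2_rest

  ex_on <- t > p$lam
  u <- (t[ex_on] - p$lam) / p$tau1
  E <- 1 - exp(-u)

  g[, "vo2_rest"] <- 1
  g[ex_on, "vo2_rest"] <- 1 - E
  g[ex_on, "vo2_ss"] <- E
  g[ex_on, "tau1"] <- -span * u * exp(-u) / p$tau1

  rec_on <- t > t0
  if (any(rec_on)) {
    x <- (t[rec_on] - t0) / p$t_half
    L <- log(x)
    z <- exp(p$tau2 * L)
    frac <- recovery_fraction(z, family)
    dgdz <- recovery_fraction_dz(z, family)
    # z can overflow to Inf at extreme times; the fraction saturates there and
    # its derivative vanishes.
    dgdz[!is.finite(z)] <- 0
    zL <- z * L
    zL[!is.finite(z)] <- 0
    g[rec_on, "vo2_ss"] <- g[rec_on, "vo2_ss"] - frac
    g[rec_on, "vo2_rec"] <- frac
    g[rec_on, "tau2"] <- drop_ * dgdz * zL
    g[rec_on, "t_half"] <- -drop_ * dgdz * z * p$tau2 / p$t_half
  }
  g
}

#' Mean response time of the exercise rise
#'
#' Time after exercise onset at which the mono-exponential reaches
#' `1 - exp(-1)` (about 63%) of its span; equals `tau1`.
#'
#' @param p A [kinetic_params()] object.
#' @return Seconds.
#' @export
mean_response_time <- function(p) {
  stopifnot(p$tau1 > 0)
  p$tau1
}
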