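#' Per-stage estimates of a focal parameter
#'
#' Common container for the per-stage estimates produced by any of the three
#' summarization strategies, carrying the between-stage covariance (zero off
#' the diagonal for the two-step strategies by construction, the Wald
#' covariance for the mixed-effects strategy) and the reference distribution
#' used for p-values (`"z"` for mixed effects and meta-analysis, `"t"` with
#' `df` residual degrees of freedom for weighted regression).
#'
#' @param stage Integer vector of GOLD stages.
#' @param estimate,se Per-stage estimates and standard errors (seconds for
#'   the default focal parameter `t_half`).
#' @param vcov Covariance matrix of the stage estimates; default
#'   `diag(se^2)`.
#' @param method One of `"mixed"`, `"meta"`, `"weighted"`.
#' @param family Curve family label.
#' @param param Focal parameter name.
#' @param reference `"z"` or `"t"`.
#' @param df Degrees of freedom when `reference = "t"`.
#' @return Object of class `stage_estimates`.
#' @export
stage_estimates <- function(stage, estimate, se, vcov = NULL,
                            method, family, param = "t_half",
                            reference = c("z", "t"), df = NULL) {
  reference <- match.arg(reference)
  stopifnot(length(stage) == length(estimate),
            length(estimate) == length(se), all(se > 0))
  if (is.null(vcov)) vcov <- diag(se^2, nrow = length(se))
  stopifnot(nrow(vcov) == length(stage))
  if (reference == "t" && is.null(df)) stop("t reference needs df")
  ord <- order(stage)
  structure(
    list(
      stage = as.integer(stage)[ord], estimate = estimate[ord], se = se[ord],
      vcov = vcov[ord, ord, drop = FALSE],
      method = method, family = family, param = param,
      reference = reference, df = df
    ),
    class = "stage_estimates"
  )
}

ref_pvalue <- function(stat, reference, df = NULL) {
  if (reference == "z") {
    2 * stats::pnorm(-abs(stat))
  } else {
    2 * stats::pt(-abs(stat), df = df)
  }
}

#' @export
print.stage_estimates <- function(x, ...) {
  cat("Per-stage ", x$param, " estimates (", x$method, ", ", x$family,
      "; ", x$reference, " reference", if (!is.null(x$df)) paste0(", df = ", x$df),
      ")\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @method tidy stage_estimates
#' @export
tidy.stage_estimates <- function(x, ...) {
  tibble::tibble(
    method = x$method, family = x$family, parameter = x$param,
    stage = x$stage, estimate = x$estimate, std.error = x$se,
    p.value = ref_pvalue(x$estimate / x$se, x$reference, x$df)
  )
}

#' Contrast between two disease stages
#'
#' `Delta = theta_a - theta_b` with
#' `SE = sqrt(se_a^2 + se_b^2 - 2 cov(a, b))` and a two-sided p-value from
#' the strategy's reference distribution (normal for mixed effects and
#' meta-analysis; t with residual df for weighted regression). No
#' multiplicity adjustment.
#'
#' @param est A [stage_estimates()] object.
#' @param a,b Stages to compare (the contrast is `a - b`).
#' @return One-row tibble: `contrast`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @export
stage_contrast <- function(est, a, b) {
  stopifnot(inherits(est, "stage_estimates"))
  ia <- match(a, est$stage)
  ib <- match(b, est$stage)
  if (is.na(ia) || is.na(ib)) stop("unknown stage in contrast")
  delta <- est$estimate[ia] - est$estimate[ib]
  se <- sqrt(est$vcov[ia, ia] + est$vcov[ib, ib] - 2 * est$vcov[ia, ib])
  stat <- delta / se
  p <- if (delta == 0) 1 else ref_pvalue(stat, est$reference, est$df)
  tibble::tibble(
    method = est$method, family = est$family, parameter = est$param,
    contrast = sprintf("%d-%d", a, b),
    estimate = delta, std.error = se, statistic = stat, p.value = p
  )
}

#' All pairwise stage contrasts (4-2, 3-2, 4-3)
#'
#' @param est A [stage_estimates()] object covering stages 2, 3 and 4.
#' @param adjust P-value adjustment method (default `"none"`, matching the
#'   convention of reporting raw p-values; `"holm"` available).
#' @return Tibble with one row per contrast.
#' @export
all_contrasts <- function(est, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  pairs <- list(c(4L, 2L), c(3L, 2L), c(4L, 3L))
  out <- purrr::map(pairs, function(pr) stage_contrast(est, pr[1], pr[2])) |>
    purrr::list_rbind()
  if (adjust != "none") {
    out$p.value <- stats::p.adjust(out$p.value, method = adjust)
  }
  out
}

#' Two-sided p-value for a printed estimate/SE pair
#'
#' Convenience wrapper to recompute a Wald p-value from a reported estimate
#' and standard error under a normal or t reference.
#'
#' @param estimate,se Estimate and its standard error.
#' @param reference `"z"` or `"t"`.
#' @param df Degrees of freedom for the t reference.
#' @return P-value.
#' @export
wald_pvalue <- function(estimate, se, reference = c("z", "t"), df = NULL) {
  reference <- match.arg(reference)
  ref_pvalue(estimate / se, reference, df)
}
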