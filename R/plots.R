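#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot one patient's data with the fitted curve
#'
#' @param object A converged [fit_patient()] result.
#' @param data Optional tibble of the fitted observations (`time`, `vo2`);
#'   when omitted only the curve is drawn over the fitted time range.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot vo2_fit
#' @export
autoplot.vo2_fit <- function(object, data = NULL, ...) {
  stopifnot(isTRUE(object$converged))
  p <- object$estimates
  t0 <- p$lam_max + 360
  upper <- if (!is.null(data)) max(data$time) else t0 + 6 * p$t_half
  grid <- tibble::tibble(time = seq(0, upper, length.out = 400))
  grid$vo2 <- vo2_curve(grid$time, p, object$family)
  g <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$time, y = .data$vo2))
  if (!is.null(data)) {
    g <- g + ggplot2::geom_point(data = data, alpha = 0.5, size = 0.8)
  }
  g +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_vline(xintercept = c(p$lam_max, t0), linetype = "dotted") +
    ggplot2::labs(
      x = "aligned time (s)", y = expression(dot(V) * O[2] ~ "(mL/min)"),
      title = sprintf("Patient %s, %s fit", object$patient_id, object$family)
    ) +
    ggplot2::theme_minimal()
}

#' Dot-and-interval plot of per-stage estimates
#'
#' @param object A [stage_estimates()] object.
#' @param level Confidence level for the intervals (default 0.95, normal
#'   approximation).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot stage_estimates
#' @export
autoplot.stage_estimates <- function(object, level = 0.95, ...) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  dat <- tidy(object) |>
    dplyr::mutate(
      lo = .data$estimate - zq * .data$std.error,
      hi = .data$estimate + zq * .data$std.error,
      stage = factor(.data$stage)
    )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$stage, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi)) +
    ggplot2::labs(
      x = "GOLD stage", y = sprintf("%s (s)", object$param),
      title = sprintf("%s estimates (%s, %s)", object$param, object$method,
                      object$family)
    ) +
    ggplot2::theme_minimal()
}

#' Summary plot of a pipeline run
#'
#' Per-stage estimates of the focal parameter with normal-approximation
#' intervals, faceted by summarization method, coloured by curve family.
#'
#' @param object A [run_pipeline()] result.
#' @param level Confidence level (default 0.95).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot vo2_pipeline
#' @export
autoplot.vo2_pipeline <- function(object, level = 0.95, ...) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  dat <- object$table2 |>
    dplyr::filter(!grepl("\\(", .data$label)) |>
    dplyr::mutate(
      lo = .data$estimate - zq * .data$std.error,
      hi = .data$estimate + zq * .data$std.error
    )
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$label, y = .data$estimate,
                 colour = .data$family)
  ) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      position = ggplot2::position_dodge(width = 0.4)
    ) +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(
      x = NULL, y = sprintf("%s (s)", object$config$focal_param),
      colour = "family"
    ) +
    ggplot2::theme_minimal()
}
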