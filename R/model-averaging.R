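#' Akaike weights from information-criterion values
#'
#' `w_p = exp(-Delta_p/2) / sum_r exp(-Delta_r/2)` with
#' `Delta_p = IC_p - min(IC)`. Weights live on the probability simplex and
#' are invariant to adding a constant to every IC; a lower IC always gets a
#' strictly larger weight.
#'
#' @param ic Numeric vector of finite AIC (or other IC) values.
#' @return Numeric vector of weights summing to 1, named like `ic`.
#' @export
akaike_weights <- function(ic) {
  if (length(ic) == 0) stop("empty IC vector")
  if (!is.numeric(ic) || any(!is.finite(ic))) stop("ICs must be finite")
  delta <- ic - min(ic)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Model-averaged estimate with conservative unconditional variance
#'
#' Combines per-model estimates of a common focal quantity into
#' `theta_MA = sum_p w_p theta_p`, with the conservative (Buckland-style)
#' standard error
#' `se_MA = sum_p w_p sqrt(var_p + (theta_p - theta_MA)^2)`, which charges
#' both within-model variance and between-model spread. If any variance is
#' missing the averaged estimate is still returned with `se_ma = NA`.
#'
#' @param candidates Data frame with one row per candidate model: columns
#'   `family` (label), `ic` (information criterion), `theta` (estimate) and
#'   optionally `var` (its variance) or `se`.
#' @return One-row tibble: `weights` (list-column of named weights),
#'   `theta_ma`, `se_ma`.
#' @export
model_average <- function(candidates) {
  stopifnot(is.data.frame(candidates),
            all(c("ic", "theta") %in% names(candidates)),
            nrow(candidates) >= 2)
  if (!"var" %in% names(candidates)) {
    candidates$var <- if ("se" %in% names(candidates)) {
      candidates$se^2
    } else {
      NA_real_
    }
  }
  w <- akaike_weights(candidates$ic)
  if (!is.null(candidates$family)) names(w) <- candidates$family
  theta_ma <- sum(w * candidates$theta)
  se_ma <- if (anyNA(candidates$var)) {
    NA_real_
  } else {
    sum(w * sqrt(candidates$var + (candidates$theta - theta_ma)^2))
  }
  tibble::tibble(weights = list(w), theta_ma = theta_ma, se_ma = se_ma)
}

#' Per-subgroup AIC comparison of the curve families
#'
#' Compares the goodness of fit of the candidate families within each
#' disease-stage subgroup, for a given summarization method. Cells whose fit
#' failed (mixed-effects fits on small subgroups are expected to fail
#' sometimes) are kept as missing with the failure reason rather than
#' dropped.
#'
#' @param aic_table Tibble with columns `stage`, `family`, `aic` and
#'   optionally `reason` (for missing cells).
#' @return Tibble, one row per stage x family, with `delta_aic` within stage
#'   and a logical `best` flagging the within-stage AIC minimizer.
#' @export
subgroup_selection <- function(aic_table) {
  stopifnot(all(c("stage", "family", "aic") %in% names(aic_table)))
  group_min <- function(x) {
    if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)
  }
  aic_table |>
    dplyr::group_by(.data$stage) |>
    dplyr::mutate(
      delta_aic = .data$aic - group_min(.data$aic),
      best = !is.na(.data$aic) & .data$aic == group_min(.data$aic)
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$stage, .data$family)
}

#' Fit every family within every stage subgroup and compare AICs
#'
#' Runs one summarization method on each stage-restricted subset of the
#' cohort, for each curve family, and tabulates the resulting AICs via
#' [subgroup_selection()]. For the two-step methods the AIC is that of the
#' second-step pooling model refitted within the subgroup; for the
#' mixed-effects method it is the subgroup NLME AIC, with non-convergence
#' carried as a missing cell.
#'
#' @param data Binned, aligned cohort tibble.
#' @param method `"meta"`, `"weighted"`, or `"mixed"`.
#' @param families Families to compare.
#' @param fits Optional precomputed [fit_cohort()] result (two-step methods).
#' @param param Focal parameter for the two-step pooling.
#' @return Tibble from [subgroup_selection()].
#' @export
subgroup_aic <- function(data, method = c("meta", "weighted", "mixed"),
                         families = vo2_families(), fits = NULL,
                         param = "t_half") {
  method <- match.arg(method)
  stages <- sort(unique(data$stage))
  if (method %in% c("meta", "weighted")) {
    if (is.null(fits)) fits <- fit_cohort(data, families)
    tab <- tidy_cohort_fits(fits)
    cells <- tidyr::expand_grid(stage = stages, family = families)
    rows <- purrr::pmap(cells, function(stage, family) {
      inp <- tab |> dplyr::filter(.data$stage == !!stage)
      res <- tryCatch({
        inp <- meta_input(inp, family, param)
        f <- if (method == "meta") fit_meta(inp, family, param) else {
          fit_weighted(inp, family, param)
        }
        tibble::tibble(stage = stage, family = family, aic = f$aic,
                       reason = NA_character_)
      }, error = function(e) {
        tibble::tibble(stage = stage, family = family, aic = NA_real_,
                       reason = conditionMessage(e))
      })
      res
    })
  } else {
    cells <- tidyr::expand_grid(stage = stages, family = families)
    rows <- purrr::pmap(cells, function(stage, family) {
      sub <- data |> dplyr::filter(.data$stage == !!stage)
      f <- fit_nlme(sub, family)
      if (isTRUE(f$converged)) {
        tibble::tibble(stage = stage, family = family, aic = f$aic,
                       reason = NA_character_)
      } else {
        tibble::tibble(stage = stage, family = family, aic = NA_real_,
                       reason = f$message %||% "did not converge")
      }
    })
  }
  subgroup_selection(purrr::list_rbind(rows))
}
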