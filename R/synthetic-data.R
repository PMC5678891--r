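#' Specification of a synthetic COPD cohort
#'
#' Describes the statistical structure the analysis assumes: stage-specific
#' mean curves, Gaussian patient-level random effects on the four recovery
#' parameters (`vo2_ss`, `vo2_rec`, `tau2`, `t_half`; diagonal covariance by
#' default), i.i.d. Gaussian residual noise on each breath, per-patient
#' resting-phase lengths drawn uniformly, and jittered breath-by-breath
#' sampling times.
#'
#' @param n_per_stage Named or ordered counts for GOLD stages 2/3/4
#'   (default `c(21, 30, 10)`, a realistic severity mix for a referred
#'   COPD cohort).
#' @param family_truth Generating curve family (default `"log_logistic"`).
#' @param stage_means List of three [kinetic_params()] (stages 2, 3, 4);
#'   default [default_truth()] means. `lam`/`lam_max` fields are ignored
#'   (per-patient `lam` is drawn).
#' @param random_sd Named SDs of the patient-level random effects for
#'   `vo2_ss`, `vo2_rec`, `tau2`, `t_half`.
#' @param noise_sd Residual SD in mL/min.
#' @param lam_range Range (s) for the uniform draw of per-patient resting
#'   length.
#' @param breath_interval Range (s) of the jittered gap between breaths.
#' @param recovery_duration Recorded recovery length (s) after the 360-s walk.
#' @param seed Integer seed; every draw is reproducible given it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_stage = c(`2` = 21, `3` = 30, `4` = 10),
                        family_truth = "log_logistic",
                        stage_means = NULL,
                        random_sd = c(vo2_ss = 100, vo2_rec = 50,
                                      tau2 = 0.3, t_half = 25),
                        noise_sd = 50,
                        lam_range = c(30, 90),
                        breath_interval = c(2, 4),
                        recovery_duration = 300,
                        seed = 1L) {
  if (is.null(names(n_per_stage))) names(n_per_stage) <- c("2", "3", "4")
  stopifnot(all(n_per_stage >= 1), all(random_sd >= 0), noise_sd >= 0,
            recovery_duration > 0)
  if (is.null(stage_means)) stage_means <- default_stage_means()
  stopifnot(length(stage_means) == length(n_per_stage))
  structure(
    list(
      n_per_stage = n_per_stage,
      family_truth = match_family(family_truth),
      stage_means = stage_means,
      random_sd = random_sd[c("vo2_ss", "vo2_rec", "tau2", "t_half")],
      noise_sd = noise_sd,
      lam_range = lam_range,
      breath_interval = breath_interval,
      recovery_duration = recovery_duration,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# Plausible stage-mean parameters: recovery half-times of roughly
# 128/133/168 s across GOLD 2/3/4 and exercise capacity decreasing with
# severity. Plausible magnitudes for a COPD walking cohort, not ground truth.
default_stage_means <- function() {
  list(
    `2` = kinetic_params(vo2_rest = 300, vo2_ss = 1300, vo2_rec = 400,
                         tau1 = 30, tau2 = -2, t_half = 128, lam = 60),
    `3` = kinetic_params(vo2_rest = 300, vo2_ss = 1150, vo2_rec = 400,
                         tau1 = 30, tau2 = -2, t_half = 133, lam = 60),
    `4` = kinetic_params(vo2_rest = 300, vo2_ss = 1000, vo2_rec = 400,
                         tau1 = 30, tau2 = -2, t_half = 168, lam = 60)
  )
}

#' Default synthetic-cohort truth
#'
#' The package's reference simulation conditions: 21/30/10 patients in GOLD
#' stages 2/3/4, log-logistic truth with stage recovery half-times
#' 128/133/168 s, and heterogeneity/noise levels documented in
#' [cohort_spec()].
#'
#' @param seed Integer seed.
#' @return A `cohort_spec`.
#' @export
default_truth <- function(seed = 1L) cohort_spec(seed = seed)

draw_patient_params <- function(mean_p, random_sd, lam, max_tries = 100) {
  for (try in seq_len(max_tries)) {
    cand <- unclass(mean_p)
    for (nm in names(random_sd)) {
      cand[[nm]] <- cand[[nm]] + stats::rnorm(1, 0, random_sd[[nm]])
    }
    p <- tryCatch(
      kinetic_params(
        vo2_rest = cand$vo2_rest, vo2_ss = cand$vo2_ss,
        vo2_rec = cand$vo2_rec, tau1 = cand$tau1,
        tau2 = cand$tau2, t_half = cand$t_half,
        lam = lam, lam_max = lam
      ),
      error = function(e) NULL
    )
    if (!is.null(p)) return(p)
  }
  stop("could not draw valid patient parameters in ", max_tries, " attempts")
}

#' Generate a synthetic breath-by-breath cohort
#'
#' Per patient: draws a resting length, draws the four recovery-parameter
#' random effects (redrawing, up to 100 times, any draw that violates the
#' parameter-space constraints), lays down jittered breath times over
#' `[0, lam + 360 + recovery_duration]`, evaluates the generating curve and
#' adds i.i.d. Gaussian noise. Fully reproducible given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return List with `breaths` (tibble `patient_id`, `stage`, `lam`, `time`,
#'   `vo2`) and `truth` (one row per patient: the generating parameters).
#' @export
generate_cohort <- function(spec = default_truth()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  stages <- names(spec$n_per_stage)
  breaths <- list()
  truth <- list()
  k <- 0
  for (s in seq_along(stages)) {
    for (i in seq_len(spec$n_per_stage[[s]])) {
      k <- k + 1
      id <- sprintf("P%03d", k)
      lam <- stats::runif(1, spec$lam_range[1], spec$lam_range[2])
      p <- draw_patient_params(spec$stage_means[[s]], spec$random_sd, lam)
      total <- lam + 360 + spec$recovery_duration
      gaps <- stats::runif(
        ceiling(total / spec$breath_interval[1]) + 1,
        spec$breath_interval[1], spec$breath_interval[2]
      )
      t <- cumsum(gaps)
      t <- t[t <= total]
      vo2 <- vo2_curve(t, p, spec$family_truth) +
        stats::rnorm(length(t), 0, spec$noise_sd)
      breaths[[k]] <- tibble::tibble(
        patient_id = id, stage = as.integer(stages[s]),
        lam = lam, time = t, vo2 = vo2
      )
      truth[[k]] <- tibble::tibble(
        patient_id = id, stage = as.integer(stages[s]), lam = lam,
        !!!unclass(p)[param_names()]
      )
    }
  }
  list(
    breaths = purrr::list_rbind(breaths),
    truth = purrr::list_rbind(truth),
    spec = spec
  )
}
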