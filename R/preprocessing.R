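#' Read a long-format breath-by-breath cohort CSV
#'
#' Expected columns: `patient_id`, `stage` (GOLD 2/3/4), `lam` (resting-phase
#' length, s), `time_s`, `vo2_ml_min`. Extra columns are preserved.
#'
#' @param path CSV path.
#' @return Tibble with columns `patient_id`, `stage`, `lam`, `time`, `vo2`
#'   (plus any extras).
#' @export
read_vo2_csv <- function(path) {
  dat <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("patient_id", "stage", "lam", "time_s", "vo2_ml_min")
  missing <- setdiff(need, names(dat))
  if (length(missing) > 0) {
    stop("missing columns: ", paste(missing, collapse = ", "))
  }
  dat |>
    dplyr::rename(time = "time_s", vo2 = "vo2_ml_min") |>
    dplyr::mutate(
      patient_id = as.character(.data$patient_id),
      stage = as.integer(.data$stage)
    )
}

#' Write a cohort tibble back to the long CSV schema
#'
#' @param data Tibble with `patient_id`, `stage`, `lam`, `time`, `vo2` and
#'   optionally `bin_width`, `lam_max`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_vo2_csv <- function(data, path) {
  out <- data |>
    dplyr::rename(time_s = "time", vo2_ml_min = "vo2")
  readr::write_csv(out, path)
  invisible(path)
}

check_cohort <- function(data, cols = c("patient_id", "time", "vo2")) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    stop("missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(data) == 0) stop("no records")
  invisible(data)
}

#' Average breath-by-breath records into fixed-width bins
#'
#' Raw breath-by-breath traces are noisy; the standard preprocessing averages
#' them over consecutive non-overlapping windows (20 s by default, following
#' cardiopulmonary exercise-testing practice; 5/10/15 s are exposed for
#' sensitivity analyses). Each bin takes the arithmetic mean of the member
#' breaths' uptake and is stamped at the window midpoint; empty windows are
#' dropped. Partial first/last bins are kept if nonempty.
#'
#' @param data Tibble of breath records: `patient_id`, `time`, `vo2`, plus
#'   per-patient metadata (`stage`, `lam`) carried through.
#' @param bin_width Window width in seconds (default 20).
#' @return Tibble of binned records with a `bin_width` column, one row per
#'   patient x nonempty window, ordered by patient and time.
#' @export
bin_breaths <- function(data, bin_width = 20) {
  stopifnot(is.numeric(bin_width), length(bin_width) == 1, bin_width > 0)
  check_cohort(data)
  meta_cols <- intersect(c("stage", "lam"), names(data))
  data |>
    dplyr::mutate(.bin = floor(.data$time / bin_width)) |>
    dplyr::group_by(.data$patient_id, dplyr::across(dplyr::all_of(meta_cols)),
                    .data$.bin) |>
    dplyr::summarise(vo2 = mean(.data$vo2), .groups = "drop") |>
    dplyr::mutate(
      time = (.data$.bin + 0.5) * bin_width,
      bin_width = bin_width
    ) |>
    dplyr::select(-".bin") |>
    dplyr::relocate("time", .before = "vo2") |>
    dplyr::arrange(.data$patient_id, .data$time)
}

#' Align patients to a common recovery onset
#'
#' Individual resting phases differ in length (\eqn{\lambda_i}); shifting each
#' patient's clock by `lam_max - lam` puts exercise onset at `lam_max` and
#' recovery onset at `lam_max + 360` for everyone, so a single set of curve
#' parameters describes the cohort. A pure time translation: within-patient
#' time differences are unchanged.
#'
#' @param data Binned cohort tibble with a `lam` column.
#' @param lam_max Cohort maximum resting length; defaults to `max(lam)`.
#' @return The tibble with `time` shifted and a `lam_max` column added.
#' @export
align_to_lam_max <- function(data, lam_max = NULL) {
  check_cohort(data, c("patient_id", "time", "vo2", "lam"))
  if (anyNA(data$lam)) stop("lam missing for some records")
  if (is.null(lam_max)) lam_max <- max(data$lam)
  if (lam_max < max(data$lam)) stop("lam_max below an individual lam")
  data |>
    dplyr::mutate(
      time = .data$time + (lam_max - .data$lam),
      lam_max = lam_max
    )
}

#' Bin and align a raw cohort in one step
#'
#' @inheritParams bin_breaths
#' @inheritParams align_to_lam_max
#' @return Binned, aligned cohort tibble ready for fitting.
#' @export
preprocess_cohort <- function(data, bin_width = 20, lam_max = NULL) {
  align_to_lam_max(bin_breaths(data, bin_width = bin_width), lam_max = lam_max)
}
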