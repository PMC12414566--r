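# Clinical endpoint derivation.
#
# Endpoints are pure functions of the score series; any endpoint whose
# required visits are unobserved is "not evaluable" (NA), never
# false-by-default.  Remission windows are operationalized as "criterion
# met at both scheduled visits bounding the window" (18 and 24 months for
# symptoms, 12 and 24 months for functioning), with no interpolation.

#' Early treatment response (50% reduction by month 3)
#'
#' A subject is an early responder when the month-3 score is at most half
#' the baseline score. A zero baseline is degenerate: response is defined
#' as a month-3 score of exactly zero and flagged.
#'
#' @param data Long table (`subject_id`, `time`, `value`).
#' @param baseline_time,response_time Visit times in months (0 and 3).
#' @return Tibble with `subject_id`, `early_response` (logical, NA when a
#'   required visit is unobserved), `evaluable`, `degenerate_baseline`.
#' @export
early_response <- function(data, baseline_time = 0, response_time = 3) {
  data <- as_tibble(data)
  wide <- data |>
    dplyr::filter(.data$time %in% c(baseline_time, response_time)) |>
    dplyr::mutate(visit = ifelse(.data$time == baseline_time, "v0", "v3")) |>
    dplyr::distinct(.data$subject_id, .data$visit, .keep_all = TRUE) |>
    tidyr::pivot_wider(id_cols = "subject_id", names_from = "visit",
                       values_from = "value")
  if (!"v0" %in% names(wide)) wide$v0 <- NA_real_
  if (!"v3" %in% names(wide)) wide$v3 <- NA_real_
  all_ids <- unique(data$subject_id)
  wide <- dplyr::right_join(wide, tibble(subject_id = all_ids),
                            by = "subject_id")
  wide |>
    dplyr::mutate(
      evaluable = !is.na(.data$v0) & !is.na(.data$v3),
      degenerate_baseline = .data$evaluable & .data$v0 == 0,
      early_response = dplyr::case_when(
        !evaluable ~ NA,
        v0 == 0 ~ v3 == 0,
        TRUE ~ v3 <= 0.5 * v0)) |>
    dplyr::select("subject_id", "early_response", "evaluable",
                  "degenerate_baseline")
}

#' Sustained symptom remission (RSWG-style global-item criterion)
#'
#' Remission requires every global item at or below the severity threshold
#' at both scheduled visits spanning the sustainment window (months 18 and
#' 24 for a 6-month window on a 2-year schedule). For negative-symptom
#' scales the attention item is excluded. Missing either visit (any item)
#' renders the endpoint not evaluable.
#'
#' @param items Long item-level table: `subject_id`, `time`, `item`,
#'   `value`.
#' @param window_times The two scheduled visits bounding the window.
#' @param threshold Maximum item severity compatible with remission
#'   (global items at or below 2).
#' @param exclude_items Item names excluded from the criterion (e.g.
#'   `"attention"` for SANS).
#' @return Tibble with `subject_id`, `remission` (logical or NA),
#'   `evaluable`.
#' @export
symptom_remission <- function(items, window_times = c(18, 24), threshold = 2,
                              exclude_items = character()) {
  items <- as_tibble(items)
  stopifnot(all(c("subject_id", "time", "item", "value") %in% names(items)))
  all_ids <- unique(items$subject_id)
  use <- items |>
    dplyr::filter(.data$time %in% window_times,
                  !.data$item %in% exclude_items)
  n_items <- length(unique(use$item))
  per <- use |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      all_low = all(.data$value <= threshold),
      .groups = "drop") |>
    dplyr::mutate(
      evaluable = .data$n_cells == n_items * length(window_times),
      remission = ifelse(.data$evaluable, .data$all_low, NA))
  dplyr::left_join(tibble(subject_id = all_ids), per, by = "subject_id") |>
    dplyr::mutate(evaluable = !is.na(.data$evaluable) & .data$evaluable) |>
    dplyr::select("subject_id", "remission", "evaluable")
}

#' Functional remission (good functioning persisting over one year)
#'
#' Functioning strictly above the good-functioning cut-off (SOFAS > 60) at
#' both the month-12 and month-24 visits.
#'
#' @param data Long table (`subject_id`, `time`, `value`) of functioning
#'   scores.
#' @param window_times The two visits bounding the year (12 and 24).
#' @param cutoff Strict lower cut-off (default 60).
#' @return Tibble with `subject_id`, `functional_remission`, `evaluable`.
#' @export
functional_remission <- function(data, window_times = c(12, 24), cutoff = 60) {
  data <- as_tibble(data)
  all_ids <- unique(data$subject_id)
  per <- data |>
    dplyr::filter(.data$time %in% window_times, !is.na(.data$value)) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(n_vis = dplyr::n(),
                     all_above = all(.data$value > cutoff),
                     .groups = "drop") |>
    dplyr::mutate(evaluable = .data$n_vis == length(window_times),
                  functional_remission = ifelse(.data$evaluable,
                                                .data$all_above, NA))
  dplyr::left_join(tibble(subject_id = all_ids), per, by = "subject_id") |>
    dplyr::mutate(evaluable = !is.na(.data$evaluable) & .data$evaluable) |>
    dplyr::select("subject_id", "functional_remission", "evaluable")
}

#' Derive the full endpoint panel for a cohort
#'
#' Computes early response on positive, negative and total (sum of both,
#' where both are observed) symptoms; sustained positive/negative symptom
#' remission from global items; clinical remission (both symptom
#' remissions); functional remission; and recovery (clinical AND
#' functional remission). Logical conjunctions use three-valued logic, so
#' a definite FALSE in one component makes recovery FALSE even when the
#' other is not evaluable.
#'
#' @param saps,sans Long score tables (`subject_id`, `time`, `value`).
#' @param saps_items,sans_items Long item-level tables for the remission
#'   window visits.
#' @param sofas Long functioning table.
#' @param attention_item Name of the negative-symptom attention item
#'   excluded from remission (default `"attention"`).
#' @return A tibble with one row per subject and all endpoint flags.
#' @export
derive_endpoints <- function(saps, sans, saps_items, sans_items, sofas,
                             attention_item = "attention") {
  er_pos <- early_response(saps) |>
    dplyr::select("subject_id", early_response_pos = "early_response")
  er_neg <- early_response(sans) |>
    dplyr::select("subject_id", early_response_neg = "early_response")
  total <- dplyr::inner_join(
    as_tibble(saps) |> dplyr::select("subject_id", "time", p = "value"),
    as_tibble(sans) |> dplyr::select("subject_id", "time", n = "value"),
    by = c("subject_id", "time")) |>
    dplyr::mutate(value = .data$p + .data$n) |>
    dplyr::select("subject_id", "time", "value")
  er_tot <- early_response(total) |>
    dplyr::select("subject_id", early_response_total = "early_response")
  rem_pos <- symptom_remission(saps_items) |>
    dplyr::select("subject_id", remission_pos = "remission")
  rem_neg <- symptom_remission(sans_items, exclude_items = attention_item) |>
    dplyr::select("subject_id", remission_neg = "remission")
  fun_rem <- functional_remission(sofas) |>
    dplyr::select("subject_id", "functional_remission")
  out <- list(er_pos, er_neg, er_tot, rem_pos, rem_neg, fun_rem) |>
    purrr::reduce(dplyr::full_join, by = "subject_id")
  out |>
    dplyr::mutate(
      early_response_any = .data$early_response_pos |
        .data$early_response_neg | .data$early_response_total,
      clinical_remission = .data$remission_pos & .data$remission_neg,
      recovery = .data$clinical_remission & .data$functional_remission) |>
    dplyr::arrange(.data$subject_id)
}

#' Exclude subjects with excessive missing assessments
#'
#' Sensitivity filter removing subjects whose fraction of missing
#' scheduled visits exceeds the threshold (the ">30% missing data"
#' exclusion used for sensitivity analyses).
#'
#' @param data An [lgm_data()] table (schedule-aware).
#' @param max_missing_fraction Exclusion threshold (default 0.30,
#'   strictly-greater comparison).
#' @return A list of class `attrition_filter`: `data` (filtered, still an
#'   `lgm_data`), `excluded` (per-subject report of removed subjects) and
#'   `threshold`.
#' @export
attrition_filter <- function(data, max_missing_fraction = 0.30) {
  if (!inherits(data, "lgm_data")) data <- lgm_data(data)
  mf <- missing_fraction(data)
  excl <- dplyr::filter(mf, .data$missing_fraction > max_missing_fraction)
  kept <- dplyr::filter(data, !.data$subject_id %in% excl$subject_id)
  out_data <- lgm_data(kept, times = schedule_times(data),
                       outcome = attr(data, "outcome"),
                       range = attr(data, "range"))
  structure(list(data = out_data, excluded = excl,
                 threshold = max_missing_fraction),
            class = "attrition_filter")
}

#' @export
print.attrition_filter <- function(x, ...) {
  cat(sprintf("<attrition_filter> threshold > %.0f%% missing: %d excluded, %d retained\n",
              100 * x$threshold, nrow(x$excluded),
              length(unique(x$data$subject_id))))
  invisible(x)
}
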