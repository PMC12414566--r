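#' Read a long-format outcome CSV
#'
#' Expects a UTF-8 CSV with header columns `subject_id`, `time_months`,
#' `value` (one row per observed assessment) and validates it into an
#' [lgm_data()] table against the declared visit schedule; duplicate
#' (subject, time) rows and off-schedule times are errors naming the
#' offending rows.
#'
#' @param path File path.
#' @param times Scheduled visit times (defaults to the times present).
#' @param outcome,range Passed to [lgm_data()].
#' @return An [lgm_data()] tibble.
#' @export
read_long_csv <- function(path, times = NULL, outcome = "outcome",
                          range = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("subject_id", "time_months", "value")
  if (!all(need %in% names(df))) {
    abort(sprintf("%s must have columns %s.", path,
                  paste(need, collapse = ", ")))
  }
  if (!is.numeric(df$time_months) || !is.numeric(df$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$time_months))) |
                   is.na(suppressWarnings(as.numeric(df$value))))
    abort(sprintf("Non-numeric time/value entries at rows: %s.",
                  paste(head(bad, 5), collapse = ", ")))
  }
  dup <- which(duplicated(df[c("subject_id", "time_months")]))
  if (length(dup)) {
    abort(sprintf("Duplicate (subject, time) rows at: %s.",
                  paste(head(dup + 1L, 5), collapse = ", ")))
  }
  lgm_data(tibble(subject_id = as.character(df$subject_id),
                  time = df$time_months, value = df$value),
           times = times, outcome = outcome, range = range)
}

#' Write a long-format outcome CSV
#'
#' Inverse of [read_long_csv()]; a write-then-read round trip reproduces
#' the dataset exactly.
#'
#' @param data An [lgm_data()] table.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(data, path) {
  readr::write_csv(
    tibble(subject_id = data$subject_id, time_months = data$time,
           value = data$value),
    path)
  invisible(path)
}

#' Read a wide-format outcome CSV (one column per visit)
#'
#' Convenience reader for trajectory datasets shipped wide: a
#' `subject_id` column plus one column per scheduled visit named like
#' `m0, m1, ..., m24` (any prefix; the numeric suffix is the time in
#' months). Empty cells are missing visits.
#'
#' @param path File path.
#' @param outcome,range Passed to [lgm_data()].
#' @return An [lgm_data()] tibble.
#' @export
read_wide_csv <- function(path, outcome = "outcome", range = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"subject_id" %in% names(df)) abort("Wide CSV needs a subject_id column.")
  vcols <- setdiff(names(df), "subject_id")
  times <- suppressWarnings(as.numeric(sub("^[^0-9]*", "", vcols)))
  if (any(is.na(times))) {
    abort("Visit columns must encode the time in months (e.g. m0, m12).")
  }
  long <- tidyr::pivot_longer(df, dplyr::all_of(vcols), names_to = "col",
                              values_to = "value") |>
    dplyr::mutate(time = times[match(.data$col, vcols)]) |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::transmute(subject_id = as.character(.data$subject_id),
                     time = .data$time, value = .data$value)
  lgm_data(long, times = sort(times), outcome = outcome, range = range)
}
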