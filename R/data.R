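#' Validate a long-format longitudinal dataset
#'
#' Takes a long table of repeated outcome measurements and validates it
#' against a scheduled visit grid, making missingness explicit: every
#' (subject, scheduled visit) pair is either observed or missing.
#'
#' @param data A data frame with columns `subject_id`, `time` (months) and
#'   `value` (one row per observed assessment).
#' @param times Scheduled visit times in months. Defaults to the sorted
#'   unique times present in `data`.
#' @param outcome Name of the outcome (e.g. `"SAPS"`), carried in metadata.
#' @param range Optional numeric `c(lower, upper)` giving the valid score
#'   range; observed values outside it are an error. Symptom global-score
#'   sums are bounded below by 0; functioning scores live in `[0, 100]`.
#'
#' @return A tibble of class `lgm_data` with columns `subject_id`, `time`,
#'   `value`, and attributes `times` (the schedule) and `outcome`. Rows are
#'   observed assessments only; missing visits are implicit in the schedule.
#' @export
lgm_data <- function(data, times = NULL, outcome = "outcome", range = NULL) {
  data <- as_tibble(data)
  need <- c("subject_id", "time", "value")
  if (!all(need %in% names(data))) {
    abort("`data` needs columns subject_id, time, value.")
  }
  data <- dplyr::select(data, dplyr::all_of(need))
  data <- dplyr::filter(data, !is.na(.data$value))
  if (!is.numeric(data$time) || !is.numeric(data$value)) {
    abort("`time` and `value` must be numeric.")
  }
  if (is.null(times)) times <- sort(unique(data$time))
  times <- sort(as.numeric(times))
  off <- setdiff(unique(data$time), times)
  if (length(off)) {
    abort(paste0("Observed times off the visit schedule: ",
                 paste(off, collapse = ", ")))
  }
  dup <- data[duplicated(data[c("subject_id", "time")]), , drop = FALSE]
  if (nrow(dup)) {
    abort(paste0("Duplicate (subject, time) rows: ",
                 paste(utils::head(paste0(dup$subject_id, "@", dup$time), 5),
                       collapse = ", ")))
  }
  if (!is.null(range)) {
    bad <- data$value < range[1] | data$value > range[2]
    if (any(bad)) {
      abort(sprintf("%d values outside the valid range [%g, %g].",
                    sum(bad), range[1], range[2]))
    }
  }
  if (nrow(data) == 0L) abort("No observed assessments in `data`.")
  data <- dplyr::arrange(data, .data$subject_id, .data$time)
  structure(data,
            class = c("lgm_data", class(tibble())),
            times = times, outcome = outcome, range = range)
}

schedule_times <- function(data) attr(data, "times")

# internal wide representation: N x T value matrix with NA for missing,
# plus observation patterns grouped for likelihood work.
as_lgm_wide <- function(data, times = NULL) {
  if (inherits(data, "lgm_data")) {
    times <- times %||% schedule_times(data)
  } else {
    data <- lgm_data(data, times = times)
    times <- schedule_times(data)
  }
  ids <- unique(data$subject_id)
  N <- length(ids); T_ <- length(times)
  Y <- matrix(NA_real_, N, T_)
  ri <- match(data$subject_id, ids)
  ci <- match(data$time, times)
  Y[cbind(ri, ci)] <- data$value
  obs <- !is.na(Y)
  key <- apply(obs, 1L, function(z) paste(as.integer(z), collapse = ""))
  groups <- split(seq_len(N), key)
  patterns <- lapply(groups, function(rows) {
    idx <- which(obs[rows[1L], ])
    list(rows = rows, idx = idx)
  })
  list(Y = Y, times = times, subject_ids = ids, obs = obs,
       patterns = unname(patterns))
}

# missing fraction per subject relative to the schedule
missing_fraction <- function(data) {
  times <- schedule_times(data)
  data |>
    dplyr::count(.data$subject_id, name = "n_obs") |>
    dplyr::mutate(n_scheduled = length(times),
                  missing_fraction = 1 - .data$n_obs / .data$n_scheduled)
}
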