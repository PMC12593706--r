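#' Read a workday measurement table
#'
#' One row per participant-workday: job code, trimester status, age,
#' measured work hours and hours spent standing, walking, sitting and
#' forward bending (>= 30 degrees trunk inclination). Hours are decimal
#' floats. A `bout_id` column identifies the measurement week; if
#' absent, worker x trimester is used (each trimester status is one
#' bout).
#'
#' @param path CSV file with columns `worker_id`, `job_code`,
#'   `trimester` (NP/T2/T3), `age`, `work_hours`, `standing_h`,
#'   `walking_h`, `sitting_h`, `bending_h`, optionally `bout_id`.
#' @return data.frame of measurement days.
#' @export
read_measurements <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(worker_id = "character", job_code = "character"))
  needed <- c("worker_id", "job_code", "trimester", "age", "work_hours",
              "standing_h", "walking_h", "sitting_h", "bending_h")
  miss <- setdiff(needed, names(d))
  if (length(miss)) stop("measurement table lacks column(s): ", paste(miss, collapse = ", "))
  bad <- !(d$trimester %in% c("NP", "T2", "T3"))
  if (any(bad)) stop("unknown trimester label(s): ",
                     paste(sQuote(unique(d$trimester[bad])), collapse = ", "))
  d$job_code <- parse_code(d$job_code)
  if (is.null(d$bout_id)) d$bout_id <- paste(d$worker_id, d$trimester, sep = ":")
  d
}

#' Apply workday validity rules
#'
#' A workday is valid if it comprises at least 4 measured work hours;
#' a measurement bout (week) is valid if its remaining valid workdays
#' total at least 8 work hours. Short days are dropped first
#' (`short_day`), then all days of any bout falling under the weekly
#' minimum (`short_week`). Both thresholds are inclusive.
#'
#' @param days measurement-day data.frame (see [read_measurements()]).
#' @param min_day_hours,min_week_hours validity thresholds in hours.
#' @return list with `kept` (valid rows) and `dropped` (invalid rows
#'   plus a `reason` column, `short_day` or `short_week`).
#' @export
filter_valid_days <- function(days, min_day_hours = 4, min_week_hours = 8) {
  if (is.null(days$bout_id)) days$bout_id <- paste(days$worker_id, days$trimester, sep = ":")
  short_day <- days$work_hours < min_day_hours
  dropped <- days[short_day, , drop = FALSE]
  if (nrow(dropped)) dropped$reason <- "short_day"
  rest <- days[!short_day, , drop = FALSE]
  if (nrow(rest)) {
    key <- paste(rest$worker_id, rest$bout_id, sep = "\r")
    tot <- tapply(rest$work_hours, key, sum)
    short_week <- tot[key] < min_week_hours
    dw <- rest[short_week, , drop = FALSE]
    if (nrow(dw)) {
      dw$reason <- "short_week"
      dropped <- rbind(dropped, dw)
    }
    rest <- rest[!short_week, , drop = FALSE]
  }
  rownames(rest) <- rownames(dropped) <- NULL
  list(kept = rest, dropped = dropped)
}

.posture_cols <- c("standing_h", "walking_h", "sitting_h", "bending_h")

#' Duration-normalize workdays to 8-hour time-weighted averages
#'
#' Rescales each posture duration by `8 / work_hours` so every workday
#' is expressed as hours per standard 8-hour workday (TWA). Days must
#' already have passed [filter_valid_days()]. Rows whose posture hours
#' exceed the measured work time (beyond a 1% rounding tolerance on the
#' standing+walking+sitting sum) are a data-integrity error.
#'
#' @param days valid measurement-day data.frame.
#' @return the same data.frame with posture columns re-expressed as TWA
#'   hours per 8-hour workday.
#' @export
normalize_twa <- function(days) {
  stopifnot(all(.posture_cols %in% names(days)), all(days$work_hours > 0))
  for (cl in .posture_cols) {
    over <- days[[cl]] > days$work_hours + 1e-8
    if (any(over)) {
      stop("data integrity: ", cl, " exceeds work_hours in row(s) ",
           paste(utils::head(which(over), 5L), collapse = ", "))
    }
  }
  act <- days$standing_h + days$walking_h + days$sitting_h
  over <- act > days$work_hours * 1.01
  if (any(over)) {
    stop("data integrity: standing+walking+sitting exceeds work_hours in row(s) ",
         paste(utils::head(which(over), 5L), collapse = ", "))
  }
  f <- 8 / days$work_hours
  for (cl in .posture_cols) days[[cl]] <- days[[cl]] * f
  days
}
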