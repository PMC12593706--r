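#' Validate categorical expert ratings
#'
#' Raters score occupational time spent standing, walking and sitting on
#' a 1--5 scale (1 = very little ... 5 = almost all the time) with the
#' constraint that their own three scores sum to exactly 7; forward
#' bending is scored 0--4, where 0 means "cannot be assessed". This
#' check is report-only: it flags directly rated (integer) triples whose
#' sum is not 7 and bending scores outside 0..4. Fractional scores
#' (produced by hierarchy imputation) are exempt from the sum rule.
#'
#' @param ratings long data.frame with columns `group_id`, `rater_id`,
#'   `exposure` (standing/walking/sitting/bending), `category`.
#' @return data.frame of violations (`group_id`, `rater_id`, `rule`,
#'   `detail`); zero rows when all ratings are consistent.
#' @export
validate_ratings <- function(ratings) {
  stopifnot(all(c("group_id", "rater_id", "exposure", "category") %in% names(ratings)))
  viol <- list()
  trio <- ratings[ratings$exposure %in% c("standing", "walking", "sitting"), ]
  if (nrow(trio)) {
    key <- interaction(trio$group_id, trio$rater_id, drop = TRUE)
    for (k in levels(key)) {
      sl <- trio[key == k, ]
      if (nrow(sl) != 3L || anyNA(sl$category)) next
      if (any(sl$category != round(sl$category))) next  # imputed, exempt
      if (sum(sl$category) != 7) {
        viol[[length(viol) + 1L]] <- data.frame(
          group_id = sl$group_id[1L], rater_id = sl$rater_id[1L],
          rule = "sum_to_7", detail = sprintf("sum = %g", sum(sl$category)))
      }
    }
  }
  bend <- ratings[ratings$exposure == "bending" & !is.na(ratings$category), ]
  bad <- !(bend$category %in% 0:4) & bend$category == round(bend$category)
  bad <- bad | bend$category < 0 | bend$category > 4
  if (any(bad)) {
    b <- bend[bad, ]
    viol[[length(viol) + 1L]] <- data.frame(
      group_id = b$group_id, rater_id = b$rater_id,
      rule = "bending_range", detail = sprintf("category = %g", b$category))
  }
  if (!length(viol)) {
    return(data.frame(group_id = character(), rater_id = character(),
                      rule = character(), detail = character()))
  }
  out <- do.call(rbind, viol)
  rownames(out) <- NULL
  out
}

#' Consensus category per occupational group
#'
#' Benchmark groups are rated jointly by the panel until consensus; such
#' a rating is carried in the table under `rater_id == "consensus"` and
#' is returned verbatim. For all other groups the available raters'
#' scores are pooled (0 / "cannot be assessed" excluded) by mean or
#' median. Groups where every rater abstained propagate as `NA`, to be
#' resolved by hierarchy imputation.
#'
#' @inheritParams validate_ratings
#' @param rule pooling rule, `"mean"` (default) or `"median"`.
#' @return data.frame `group_id`, `exposure`, `category`.
#' @export
consensus_category <- function(ratings, rule = c("mean", "median")) {
  rule <- match.arg(rule)
  pool <- if (rule == "mean") mean else stats::median
  r <- ratings
  r$category[r$category == 0] <- NA_real_
  key <- interaction(r$group_id, r$exposure, drop = TRUE)
  rows <- !duplicated(key)
  out <- data.frame(group_id = r$group_id[rows], exposure = r$exposure[rows],
                    stringsAsFactors = FALSE)
  out$category <- vapply(which(rows), function(i) {
    sl <- r[key == key[i], ]
    cons <- sl$category[sl$rater_id == "consensus"]
    if (length(cons)) return(cons[1L])
    v <- sl$category[!is.na(sl$category)]
    if (!length(v)) NA_real_ else pool(v)
  }, numeric(1))
  out[order(out$group_id, out$exposure), , drop = FALSE]
}

#' Calibrate expert categories to hours per 8-hour workday
#'
#' Fits an ordinary least-squares line of per-job mean measured TWA
#' hours on the job's consensus category score, one model per exposure.
#' Job-level means (not workdays) enter the fit so that a job's weight
#' does not depend on its measurement volume. Predictions from the line
#' are clipped to the physical range 0--8 hours.
#'
#' @param job_hours numeric: mean measured TWA hours for each measured
#'   job (one value per code).
#' @param job_category numeric: the matching consensus category scores
#'   (fractional values from imputation are allowed).
#' @param exposure exposure name the model is for.
#' @return object of class `jem_calibration` with elements `exposure`,
#'   `slope`, `intercept`, `n_jobs_fit`, `r_squared`.
#' @export
fit_calibration <- function(job_hours, job_category, exposure = "standing") {
  ok <- !is.na(job_hours) & !is.na(job_category)
  job_hours <- job_hours[ok]; job_category <- job_category[ok]
  if (length(job_hours) < 3L) {
    stop("calibration for ", exposure, " needs >= 3 jobs with both measured hours and a category")
  }
  if (stats::var(job_category) == 0) {
    stop("calibration for ", exposure, " is degenerate: all category scores equal")
  }
  fit <- stats::lm(job_hours ~ job_category)
  structure(list(exposure = exposure,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 n_jobs_fit = length(job_hours),
                 r_squared = suppressWarnings(summary(fit)$r.squared)),
            class = "jem_calibration")
}

#' @export
print.jem_calibration <- function(x, ...) {
  cat(sprintf("Expert calibration [%s]: hours = %.3f + %.3f x category (n = %d jobs, R^2 = %.2f)\n",
              x$exposure, x$intercept, x$slope, x$n_jobs_fit, x$r_squared))
  invisible(x)
}

#' @rdname fit_calibration
#' @param object a `jem_calibration` model.
#' @param category category scores to convert.
#' @param ... unused.
#' @return `predict()`: hours per 8-hour workday, clipped to \[0, 8\].
#' @export
predict.jem_calibration <- function(object, category, ...) {
  pmin(pmax(object$intercept + object$slope * category, 0), 8)
}

#' Convert imputed categories into quantitative model covariates
#'
#' Applies the calibration line per exposure and attaches the model
#' covariate: the calibrated hours themselves, except for walking where
#' the square root of the hours is used (experts systematically
#' over-estimate walking time relative to measurements, and the square
#' root restores an approximately linear relation).
#'
#' @param categories data.frame `code`, `exposure`, `category`
#'   (consensus, post-imputation).
#' @param models named list of `jem_calibration` objects keyed by
#'   exposure.
#' @return data.frame `code`, `exposure`, `hours`, `covariate`.
#' @export
quantify_ratings <- function(categories, models) {
  stopifnot(all(c("code", "exposure", "category") %in% names(categories)))
  out <- categories[, c("code", "exposure")]
  out$hours <- NA_real_
  for (e in unique(categories$exposure)) {
    m <- models[[e]]
    if (is.null(m)) stop("no calibration model for exposure ", sQuote(e))
    idx <- categories$exposure == e
    out$hours[idx] <- predict(m, categories$category[idx])
  }
  out$covariate <- ifelse(out$exposure == "walking", sqrt(out$hours), out$hours)
  out
}

#' Inter-rater agreement (intraclass correlation)
#'
#' Agreement between raters over occupational groups, computed from the
#' two-way ANOVA mean squares of a complete groups x raters score
#' matrix. The default is the two-way random-effects, absolute-
#' agreement, single-rater form ICC(2,1), which treats the rater panel
#' as a sample from a population of raters; ICC(3,1) (consistency,
#' raters fixed) is available as an alternative.
#'
#' @param scores numeric matrix, rows = groups, columns = raters, no
#'   missing cells (impute or drop incomplete groups first).
#' @param type `"ICC2"` (absolute agreement, default) or `"ICC3"`
#'   (consistency).
#' @return single ICC value in \[-1, 1\], or `NA` with a warning when
#'   total variance is zero.
#' @export
icc_agreement <- function(scores, type = c("ICC2", "ICC3")) {
  type <- match.arg(type)
  scores <- as.matrix(scores)
  if (anyNA(scores)) stop("ICC requires a complete matrix; impute or drop incomplete groups")
  n <- nrow(scores); k <- ncol(scores)
  if (n < 2L || k < 2L) stop("ICC requires >= 2 groups and >= 2 raters")
  g <- mean(scores)
  rowm <- rowMeans(scores); colm <- colMeans(scores)
  ss_total <- sum((scores - g)^2)
  if (ss_total == 0) {
    warning("zero total variance: ICC undefined")
    return(NA_real_)
  }
  ss_rows <- k * sum((rowm - g)^2)
  ss_cols <- n * sum((colm - g)^2)
  ms_rows <- ss_rows / (n - 1)
  ms_cols <- ss_cols / (k - 1)
  ms_err <- (ss_total - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  if (type == "ICC2") {
    (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err + k * (ms_cols - ms_err) / n)
  } else {
    (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err)
  }
}
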