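#' Round half away from zero
#'
#' Display rounding for percentage tables: exact halves round up in
#' magnitude (base R's `round()` rounds half to even).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  trunc(x * f + 0.5 * sign(x)) / f
}

#' Percentage shares of variance components
#'
#' Expresses the between-job, between-worker and within-worker variances
#' as percentages of their total.
#'
#' @param components numeric length 3: variances `(job, worker, resid)`.
#' @return list with `raw` (exact percentages) and `rounded` (half-up to
#'   integers, the table display convention).
#' @export
variance_shares <- function(components) {
  stopifnot(length(components) == 3L, all(components >= 0))
  total <- sum(components)
  if (total <= 0) stop("total variance is zero: shares undefined")
  raw <- 100 * components / total
  list(raw = raw, rounded = round_half_up(raw))
}

#' Percentage reduction of a variance component relative to the null model
#'
#' @param null_value component variance under the null model.
#' @param model_value the same component under a richer model.
#' @return list with `raw` and `rounded` percentage reduction; negative
#'   when the component increased.
#' @export
variance_reduction <- function(null_value, model_value) {
  stopifnot(null_value > 0)
  raw <- 100 * (null_value - model_value) / null_value
  list(raw = raw, rounded = round_half_up(raw))
}

#' Variance-component comparison across nested models
#'
#' Builds the null / covariate / final model comparison for one
#' exposure: component variances, their percentage shares within each
#' model, and percentage reductions relative to the null model
#' (computed from unrounded components; the integer columns are display
#' rounding only). All fits must be on the identical row set.
#'
#' @param fits named list of `jem_fit` objects; the first element is the
#'   null model the others are compared against (conventionally
#'   `null`, `model1`, `final`).
#' @param exposure exposure label for the output.
#' @return data.frame of class `jem_variance_table` with columns
#'   `exposure`, `model`, `component`, `variance`, `share_pct`,
#'   `reduction_pct`, `share_raw`, `reduction_raw`; components are
#'   `between_jobs`, `between_workers`, `within_worker` and `total`.
#' @export
build_variance_table <- function(fits, exposure = fits[[1L]]$exposure) {
  stopifnot(is.list(fits), length(fits) >= 2L, !is.null(names(fits)))
  n_obs <- vapply(fits, function(f) f$n_obs %||% NA_real_, numeric(1))
  cks <- vapply(fits, function(f) f$response_checksum %||% NA_real_, numeric(1))
  if (!all(is.na(n_obs)) &&
      (length(unique(stats::na.omit(n_obs))) > 1L ||
       max(abs(cks - cks[1L]), na.rm = TRUE) > 1e-6)) {
    stop("models were not fitted on the identical row set; comparison invalid")
  }
  comp_of <- function(f) c(between_jobs = f$sigma2_job,
                           between_workers = f$sigma2_worker,
                           within_worker = f$sigma2_resid)
  null_c <- comp_of(fits[[1L]])
  rows <- lapply(names(fits), function(nm) {
    cc <- comp_of(fits[[nm]])
    sh <- variance_shares(cc)
    red <- 100 * (c(null_c, total = sum(null_c)) - c(cc, total = sum(cc))) /
      c(null_c, total = sum(null_c))
    data.frame(exposure = exposure, model = nm,
               component = c(names(cc), "total"),
               variance = c(unname(cc), sum(cc)),
               share_pct = c(sh$rounded, 100),
               reduction_pct = round_half_up(unname(red)),
               share_raw = c(sh$raw, 100),
               reduction_raw = unname(red),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$reduction_pct[out$model == names(fits)[1L]] <- NA_real_
  out$reduction_raw[out$model == names(fits)[1L]] <- NA_real_
  rownames(out) <- NULL
  class(out) <- c("jem_variance_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
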