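#' Pipeline configuration
#'
#' Validated configuration for an end-to-end JEM build. Every enum
#' field is checked at construction and the configuration is echoed
#' into the run log, so a run is fully described by its inputs plus
#' this object.
#'
#' @param exposures exposures to model and emit.
#' @param consensus_rule rater pooling rule, `"mean"` or `"median"`.
#' @param icc_type `"ICC2"` (absolute agreement) or `"ICC3"`
#'   (consistency).
#' @param pregnancy_convention single-entry convention for
#'   non-trimester-specific exposures: `"reference"` or `"weighted"`.
#' @param reference_age `"auto"` (mean age of the fitted data) or a
#'   number in years.
#' @param trimester_specific exposures emitted per trimester status.
#' @param seed integer seed for any simulated inputs.
#' @param output_dir where [run_build()] writes its CSV outputs.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(exposures = c("standing", "walking", "bending"),
                            consensus_rule = c("mean", "median"),
                            icc_type = c("ICC2", "ICC3"),
                            pregnancy_convention = c("reference", "weighted"),
                            reference_age = "auto",
                            trimester_specific = "standing",
                            seed = 1L,
                            output_dir = "results") {
  consensus_rule <- match.arg(consensus_rule)
  icc_type <- match.arg(icc_type)
  pregnancy_convention <- match.arg(pregnancy_convention)
  stopifnot(identical(reference_age, "auto") || is.numeric(reference_age),
            all(exposures %in% c("standing", "walking", "sitting", "bending")))
  structure(list(exposures = exposures, consensus_rule = consensus_rule,
                 icc_type = icc_type, pregnancy_convention = pregnancy_convention,
                 reference_age = reference_age,
                 trimester_specific = trimester_specific,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

#' Write a synthetic cohort to pipeline input files
#'
#' Wraps [generate_cohort()] and writes the measurement, rating,
#' grouping and code-universe tables as CSV plus the ground truth as a
#' JSON sidecar.
#'
#' @param truth a [synthetic_truth()].
#' @param dir output directory (created if needed).
#' @return invisibly, the file paths written.
#' @export
run_simulate <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(truth)
  paths <- c(measurements = file.path(dir, "measurements.csv"),
             ratings = file.path(dir, "ratings.csv"),
             grouping = file.path(dir, "grouping.csv"),
             universe = file.path(dir, "universe.csv"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(cohort$measurements, paths["measurements"], row.names = FALSE)
  utils::write.csv(cohort$ratings, paths["ratings"], row.names = FALSE)
  utils::write.csv(cohort$grouping, paths["grouping"], row.names = FALSE)
  utils::write.csv(cohort$universe, paths["universe"], row.names = FALSE)
  echo <- unclass(cohort$truth_echo)
  echo$trimester_mix <- as.list(echo$trimester_mix)
  echo$expert_hours <- as.list(echo$expert_hours)
  echo$u_j <- as.list(echo$u_j)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(echo, paths["truth"], auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}

#' Run the full JEM construction pipeline
#'
#' Executes, per exposure: workday validation, TWA normalization,
#' consensus and hierarchy imputation of expert categories, category
#' calibration, the null / model 1 (age + trimester) / final (+ expert)
#' REML fits, variance decomposition, and JEM assembly. Writes the
#' variance-component table, the fixed-effect table, the JEM, the ICC
#' summary, the calibration report and a structured run log to
#' `config$output_dir`.
#'
#' @param measurements,ratings,grouping,universe input data.frames (see
#'   the module readers), or paths to the corresponding CSV files.
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `fits`, `variance_tables`, `jem`,
#'   `icc`, `calibrations`, `log`.
#' @export
run_build <- function(measurements, ratings, grouping, universe,
                      config = pipeline_config()) {
  if (is.character(measurements)) measurements <- read_measurements(measurements)
  if (is.character(ratings)) ratings <- utils::read.csv(ratings, stringsAsFactors = FALSE,
                                                        colClasses = c(group_id = "character"))
  if (is.character(grouping)) grouping <- utils::read.csv(grouping, stringsAsFactors = FALSE,
                                                          colClasses = "character")
  if (is.character(universe)) universe <- utils::read.csv(universe, stringsAsFactors = FALSE,
                                                          colClasses = c(code = "character"))
  codes <- parse_code(universe$code)
  log <- list()
  note <- function(stage, event, count) {
    log[[length(log) + 1L]] <<- data.frame(stage = stage, event = event, count = count)
  }

  filt <- filter_valid_days(measurements)
  note("filter", "kept_days", nrow(filt$kept))
  for (r in c("short_day", "short_week")) {
    note("filter", paste0("dropped_", r), sum(filt$dropped$reason == r))
  }
  if (!nrow(filt$kept)) stop("stage filter: no valid workdays remain")
  days <- normalize_twa(filt$kept)

  viol <- validate_ratings(ratings)
  note("ratings", "violations", nrow(viol))
  cons <- consensus_category(ratings, rule = config$consensus_rule)
  # group-level consensus -> per-code categories over the universe
  cons_rt <- data.frame(group_id = cons$group_id, rater_id = "consensus",
                        exposure = cons$exposure, category = cons$category)
  cons_rt <- cons_rt[!is.na(cons_rt$category), ]
  imp <- impute_ratings(cons_rt, codes, grouping)
  note("impute", "codes_covered", length(unique(imp$code)))

  # inter-rater agreement per exposure on complete rater triples
  icc <- lapply(stats::setNames(nm = unique(ratings$exposure)), function(e) {
    sl <- ratings[ratings$exposure == e & ratings$rater_id != "consensus", ]
    sl$category[sl$category == 0] <- NA_real_
    m <- tapply(sl$category, list(sl$group_id, sl$rater_id), mean)
    m <- m[stats::complete.cases(m), , drop = FALSE]
    if (nrow(m) < 2L) return(NA_real_)
    icc_agreement(m, type = config$icc_type)
  })

  fits <- list(); vtabs <- list(); jems <- list(); calibs <- list()
  for (e in config$exposures) {
    resp <- paste0(e, "_h")
    job_mean <- tapply(days[[resp]], days$job_code, mean)
    cat_e <- imp[imp$exposure == e, ]
    cat_by_code <- stats::setNames(cat_e$category, cat_e$code)
    measured_codes <- names(job_mean)
    calib <- fit_calibration(as.numeric(job_mean),
                             as.numeric(cat_by_code[measured_codes]), exposure = e)
    calibs[[e]] <- calib
    quant <- quantify_ratings(
      data.frame(code = cat_e$code, exposure = e, category = cat_e$category),
      stats::setNames(list(calib), e))
    d <- days
    qcov <- stats::setNames(quant$covariate, quant$code)
    d$expert_cov <- unname(qcov[d$job_code])

    fit_null <- fit_exposure_model(d, e, fixed_terms = character(0))
    fit_m1 <- fit_exposure_model(d, e, fixed_terms = c("age", "trimester"))
    fit_fin <- fit_exposure_model(d, e)
    note(e, "final_converged", as.integer(fit_fin$converged))
    fits[[e]] <- list(null = fit_null, model1 = fit_m1, final = fit_fin)
    vtabs[[e]] <- build_variance_table(fits[[e]], exposure = e)

    ref_age <- if (identical(config$reference_age, "auto")) fit_fin$mean_age else config$reference_age
    jems[[e]] <- build_jem(fit_fin, quant, codes, reference_age = ref_age,
                           trimester_specific = e %in% config$trimester_specific,
                           pregnancy_convention = config$pregnancy_convention)
    note(e, "jem_measured_rows", sum(jems[[e]]$provenance == "measured"))
  }

  log_df <- do.call(rbind, log)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vt_all <- do.call(rbind, vtabs); rownames(vt_all) <- NULL
  jem_all <- do.call(rbind, lapply(jems, as.data.frame)); rownames(jem_all) <- NULL
  fe_all <- do.call(rbind, lapply(names(fits), function(e)
    cbind(exposure = e, fixed_effect_table(list(final = fits[[e]]$final)))))
  calib_df <- do.call(rbind, lapply(calibs, function(cm)
    data.frame(exposure = cm$exposure, slope = cm$slope, intercept = cm$intercept,
               n_jobs_fit = cm$n_jobs_fit, r_squared = cm$r_squared)))
  rownames(calib_df) <- NULL
  utils::write.csv(vt_all, file.path(out_dir, "variance_components.csv"), row.names = FALSE)
  utils::write.csv(fe_all, file.path(out_dir, "fixed_effects.csv"), row.names = FALSE)
  utils::write.csv(jem_all, file.path(out_dir, "jem.csv"), row.names = FALSE)
  utils::write.csv(calib_df, file.path(out_dir, "calibration.csv"), row.names = FALSE)
  utils::write.csv(data.frame(exposure = names(icc), icc = unlist(icc),
                              type = config$icc_type),
                   file.path(out_dir, "icc.csv"), row.names = FALSE)
  utils::write.csv(log_df, file.path(out_dir, "run_log.csv"), row.names = FALSE)

  invisible(list(fits = fits, variance_tables = vtabs, jem = jems, icc = icc,
                 calibrations = calibs, log = log_df))
}
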