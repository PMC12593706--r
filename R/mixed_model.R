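#' Linear mixed-effects exposure model
#'
#' The exposure model for one posture decomposes a worker's
#' duration-normalized workday exposure \eqn{y_{jwd}} (hours per 8-hour
#' workday, job j, worker w, day d) as
#' \deqn{y_{jwd} = \beta_0 + \beta_E E_j + \beta_A age_w + \beta_{T2} T2 +
#'   \beta_{T3} T3 + u_j + v_w + \epsilon_{jwd}}
#' with job and worker random intercepts \eqn{u_j \sim N(0,\sigma^2_{job})},
#' \eqn{v_w \sim N(0,\sigma^2_{worker})} (workers nested in jobs; worker
#' labels are globally unique so nested and crossed coding coincide) and
#' residual day-to-day variation \eqn{\epsilon \sim N(0,\sigma^2_{resid})}.
#' \eqn{E_j} is the calibrated expert covariate (hours; for walking, the
#' square root of the hours), trimester contrasts are against the
#' non-pregnant reference. Estimation is by REML via [lme4::lmer()]; age
#' is centred at the sample mean for conditioning and the intercept is
#' reported back on the original age scale.
#'
#' @param data data.frame with the response column plus `expert_cov`,
#'   `age`, `trimester` (NP/T2/T3), `job_code`, `worker_id` as required
#'   by `fixed_terms` / `random`.
#' @param exposure exposure name (used for labeling and the default
#'   response column `<exposure>_h`).
#' @param fixed_terms subset of `c("expert", "age", "trimester")`; the
#'   intercept is always included. The null model is `character(0)`.
#' @param random subset of `c("job", "worker")` random intercepts.
#' @param response response column name.
#' @return object of class `jem_fit`; see [jem_fit()] for its contents,
#'   plus `reml_criterion` (-2 REML log-likelihood), `converged`,
#'   `n_obs`, `trimester_shares` and the underlying lme4 fit in
#'   `engine`.
#' @export
fit_exposure_model <- function(data, exposure = "standing",
                               fixed_terms = c("expert", "age", "trimester"),
                               random = c("job", "worker"),
                               response = paste0(exposure, "_h")) {
  stopifnot(response %in% names(data), length(random) >= 1L,
            all(fixed_terms %in% c("expert", "age", "trimester")),
            all(random %in% c("job", "worker")))
  d <- data
  d$.y <- d[[response]]
  if (anyNA(d$.y)) stop("missing response values in ", response)

  mean_age <- NA_real_
  rhs <- character(0)
  if ("expert" %in% fixed_terms) {
    if (is.null(d$expert_cov)) stop("fixed term 'expert' requires an expert_cov column")
    rhs <- c(rhs, "expert_cov")
  }
  if ("age" %in% fixed_terms) {
    mean_age <- mean(d$age)
    d$.age_c <- d$age - mean_age
    rhs <- c(rhs, ".age_c")
  }
  if ("trimester" %in% fixed_terms) {
    levs <- intersect(c("NP", "T2", "T3"), unique(d$trimester))
    if (length(levs) < 2L) {
      warning("trimester has a single level in the data; dropping the trimester term")
      fixed_terms <- setdiff(fixed_terms, "trimester")
    } else {
      if (length(levs) < 3L) {
        warning("trimester reduced to ", length(levs), " levels (",
                paste(levs, collapse = ", "), ")")
      }
      d$trimester <- factor(d$trimester, levels = levs)
      rhs <- c(rhs, "trimester")
    }
  }
  fixed_rhs <- if (length(rhs)) paste(rhs, collapse = " + ") else "1"

  X <- stats::model.matrix(stats::as.formula(paste("~", fixed_rhs)), d)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("singular fixed-effect design; collinear term(s): ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]], collapse = ", "))
  }

  rparts <- c(job = "(1 | job_code)", worker = "(1 | worker_id)")[random]
  form <- stats::as.formula(paste(".y ~", fixed_rhs, "+", paste(rparts, collapse = " + ")))

  msgs <- character(0)
  fit <- withCallingHandlers(
    lme4::lmer(form, data = d, REML = TRUE,
               control = lme4::lmerControl(optimizer = "bobyqa",
                                           optCtrl = list(rhobeg = 0.2, rhoend = 2e-10),
                                           check.conv.singular = "ignore")),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  converged <- !any(grepl("converge", msgs, ignore.case = TRUE))
  if (!converged) warning("mixed-model fit did not converge cleanly: ",
                          paste(msgs, collapse = "; "))

  vc <- lme4::VarCorr(fit)
  sigma2_job <- if ("job" %in% random) unname(attr(vc$job_code, "stddev")^2) else NA_real_
  sigma2_worker <- if ("worker" %in% random) unname(attr(vc$worker_id, "stddev")^2) else NA_real_
  sigma2_resid <- stats::sigma(fit)^2

  fe <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  est <- unname(fe); se <- sqrt(diag(V)); nm <- names(fe)
  # intercept back to the original age scale: b0 - bA * mean(age)
  if (".age_c" %in% nm) {
    i0 <- which(nm == "(Intercept)"); ia <- which(nm == ".age_c")
    est[i0] <- est[i0] - fe[[ia]] * mean_age
    se[i0] <- sqrt(V[i0, i0] + mean_age^2 * V[ia, ia] - 2 * mean_age * V[i0, ia])
  }
  term <- nm
  term[term == "(Intercept)"] <- "intercept"
  term[term == "expert_cov"] <- "expert"
  term[term == ".age_c"] <- "age"
  term <- sub("^trimester", "", term)
  z <- stats::qnorm(0.975)
  beta <- data.frame(term = term, estimate = est, se = se,
                     ci_low = est - z * se, ci_high = est + z * se,
                     stringsAsFactors = FALSE)

  re <- lme4::ranef(fit)
  blup_job <- if ("job" %in% random) stats::setNames(re$job_code[[1L]], rownames(re$job_code)) else NULL
  blup_worker <- if ("worker" %in% random) stats::setNames(re$worker_id[[1L]], rownames(re$worker_id)) else NULL

  out <- jem_fit(beta = beta,
                 sigma2 = c(job = sigma2_job, worker = sigma2_worker, resid = sigma2_resid),
                 blup_job = blup_job, blup_worker = blup_worker,
                 exposure = exposure, mean_age = mean_age, converged = converged)
  out$reml_criterion <- lme4::REMLcrit(fit)
  out$n_obs <- nrow(d)
  out$response_checksum <- sum(d$.y)
  out$trimester_shares <- if (!is.null(d$trimester)) {
    prop.table(table(as.character(d$trimester)))
  } else NULL
  out$fixed_terms <- fixed_terms
  out$engine <- fit
  out
}

#' Construct an exposure-model fit object
#'
#' Assembles a `jem_fit` from known coefficients — normally called by
#' [fit_exposure_model()], but also usable directly to build a JEM from
#' published model parameters (fixed effects, variance components and
#' job BLUPs) without refitting.
#'
#' @param beta data.frame with columns `term` (among `intercept`,
#'   `expert`, `age`, `T2`, `T3`), `estimate`, and optionally `se`,
#'   `ci_low`, `ci_high`; or a named numeric vector of estimates.
#' @param sigma2 named numeric: variance components `job`, `worker`,
#'   `resid` (hours squared).
#' @param blup_job named numeric of job random-effect predictions
#'   (hours), keyed by occupation code; `NULL` when absent.
#' @param blup_worker named numeric of worker random-effect predictions.
#' @param exposure exposure name.
#' @param mean_age the age the intercept refers to via centring
#'   book-keeping (`NA` when age is not in the model).
#' @param converged logical convergence flag.
#' @return object of class `jem_fit`.
#' @export
jem_fit <- function(beta, sigma2, blup_job = NULL, blup_worker = NULL,
                    exposure = "standing", mean_age = NA_real_, converged = TRUE) {
  if (is.numeric(beta)) {
    beta <- data.frame(term = names(beta), estimate = unname(beta),
                       se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                       stringsAsFactors = FALSE)
  }
  stopifnot(all(c("term", "estimate") %in% names(beta)),
            "intercept" %in% beta$term,
            all(sigma2 >= 0, na.rm = TRUE))
  structure(list(beta = beta,
                 sigma2_job = unname(sigma2["job"]),
                 sigma2_worker = unname(sigma2["worker"]),
                 sigma2_resid = unname(sigma2["resid"]),
                 blup_job = blup_job, blup_worker = blup_worker,
                 exposure = exposure, mean_age = mean_age,
                 converged = converged),
            class = "jem_fit")
}

#' @export
print.jem_fit <- function(x, ...) {
  cat(sprintf("Exposure model [%s]: %d fixed terms, REML\n", x$exposure, nrow(x$beta)))
  b <- x$beta
  b[-1L] <- lapply(b[-1L], round, 3)
  print(b, row.names = FALSE)
  cat(sprintf("Variance components (hours^2): between-job %.3f | between-worker %.3f | within-worker %.3f\n",
              x$sigma2_job, x$sigma2_worker, x$sigma2_resid))
  if (!is.null(x$blup_job)) cat(sprintf("BLUPs for %d measured jobs\n", length(x$blup_job)))
  invisible(x)
}

.beta_of <- function(fit, term, default = NA_real_) {
  i <- match(term, fit$beta$term)
  if (is.na(i)) default else fit$beta$estimate[i]
}

#' Job random-effect prediction (BLUP)
#'
#' The best linear unbiased prediction of a measured job's random
#' intercept: the conditional mean of \eqn{u_j} given the data, which
#' shrinks the job's raw mean deviation toward zero by a factor that
#' grows with the number of measurements for the job.
#'
#' @param fit a `jem_fit`.
#' @param code occupation code with measurements in the fitted data.
#' @return the BLUP \eqn{u_j} in hours.
#' @export
blup <- function(fit, code) {
  stopifnot(inherits(fit, "jem_fit"))
  if (is.null(fit$blup_job) || !(code %in% names(fit$blup_job))) {
    stop("code ", sQuote(code), " is not in the fitted data; ",
         "use the expert-only prediction route for unmeasured jobs")
  }
  unname(fit$blup_job[code])
}

#' Predict exposure hours for a covariate profile
#'
#' Evaluates the fixed-effect prediction \eqn{X\beta} at the given
#' expert covariate, age and trimester, adding the job BLUP when a
#' measured code is supplied. Jobs without measurements get the pure
#' model-driven expert-based prediction (`code = NULL`).
#'
#' @param fit a `jem_fit`.
#' @param expert_cov expert covariate value(s) (hours; sqrt-hours for
#'   walking).
#' @param age age in years (ignored if age is not in the model).
#' @param trimester one of `"NP"`, `"T2"`, `"T3"`.
#' @param code optional occupation code whose BLUP to add; must be
#'   measured.
#' @param clip clip the prediction to \[0, 8\] (JEM emission only; off
#'   by default).
#' @return predicted hours per 8-hour workday.
#' @export
predict_exposure <- function(fit, expert_cov = 0, age = fit$mean_age,
                             trimester = "NP", code = NULL, clip = FALSE) {
  stopifnot(inherits(fit, "jem_fit"), length(trimester) == 1L)
  if (!trimester %in% c("NP", "T2", "T3")) {
    stop("unknown trimester label ", sQuote(trimester))
  }
  eta <- .beta_of(fit, "intercept")
  eta <- eta + .beta_of(fit, "expert", 0) * expert_cov
  bA <- .beta_of(fit, "age", 0)
  if (bA != 0 || "age" %in% fit$beta$term) {
    if (is.na(age)) stop("age required for prediction from an age-adjusted model")
    eta <- eta + .beta_of(fit, "age", 0) * age
  }
  if (trimester != "NP") {
    bt <- .beta_of(fit, trimester)
    if (is.na(bt)) {
      if (trimester %in% c("T2", "T3") && any(c("T2", "T3") %in% fit$beta$term)) {
        stop("trimester level ", sQuote(trimester), " was not estimable in this fit")
      }
      bt <- 0
    }
    eta <- eta + bt
  }
  if (!is.null(code)) eta <- eta + blup(fit, code)
  if (clip) eta <- pmin(pmax(eta, 0), 8)
  eta
}

#' Export the fixed-effect table of one or more fits
#'
#' @param fits named list of `jem_fit` objects (names = exposure or
#'   model labels).
#' @return data.frame `model`, `term`, `estimate`, `se`, `ci_low`,
#'   `ci_high`.
#' @export
fixed_effect_table <- function(fits) {
  if (inherits(fits, "jem_fit")) fits <- stats::setNames(list(fits), fits$exposure)
  out <- do.call(rbind, lapply(names(fits), function(nm) {
    cbind(model = nm, fits[[nm]]$beta)
  }))
  rownames(out) <- NULL
  out
}
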