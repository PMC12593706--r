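#' Assemble a job exposure matrix over the full code universe
#'
#' Every code receives the fixed-effect model prediction at its expert
#' covariate and the reference age; codes with measurements additionally
#' receive their job BLUP (provenance `measured`), codes without are
#' purely model-driven expert-based entries (provenance `expert_only`).
#' Trimester-specific exposures (standing) are emitted per trimester
#' status (NP/T2/T3); pregnancy-specific exposures (walking, bending)
#' are emitted once, by default at the non-pregnant reference level
#' (their fitted trimester contrasts are small), optionally as the
#' measurement-share-weighted average over trimesters. Entries are
#' clipped to the physical range 0--8 hours at emission.
#'
#' @param fit a converged `jem_fit`.
#' @param quantified data.frame `code`, `exposure`, `hours`, `covariate`
#'   from [quantify_ratings()], covering the universe.
#' @param universe character vector of codes the JEM must cover.
#' @param reference_age age (years) at which entries are predicted;
#'   default the mean age of the fitted data.
#' @param trimester_specific emit one entry per trimester status
#'   (default: only for standing).
#' @param pregnancy_convention for non-trimester-specific exposures:
#'   `"reference"` (non-pregnant level, default) or `"weighted"`
#'   (average over trimesters weighted by measurement shares).
#' @return data.frame of class `jem_table`: `code`, `exposure`,
#'   `trimester` (NP/T2/T3 or ALL), `hours_per_8h`, `provenance`;
#'   deterministic (code, trimester) row order; `reference_age` and a
#'   clipping indicator as attributes.
#' @export
build_jem <- function(fit, quantified, universe,
                      reference_age = fit$mean_age,
                      trimester_specific = identical(fit$exposure, "standing"),
                      pregnancy_convention = c("reference", "weighted")) {
  pregnancy_convention <- match.arg(pregnancy_convention)
  stopifnot(inherits(fit, "jem_fit"))
  if (!isTRUE(fit$converged)) stop("refusing to build a JEM from a non-converged fit")
  universe <- parse_code(universe)
  q <- quantified[quantified$exposure == fit$exposure, ]
  cov <- stats::setNames(q$covariate, q$code)
  missing_codes <- setdiff(universe, names(cov))
  if (length(missing_codes)) {
    stop("unresolvable code(s): no quantified rating for ",
         paste(sQuote(utils::head(sort(missing_codes), 10L)), collapse = ", "))
  }
  measured <- if (is.null(fit$blup_job)) rep(FALSE, length(universe)) else universe %in% names(fit$blup_job)
  uj <- rep(0, length(universe))
  if (any(measured)) uj[measured] <- unname(fit$blup_job[universe[measured]])

  pred_trim <- function(trim) {
    vapply(seq_along(universe), function(i) {
      predict_exposure(fit, expert_cov = cov[[universe[i]]], age = reference_age,
                       trimester = trim, clip = FALSE)
    }, numeric(1)) + uj
  }

  if (trimester_specific) {
    trims <- c("NP", "T2", "T3")
    if (any(c("T2", "T3") %in% fit$beta$term)) {
      estimable <- c("NP", intersect(c("T2", "T3"), fit$beta$term))
      if (length(estimable) < 3L) {
        warning("trimester level(s) ", paste(setdiff(trims, estimable), collapse = ", "),
                " not estimable in this fit; emitting ", paste(estimable, collapse = ", "))
        trims <- estimable
      }
    }
    rows <- lapply(trims, function(tr) {
      data.frame(code = universe, exposure = fit$exposure, trimester = tr,
                 hours_per_8h = pred_trim(tr),
                 provenance = ifelse(measured, "measured", "expert_only"),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  } else {
    val <- if (pregnancy_convention == "reference") {
      pred_trim("NP")
    } else {
      w <- fit$trimester_shares
      if (is.null(w)) stop("weighted convention needs trimester shares from a fitted model")
      Reduce(`+`, lapply(names(w), function(tr) w[[tr]] * pred_trim(tr)))
    }
    out <- data.frame(code = universe, exposure = fit$exposure, trimester = "ALL",
                      hours_per_8h = val,
                      provenance = ifelse(measured, "measured", "expert_only"),
                      stringsAsFactors = FALSE)
  }
  clipped <- out$hours_per_8h < 0 | out$hours_per_8h > 8
  out$hours_per_8h <- pmin(pmax(out$hours_per_8h, 0), 8)
  out <- out[order(out$code, out$exposure, out$trimester), ]
  rownames(out) <- NULL
  attr(out, "reference_age") <- reference_age
  attr(out, "n_clipped") <- sum(clipped)
  class(out) <- c("jem_table", "data.frame")
  out
}

# per-code ranking value: standing entries are ranked by the
# non-pregnant column, pregnancy-specific ones by their single entry
.jem_values <- function(jem, exposure) {
  sl <- jem[jem$exposure == exposure, , drop = FALSE]
  if (!nrow(sl)) stop("no JEM rows for exposure ", sQuote(exposure))
  ref <- if (any(sl$trimester == "NP")) "NP" else "ALL"
  sl <- sl[sl$trimester == ref, , drop = FALSE]
  stats::setNames(sl$hours_per_8h, sl$code)
}

#' Highest- and lowest-exposed jobs
#'
#' @param jem a `jem_table`.
#' @param exposure exposure to rank (standing ranked by its non-pregnant
#'   entry).
#' @param k how many jobs at each end.
#' @return list with data.frames `top` and `bottom` (`code`, `hours_per_8h`),
#'   ties broken by lexicographic code order.
#' @export
jem_extremes <- function(jem, exposure, k = 3L) {
  stopifnot(k >= 1L)
  v <- .jem_values(jem, exposure)
  if (k > length(v)) {
    warning("k exceeds the number of codes; truncating to ", length(v))
    k <- length(v)
  }
  ord_desc <- order(-v, names(v))
  ord_asc <- order(v, names(v))
  mk <- function(ord) data.frame(code = names(v)[ord], hours_per_8h = unname(v[ord]),
                                 stringsAsFactors = FALSE)
  list(top = mk(ord_desc[seq_len(k)]), bottom = mk(ord_asc[seq_len(k)]))
}

#' Max/min exposure ratio across jobs
#'
#' The fold difference between the highest- and lowest-exposed job for
#' an exposure (standing compared at the non-pregnant level).
#'
#' @inheritParams jem_extremes
#' @return the ratio (Inf with a warning when the minimum entry is 0).
#' @export
fold_ratio <- function(jem, exposure) {
  v <- .jem_values(jem, exposure)
  if (min(v) == 0) {
    warning("minimum JEM entry is 0: fold ratio infinite")
    return(Inf)
  }
  max(v) / min(v)
}

#' Aggregate a six-digit JEM to the four-digit level
#'
#' Unweighted mean of six-digit entries within each four-digit prefix
#' (no employment weights are assumed), per exposure and trimester.
#'
#' @param jem a `jem_table` of six-digit codes.
#' @return `jem_table` keyed by four-digit codes; provenance is
#'   `measured` when any member code was measured.
#' @export
jem_level4 <- function(jem) {
  stopifnot(inherits(jem, "jem_table"))
  code4 <- substr(jem$code, 1L, 4L)
  key <- paste(code4, jem$exposure, jem$trimester, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(code = code4[first], exposure = jem$exposure[first],
                    trimester = jem$trimester[first],
                    hours_per_8h = as.numeric(tapply(jem$hours_per_8h, key, mean)[key[first]]),
                    provenance = as.character(
                      tapply(jem$provenance == "measured", key, any)[key[first]]),
                    stringsAsFactors = FALSE)
  out$provenance <- ifelse(out$provenance == "TRUE", "measured", "expert_only")
  out <- out[order(out$code, out$exposure, out$trimester), ]
  rownames(out) <- NULL
  attr(out, "reference_age") <- attr(jem, "reference_age")
  class(out) <- c("jem_table", "data.frame")
  out
}

#' @export
print.jem_table <- function(x, ...) {
  cat(sprintf("JEM: %d entries, %d codes, exposure(s) %s; reference age %.1f\n",
              nrow(x), length(unique(x$code)),
              paste(unique(x$exposure), collapse = ", "),
              attr(x, "reference_age")))
  print(utils::head(as.data.frame(x), 6L), row.names = FALSE)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
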