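#' Ground truth for a synthetic measurement cohort
#'
#' Collects the generating parameters of the synthetic cohort: the
#' fixed effects and variance components of the standing exposure
#' model, the design sizes, and the rater noise. Defaults are the
#' final-model standing estimates (slope per expert-rated hour 0.472,
#' age -0.021 h/year, trimester contrasts -0.203 / -0.380 h, intercept
#' 2.228 h; variances 0.67 / 0.45 / 0.60 hours squared). The expert-hours
#' spread across jobs defaults to Uniform(0.5, 6.5) h (variance 3.0),
#' chosen so the implied null-model between-job variance
#' \eqn{\beta_E^2 \cdot 3 + \sigma^2_{job} \approx 1.33} and its 56%
#' share of total variance match the study-scale estimates.
#'
#' @param beta0,beta_expert,beta_age,beta_t2,beta_t3 fixed effects
#'   (hours; age per year, trimester contrasts vs non-pregnant).
#' @param sigma2_job,sigma2_worker,sigma2_resid variance components
#'   (hours squared).
#' @param n_jobs measured job codes.
#' @param workers_per_job,days_per_worker design sizes.
#' @param trimester_mix named proportions of worker bouts in NP/T2/T3
#'   (must sum to 1). Ignored when `paired_bouts = TRUE` except for the
#'   NP share.
#' @param paired_bouts if `TRUE`, non-NP workers are measured in both
#'   the 2nd and 3rd trimester (cohort-style repeat design); `NP` share
#'   of `trimester_mix` sets the proportion of non-pregnant workers.
#' @param n_unmeasured_codes extra codes in the universe without
#'   measurements (rated only).
#' @param rater_sd rater noise on the category scale.
#' @param p_cannot_assess probability a rater marks bending 0.
#' @param expert_hours_range range of true expert standing hours across
#'   jobs.
#' @param seed RNG seed (integer).
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(beta0 = 2.228, beta_expert = 0.472, beta_age = -0.021,
                            beta_t2 = -0.203, beta_t3 = -0.380,
                            sigma2_job = 0.67, sigma2_worker = 0.45, sigma2_resid = 0.60,
                            n_jobs = 120L, workers_per_job = 3L, days_per_worker = 5L,
                            trimester_mix = c(NP = 1/3, T2 = 1/3, T3 = 1/3),
                            paired_bouts = FALSE,
                            n_unmeasured_codes = 60L,
                            rater_sd = 0.5, p_cannot_assess = 0.02,
                            expert_hours_range = c(0.5, 6.5),
                            seed = 1L) {
  stopifnot(sigma2_job >= 0, sigma2_worker >= 0, sigma2_resid >= 0,
            n_jobs >= 2L, workers_per_job >= 1L, days_per_worker >= 1L,
            abs(sum(trimester_mix) - 1) < 1e-8,
            all(names(trimester_mix) == c("NP", "T2", "T3")),
            rater_sd >= 0, n_unmeasured_codes >= 0L)
  structure(as.list(environment()), class = "synthetic_truth")
}

# truncated-normal draws via inverse CDF (keeps the stream one draw per value)
.rtnorm <- function(n, mean, sd, lo, hi) {
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

# Category for true exposure hours given per-exposure cut-points.
# Standing/sitting use quintiles of the 8-hour day; walking a 2-hour
# span (experts over-rate walking); bending its minute-band scale.
.exposure_cuts <- list(
  standing = c(1.6, 3.2, 4.8, 6.4),
  sitting  = c(1.6, 3.2, 4.8, 6.4),
  walking  = c(0.4, 0.8, 1.2, 1.6),
  bending  = c(0.25, 0.5, 1.0)       # 0-15, 16-30, 31-60, >60 minutes
)

.discretize <- function(hours, exposure) {
  findInterval(hours, .exposure_cuts[[exposure]]) + 1L
}

# integer triple in 1..5 summing to 7, nearest to the real triple
.sum_to_7 <- function(x) {
  x <- pmax(x, 1e-6)
  x <- x * 7 / sum(x)
  f <- floor(x)
  rem <- 7 - sum(f)
  ord <- order(x - f, decreasing = TRUE)
  f[ord[seq_len(rem)]] <- f[ord[seq_len(rem)]] + 1
  f <- pmin(pmax(f, 1), 5)
  while (sum(f) > 7) { i <- which.max(f); f[i] <- f[i] - 1 }
  while (sum(f) < 7) { i <- which.min(f); f[i] <- f[i] + 1 }
  as.integer(pmin(pmax(f, 1), 5))
}

#' Generate a synthetic measurement cohort with recorded ground truth
#'
#' Draws a cohort with the exposure model's statistical structure: job
#' random effects, worker random effects nested in jobs, day-to-day
#' residuals, ages ~ Normal(31, 4) truncated to 18--45, work hours ~
#' Normal(7.1, 1.5) truncated to 4--12, and per-worker trimester status.
#' The standing response is assembled on the TWA scale from the model
#' and converted back to raw measured hours via the day's work time, so
#' duration normalization recovers it exactly. Walking, sitting and
#' bending columns are filled with physically consistent companion
#' values. Three raters score every occupational group (a small
#' benchmark subset carries a panel-consensus rating instead) by
#' discretizing the group's true expert hours plus rater noise, with
#' standing/walking/sitting scores renormalized to sum to 7.
#'
#' RNG streams are split per component (job effects, workers, days,
#' ratings) so that, e.g., changing the rater panel does not perturb the
#' measured responses.
#'
#' @param truth a [synthetic_truth()] object.
#' @return list with `measurements`, `ratings`, `grouping`, `universe`
#'   (data.frames matching the pipeline CSV schemas) and `truth_echo`:
#'   the truth parameters plus per-code true expert hours and realized
#'   job effects.
#' @export
generate_cohort <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(truth$seed)
  streams <- sample.int(2147483646L, 5L)  # job, worker, day, rating, spare

  n_un <- truth$n_unmeasured_codes
  prefixes <- sprintf("%04d", 1000L + seq_len(truth$n_jobs + max(0L, n_un - truth$n_jobs)) - 1L)
  measured_codes <- paste0(prefixes[seq_len(truth$n_jobs)], "10")
  unmeasured_codes <- character(0)
  if (n_un > 0L) {
    sib <- paste0(prefixes[seq_len(min(n_un, truth$n_jobs))], "20")
    extra <- if (n_un > truth$n_jobs) {
      paste0(prefixes[truth$n_jobs + seq_len(n_un - truth$n_jobs)], "10")
    } else character(0)
    unmeasured_codes <- c(sib, extra)
  }
  universe <- sort(c(measured_codes, unmeasured_codes))

  # job stream: true expert hours for every code, job effects for measured codes
  set.seed(streams[1L])
  expert_hours <- stats::setNames(
    stats::runif(length(universe), truth$expert_hours_range[1L], truth$expert_hours_range[2L]),
    universe)
  u_j <- stats::setNames(stats::rnorm(length(measured_codes), 0, sqrt(truth$sigma2_job)),
                         measured_codes)

  # worker stream: ages, worker effects, trimester status
  set.seed(streams[2L])
  n_workers <- truth$n_jobs * truth$workers_per_job
  worker_id <- sprintf("W%05d", seq_len(n_workers))
  worker_job <- rep(measured_codes, each = truth$workers_per_job)
  age <- round(.rtnorm(n_workers, 31, 4, 18, 45), 1)
  v_w <- stats::rnorm(n_workers, 0, sqrt(truth$sigma2_worker))
  status <- if (truth$paired_bouts) {
    ifelse(stats::runif(n_workers) < truth$trimester_mix[["NP"]], "NP", "PREG")
  } else {
    sample(c("NP", "T2", "T3"), n_workers, replace = TRUE, prob = truth$trimester_mix)
  }
  bouts <- lapply(seq_len(n_workers), function(w) {
    tr <- if (status[w] == "PREG") c("T2", "T3") else status[w]
    data.frame(widx = w, trimester = tr, stringsAsFactors = FALSE)
  })
  bouts <- do.call(rbind, bouts)

  # day stream: work hours and residuals
  set.seed(streams[3L])
  n_days <- nrow(bouts) * truth$days_per_worker
  day <- bouts[rep(seq_len(nrow(bouts)), each = truth$days_per_worker), , drop = FALSE]
  work_hours <- round(.rtnorm(n_days, 7.1, 1.5, 4, 12), 2)
  eps <- stats::rnorm(n_days, 0, sqrt(truth$sigma2_resid))
  walk_eps <- stats::rnorm(n_days, 0, 0.08)
  bend_eps <- stats::rnorm(n_days, 0, 0.05)
  sit_slack <- stats::runif(n_days, 0.85, 0.97)

  w <- day$widx
  E <- unname(expert_hours[worker_job[w]])
  bt <- ifelse(day$trimester == "T2", truth$beta_t2,
               ifelse(day$trimester == "T3", truth$beta_t3, 0))
  y <- truth$beta0 + truth$beta_expert * E + truth$beta_age * age[w] + bt +
    unname(u_j[worker_job[w]]) + v_w[w] + eps
  y <- pmin(pmax(y, 0), 8)                      # physical bounds of a TWA day
  walk <- pmin(pmax(0.25 + 0.12 * E + walk_eps, 0.02), 1.9, pmax(8 - y - 0.05, 0.02))
  bend <- pmin(pmax(0.08 + 0.10 * E + bend_eps, 0.01), 1.6)
  sit <- pmax(8 - y - walk, 0) * sit_slack

  f <- work_hours / 8
  measurements <- data.frame(
    worker_id = worker_id[w],
    job_code = worker_job[w],
    trimester = day$trimester,
    bout_id = paste(worker_id[w], day$trimester, sep = ":"),
    age = age[w],
    work_hours = work_hours,
    standing_h = y * f,
    walking_h = walk * f,
    sitting_h = sit * f,
    bending_h = bend * f,
    stringsAsFactors = FALSE)

  # rating stream: groups, benchmark consensus, three raters
  set.seed(streams[4L])
  grp <- .assign_groups(universe, measured_codes)
  ratings <- .rate_groups(grp, expert_hours, truth)

  truth_echo <- truth
  truth_echo$expert_hours <- expert_hours
  truth_echo$u_j <- u_j
  truth_echo$measured_codes <- measured_codes

  list(measurements = measurements,
       ratings = ratings,
       grouping = grp$grouping,
       universe = data.frame(code = universe,
                             label = paste("synthetic occupation", universe),
                             stringsAsFactors = FALSE),
       truth_echo = truth_echo)
}

# Grouping strategy over the synthetic universe: the first 30% of
# measured codes are rated at their 4-digit group together with any
# sibling; most remaining codes are their own (6-digit) group; 10% of
# unmeasured sibling codes are left out of any group so hierarchy
# imputation is exercised.
.assign_groups <- function(universe, measured_codes) {
  pref4 <- substr(universe, 1L, 4L)
  measured_pref <- substr(measured_codes, 1L, 4L)
  n_l4 <- max(1L, floor(length(measured_codes) * 0.3))
  l4_prefixes <- measured_pref[seq_len(n_l4)]
  rows <- list()
  ungrouped <- character(0)
  for (i in seq_along(universe)) {
    code <- universe[i]
    if (pref4[i] %in% l4_prefixes) {
      rows[[length(rows) + 1L]] <- data.frame(group_id = pref4[i], code = code,
                                              stringsAsFactors = FALSE)
    } else if (!(code %in% measured_codes) && (i %% 10L == 0L)) {
      ungrouped <- c(ungrouped, code)      # resolved only via the hierarchy
    } else {
      rows[[length(rows) + 1L]] <- data.frame(group_id = code, code = code,
                                              stringsAsFactors = FALSE)
    }
  }
  grouping <- do.call(rbind, rows)
  list(grouping = grouping, group_ids = unique(grouping$group_id), ungrouped = ungrouped)
}

.rate_groups <- function(grp, expert_hours, truth) {
  gids <- grp$group_ids
  n_bench <- max(1L, floor(0.09 * length(gids)))
  bench <- gids[seq_len(n_bench)]
  exposures <- c("standing", "walking", "sitting", "bending")
  out <- vector("list", length(gids))
  for (gi in seq_along(gids)) {
    g <- gids[gi]
    members <- grp$grouping$code[grp$grouping$group_id == g]
    E <- mean(expert_hours[members])
    true_h <- c(standing = E,
                walking = 0.25 + 0.12 * E,
                sitting = max(8 - E - (0.25 + 0.12 * E), 0.3) * 0.91,
                bending = 0.08 + 0.10 * E)
    if (g %in% bench) {
      tri <- .sum_to_7(vapply(c("standing", "walking", "sitting"), function(e)
        .discretize(true_h[[e]], e), numeric(1)))
      cats <- c(tri, .discretize(true_h[["bending"]], "bending"))
      out[[gi]] <- data.frame(group_id = g, rater_id = "consensus",
                              exposure = exposures, category = as.numeric(cats),
                              expects_reduction = E > 4,
                              stringsAsFactors = FALSE)
    } else {
      per_rater <- lapply(c("R1", "R2", "R3"), function(r) {
        raw <- vapply(c("standing", "walking", "sitting"), function(e)
          .discretize(true_h[[e]], e) + stats::rnorm(1L, 0, truth$rater_sd), numeric(1))
        tri <- .sum_to_7(raw)
        bcat <- .discretize(true_h[["bending"]], "bending") +
          round(stats::rnorm(1L, 0, truth$rater_sd))
        bcat <- min(max(bcat, 1L), 4L)
        if (stats::runif(1L) < truth$p_cannot_assess) bcat <- 0L
        data.frame(group_id = g, rater_id = r, exposure = exposures,
                   category = as.numeric(c(tri, bcat)),
                   expects_reduction = E > 4, stringsAsFactors = FALSE)
      })
      out[[gi]] <- do.call(rbind, per_rater)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Thin third-trimester bouts at random
#'
#' Emulates pregnancy-related drop-out: each worker's third-trimester
#' bout is independently retained with the given probability; all other
#' rows are untouched.
#'
#' @param measurements measurement-day data.frame.
#' @param t3_retention retention probability in (0, 1].
#' @param seed RNG seed for the drop-out draw.
#' @return the thinned measurement table.
#' @export
generate_dropout <- function(measurements, t3_retention, seed = 1L) {
  stopifnot(t3_retention > 0, t3_retention <= 1)
  if (t3_retention == 1) return(measurements)
  set.seed(seed)
  t3_bouts <- unique(measurements$bout_id[measurements$trimester == "T3"])
  keep <- t3_bouts[stats::runif(length(t3_bouts)) < t3_retention]
  out <- measurements[measurements$trimester != "T3" | measurements$bout_id %in% keep, ]
  rownames(out) <- NULL
  out
}
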