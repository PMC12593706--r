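test_that("generation is deterministic in the seed and sensitive to it", {
  tr <- synthetic_truth(n_jobs = 10L, seed = 5L)
  a <- generate_cohort(tr)
  b <- generate_cohort(tr)
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$ratings, b$ratings)
  tr2 <- tr; tr2$seed <- 6L
  expect_false(identical(generate_cohort(tr2)$measurements$standing_h,
                         a$measurements$standing_h))
})

test_that("RNG streams are split: the rater panel does not perturb responses", {
  tr <- synthetic_truth(n_jobs = 10L, seed = 5L)
  a <- generate_cohort(tr)
  tr2 <- tr; tr2$rater_sd <- 1.5
  b <- generate_cohort(tr2)
  expect_identical(a$measurements, b$measurements)
  expect_false(identical(a$ratings$category, b$ratings$category))
})

test_that("the degenerate limit returns the fixed-effect surface exactly", {
  tr <- synthetic_truth(sigma2_job = 0, sigma2_worker = 0, sigma2_resid = 0,
                        beta_age = 0, beta_t2 = 0, beta_t3 = 0,
                        n_jobs = 8L, seed = 2L)
  co <- generate_cohort(tr)
  d <- normalize_twa(co$measurements)
  E <- co$truth_echo$expert_hours[d$job_code]
  expect_equal(d$standing_h, unname(tr$beta0 + tr$beta_expert * E), tolerance = 1e-10)
})

test_that("design sizes and schemas match the pipeline contract", {
  tr <- synthetic_truth(n_jobs = 12L, workers_per_job = 2L, days_per_worker = 3L,
                        n_unmeasured_codes = 5L, seed = 8L)
  co <- generate_cohort(tr)
  expect_equal(nrow(co$measurements), 12 * 2 * 3)     # jobs x workers x days, one bout
  expect_equal(length(unique(co$measurements$worker_id)), 24)
  expect_equal(nrow(co$universe), 17)
  expect_named(co$measurements,
               c("worker_id", "job_code", "trimester", "bout_id", "age",
                 "work_hours", "standing_h", "walking_h", "sitting_h", "bending_h"))
  expect_named(co$ratings,
               c("group_id", "rater_id", "exposure", "category", "expects_reduction"))
  expect_true(all(co$measurements$work_hours >= 4 & co$measurements$work_hours <= 12))
  expect_true(all(co$measurements$age >= 18 & co$measurements$age <= 45))
  expect_true(all(co$measurements$trimester %in% c("NP", "T2", "T3")))
  # every posture within the measured day
  for (cl in c("standing_h", "walking_h", "sitting_h", "bending_h")) {
    expect_true(all(co$measurements[[cl]] <= co$measurements$work_hours + 1e-9))
  }
})

test_that("rater categories satisfy the scale constraints", {
  co <- generate_cohort(synthetic_truth(n_jobs = 30L, seed = 13L))
  r <- co$ratings
  sws <- r[r$exposure %in% c("standing", "walking", "sitting"), ]
  sums <- tapply(sws$category, paste(sws$group_id, sws$rater_id), sum)
  expect_true(all(sums == 7))
  expect_true(all(sws$category >= 1 & sws$category <= 5))
  bend <- r$category[r$exposure == "bending"]
  expect_true(all(bend %in% 0:4))
  expect_true(any(r$rater_id == "consensus"))          # benchmark groups
  expect_true(all(table(r$group_id[r$rater_id != "consensus"],
                        r$rater_id[r$rater_id != "consensus"]) > 0))
})

test_that("simulated job means spread as the analytic between-job variance predicts", {
  tr <- synthetic_truth(n_jobs = 500L, workers_per_job = 2L, days_per_worker = 3L,
                        n_unmeasured_codes = 0L, seed = 21L)
  co <- generate_cohort(tr)
  d <- normalize_twa(co$measurements)
  jm <- tapply(d$standing_h, d$job_code, mean)
  # between-job variance of job means: beta_E^2 var(E) + s2_job plus the
  # design inflation from averaging worker effects and residuals
  infl <- tr$sigma2_worker / 2 + tr$sigma2_resid / 6
  expected <- tr$beta_expert^2 * (6^2 / 12) + tr$sigma2_job + infl
  expect_equal(unname(stats::var(jm)), expected, tolerance = 0.12)
})

test_that("third-trimester dropout thins bouts at the binomial rate", {
  tr <- synthetic_truth(n_jobs = 400L, workers_per_job = 1L, days_per_worker = 2L,
                        paired_bouts = TRUE, trimester_mix = c(NP = 0.2, T2 = 0.4, T3 = 0.4),
                        n_unmeasured_codes = 0L, seed = 31L)
  co <- generate_cohort(tr)
  m <- co$measurements
  n_t3 <- length(unique(m$bout_id[m$trimester == "T3"]))
  out <- generate_dropout(m, t3_retention = 0.5, seed = 99L)
  kept <- length(unique(out$bout_id[out$trimester == "T3"]))
  # binomial 99% bounds around 0.5 retention
  bounds <- qbinom(c(0.005, 0.995), n_t3, 0.5)
  expect_gte(kept, bounds[1]); expect_lte(kept, bounds[2])
  expect_identical(generate_dropout(m, 1), m)
  expect_identical(out[out$trimester != "T3", ]$bout_id,
                   m[m$trimester != "T3", ]$bout_id)
  # cohort-style retention reproduces the 2nd/3rd trimester bout imbalance
  out2 <- generate_dropout(m, t3_retention = 161 / 309, seed = 7L)
  n_t2 <- length(unique(out2$bout_id[out2$trimester == "T2"]))
  n_t3b <- length(unique(out2$bout_id[out2$trimester == "T3"]))
  expect_equal(n_t3b / n_t2, 161 / 309, tolerance = 0.15)
})

test_that("paired bouts give pregnant workers both a T2 and a T3 week", {
  tr <- synthetic_truth(n_jobs = 40L, paired_bouts = TRUE,
                        trimester_mix = c(NP = 0.25, T2 = 0.375, T3 = 0.375), seed = 17L)
  co <- generate_cohort(tr)
  m <- co$measurements
  by_worker <- tapply(m$trimester, m$worker_id, function(x) paste(sort(unique(x)), collapse = "+"))
  expect_setequal(unique(by_worker), c("NP", "T2+T3"))
})

test_that("invalid truth configurations are rejected", {
  expect_error(synthetic_truth(sigma2_job = -1), "sigma2_job")
  expect_error(synthetic_truth(trimester_mix = c(NP = 0.5, T2 = 0.2, T3 = 0.2)))
  expect_error(synthetic_truth(n_jobs = 1L))
})
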