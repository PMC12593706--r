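sws_ratings <- function(standing, walking, sitting, group = "G1", rater = "R1") {
  data.frame(group_id = group, rater_id = rater,
             exposure = c("standing", "walking", "sitting"),
             category = c(standing, walking, sitting), stringsAsFactors = FALSE)
}

test_that("directly rated standing/walking/sitting triples must sum to 7", {
  expect_equal(nrow(validate_ratings(sws_ratings(4, 2, 1))), 0)
  expect_equal(nrow(validate_ratings(sws_ratings(3, 3, 1))), 0)
  v <- validate_ratings(sws_ratings(5, 5, 5))
  expect_equal(v$rule, "sum_to_7")
  # fractional (imputed) triples are exempt from the integer constraint
  expect_equal(nrow(validate_ratings(sws_ratings(3.5, 2, 1))), 0)
})

test_that("bending scores outside 0..4 are flagged", {
  b <- data.frame(group_id = "G1", rater_id = "R1", exposure = "bending", category = 5)
  expect_equal(validate_ratings(b)$rule, "bending_range")
  b$category <- 0
  expect_equal(nrow(validate_ratings(b)), 0)     # 0 = cannot be assessed, legal
})

test_that("consensus pools available raters and excludes zeros", {
  r <- ratings_long(list(R1 = c(G1 = 3), R2 = c(G1 = 3), R3 = c(G1 = 3)))
  expect_equal(consensus_category(r)$category, 3.0)
  r2 <- ratings_long(list(R1 = c(G1 = 2), R2 = c(G1 = 3), R3 = c(G1 = 0)))
  expect_equal(consensus_category(r2)$category, 2.5)
  expect_equal(consensus_category(r2, rule = "median")$category, 2.5)
  r3 <- ratings_long(list(R1 = c(G1 = 0), R2 = c(G1 = 0)))
  expect_true(is.na(consensus_category(r3)$category))  # propagated for imputation
})

test_that("benchmark consensus rows are returned verbatim over rater pooling", {
  r <- rbind(ratings_long(list(R1 = c(G1 = 1), R2 = c(G1 = 2))),
             data.frame(group_id = "G1", rater_id = "consensus",
                        exposure = "standing", category = 4))
  expect_equal(consensus_category(r)$category, 4.0)
})

test_that("calibration recovers an exact line and reports its fit", {
  m <- fit_calibration(c(0, 4, 8), c(1, 3, 5))
  expect_equal(m$slope, 2.0)
  expect_equal(m$intercept, -2.0)
  expect_equal(m$r_squared, 1.0)
  expect_equal(m$n_jobs_fit, 3L)
  # noisy but linear-in-mean input: closed-form OLS agreement
  set.seed(1)
  cat <- rep(1:5, each = 6)
  hrs <- 0.5 + 1.3 * cat + rnorm(30, 0, 0.3)
  m2 <- fit_calibration(hrs, cat)
  b <- cov(hrs, cat) / var(cat)
  expect_equal(m2$slope, b, tolerance = 1e-12)
  expect_equal(m2$intercept, mean(hrs) - b * mean(cat), tolerance = 1e-12)
})

test_that("calibration predictions clip to the physical 0-8 range", {
  m <- fit_calibration(c(0, 4, 8), c(1, 3, 5))   # intercept -2: category 0.5 -> -1
  expect_equal(predict(m, 0.5), 0)
  expect_equal(predict(m, 6), 8)
  expect_equal(predict(m, 3), 4)
  # monotone in category for a positive slope
  expect_true(all(diff(predict(m, seq(0, 6, 0.25))) >= 0))
})

test_that("degenerate or tiny calibration inputs error", {
  expect_error(fit_calibration(c(1, 2, 3), c(2, 2, 2)), "degenerate")
  expect_error(fit_calibration(c(1, 2), c(1, 2)), ">= 3 jobs")
})

test_that("quantified ratings carry hours and the walking sqrt covariate", {
  models <- list(standing = fit_calibration(c(0, 4, 8), c(1, 3, 5)),
                 walking = fit_calibration(c(0, 2, 4), c(1, 3, 5)))
  cats <- data.frame(code = c("513110", "513110", "226610"),
                     exposure = c("standing", "walking", "walking"),
                     category = c(3, 2, 5))
  q <- quantify_ratings(cats, models)
  expect_equal(q$hours[1], 4); expect_equal(q$covariate[1], 4)
  expect_equal(q$hours[2], 1); expect_equal(q$covariate[2], 1)   # sqrt(1)
  expect_equal(q$hours[3], 4); expect_equal(q$covariate[3], 2)   # sqrt(4)
  expect_equal(quantify_ratings(cats, models), q)                # deterministic
  # fractional imputed category under a given line: 1.2 x 3 - 0.1 = 3.5
  m <- structure(list(exposure = "standing", slope = 1.2, intercept = -0.1,
                      n_jobs_fit = 3L, r_squared = 1), class = "jem_calibration")
  expect_equal(predict(m, 3), 3.5)
})

test_that("identical raters give ICC 1 and group order does not matter", {
  m <- cbind(r1 = c(1, 2, 3, 4, 5), r2 = c(1, 2, 3, 4, 5), r3 = c(1, 2, 3, 4, 5))
  expect_equal(icc_agreement(m), 1.0)
  set.seed(3)
  m2 <- matrix(rnorm(30, 3, 1), 10, 3) + rnorm(10)
  expect_equal(icc_agreement(m2), icc_agreement(m2[sample(10), ]))
  expect_equal(icc_agreement(m2, "ICC3"), icc_agreement(m2[sample(10), ], "ICC3"))
})

test_that("independent rater noise gives ICC near zero; constant matrix is undefined", {
  set.seed(4)
  m <- matrix(rnorm(3000), 1000, 3)
  expect_lt(abs(icc_agreement(m)), 0.05)
  expect_warning(v <- icc_agreement(matrix(2, 5, 3)), "undefined")
  expect_true(is.na(v))
  expect_error(icc_agreement(matrix(c(1, NA, 2, 3), 2, 2)), "complete")
})

test_that("ICC(2,1) tracks the variance-ratio ground truth on generated ratings", {
  # groups x raters scores with known components: ICC = s2g/(s2g+s2r+s2e)
  s2g <- 4; s2r <- 0.1; s2e <- 0.4
  truth <- s2g / (s2g + s2r + s2e)
  set.seed(11)
  est <- replicate(10, {
    g <- rnorm(60, 0, sqrt(s2g)); r <- rnorm(3, 0, sqrt(s2r))
    icc_agreement(outer(g, r, `+`) + matrix(rnorm(180, 0, sqrt(s2e)), 60, 3))
  })
  expect_equal(mean(est), truth, tolerance = 0.05)
  # cross-check the ANOVA-mean-square formula against a variance-component route
  set.seed(12)
  g <- rnorm(80, 0, 2); r <- rnorm(3, 0, 0.3)
  m <- outer(g, r, `+`) + matrix(rnorm(240, 0, 0.6), 80, 3)
  d <- data.frame(score = as.vector(m), grp = rep(seq_len(80), 3),
                  rater = rep(1:3, each = 80))
  lf <- lme4::lmer(score ~ (1 | grp) + (1 | rater), data = d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  icc_vc <- vc$vcov[vc$grp == "grp"] / sum(vc$vcov)
  expect_equal(icc_agreement(m), icc_vc, tolerance = 0.02)
})
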