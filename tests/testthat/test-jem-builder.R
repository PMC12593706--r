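# a fitted model plus quantified ratings over a small mixed universe
jem_setup <- function(seed = 51) {
  d <- make_model_data(n_jobs = 20, workers_per_job = 3, days = 4, seed = seed)
  fit <- fit_exposure_model(d, exposure = "standing")
  measured <- sort(unique(d$job_code))
  unmeasured <- sprintf("%06d", 900010 + 10 * 1:5)
  universe <- c(measured, unmeasured)
  set.seed(seed + 1)
  quant <- data.frame(code = universe, exposure = "standing",
                      hours = runif(length(universe), 0.5, 6.5))
  quant$covariate <- quant$hours
  list(fit = fit, quant = quant, universe = universe, measured = measured)
}

test_that("the JEM covers the universe once per exposure-trimester with provenance", {
  s <- jem_setup()
  jem <- build_jem(s$fit, s$quant, s$universe)
  expect_equal(nrow(jem), 3 * length(s$universe))       # NP, T2, T3 each
  expect_setequal(unique(jem$trimester), c("NP", "T2", "T3"))
  expect_true(all(table(jem$code) == 3))
  expect_equal(sum(jem$provenance == "measured") / 3, length(s$measured))
  expect_true(all(jem$hours_per_8h >= 0 & jem$hours_per_8h <= 8))
  expect_equal(attr(jem, "reference_age"), s$fit$mean_age)
  # clipping does not activate on data generated within physical bounds
  expect_equal(attr(jem, "n_clipped"), 0)
})

test_that("the trimester shift is one uniform constant equal to the fitted contrast", {
  s <- jem_setup()
  jem <- build_jem(s$fit, s$quant, s$universe)
  bT3 <- s$fit$beta$estimate[s$fit$beta$term == "T3"]
  np <- jem$hours_per_8h[jem$trimester == "NP"]
  t3 <- jem$hours_per_8h[jem$trimester == "T3"]
  expect_equal(np - t3, rep(-bT3, length(np)), tolerance = 1e-10)
})

test_that("measured entries differ from the expert-only route by exactly the BLUP", {
  s <- jem_setup()
  jem <- build_jem(s$fit, s$quant, s$universe)
  np <- jem[jem$trimester == "NP", ]
  for (code in s$measured[1:5]) {
    cov <- s$quant$covariate[s$quant$code == code]
    expert_only <- predict_exposure(s$fit, cov, s$fit$mean_age, "NP")
    expect_equal(np$hours_per_8h[np$code == code] - expert_only,
                 blup(s$fit, code), tolerance = 1e-10)
  }
  # unmeasured code at some covariate equals the pure fixed prediction
  code <- setdiff(s$universe, s$measured)[1]
  cov <- s$quant$covariate[s$quant$code == code]
  expect_equal(np$hours_per_8h[np$code == code],
               predict_exposure(s$fit, cov, s$fit$mean_age, "NP"), tolerance = 1e-10)
})

test_that("pregnancy-specific emission uses the reference level or trimester weights", {
  s <- jem_setup()
  jref <- build_jem(s$fit, s$quant, s$universe, trimester_specific = FALSE)
  expect_equal(unique(jref$trimester), "ALL")
  expect_equal(nrow(jref), length(s$universe))
  jtri <- build_jem(s$fit, s$quant, s$universe)
  expect_equal(jref$hours_per_8h,
               jtri$hours_per_8h[jtri$trimester == "NP"], tolerance = 1e-12)
  jw <- build_jem(s$fit, s$quant, s$universe, trimester_specific = FALSE,
                  pregnancy_convention = "weighted")
  w <- s$fit$trimester_shares
  manual <- sapply(c("NP", "T2", "T3"), function(tr)
    jtri$hours_per_8h[jtri$trimester == tr]) %*% as.numeric(w[c("NP", "T2", "T3")])
  expect_equal(jw$hours_per_8h, as.numeric(manual), tolerance = 1e-10)
})

test_that("missing ratings for a universe code abort JEM assembly", {
  s <- jem_setup()
  expect_error(build_jem(s$fit, s$quant[-1, ], s$universe), "unresolvable")
  bad <- s$fit; bad$converged <- FALSE
  expect_error(build_jem(bad, s$quant, s$universe), "non-converged")
})

test_that("extremes are sorted with lexicographic tie-breaks", {
  jem <- structure(
    data.frame(code = c("100010", "200010", "300010", "400010", "500010"),
               exposure = "bending", trimester = "ALL",
               hours_per_8h = c(0.5, 1.2, 0.15, 1.2, 0.8),
               provenance = "expert_only"),
    reference_age = 30, class = c("jem_table", "data.frame"))
  ex <- jem_extremes(jem, "bending", k = 2)
  expect_equal(ex$top$code, c("200010", "400010"))      # tie: lexicographic first
  expect_equal(ex$bottom$code, c("300010", "100010"))
  expect_equal(ex$top$hours_per_8h[1], 1.2)
  expect_warning(ex5 <- jem_extremes(jem, "bending", k = 9), "truncating")
  expect_equal(nrow(ex5$top), 5)
})

test_that("standing extremes rank by the non-pregnant entry", {
  s <- jem_setup()
  jem <- build_jem(s$fit, s$quant, s$universe)
  ex <- jem_extremes(jem, "standing", k = 1)
  np <- jem[jem$trimester == "NP", ]
  expect_equal(ex$top$hours_per_8h, max(np$hours_per_8h))
  expect_equal(ex$top$code, np$code[which.max(np$hours_per_8h)])
})

test_that("fold ratios are max over min and scale-invariant", {
  jem <- structure(
    data.frame(code = c("100010", "200010"), exposure = "bending",
               trimester = "ALL", hours_per_8h = c(1.24, 0.15),
               provenance = "expert_only"),
    reference_age = 30, class = c("jem_table", "data.frame"))
  expect_equal(fold_ratio(jem, "bending"), 1.24 / 0.15)
  jem2 <- jem; jem2$hours_per_8h <- jem2$hours_per_8h * 2
  expect_equal(fold_ratio(jem2, "bending"), fold_ratio(jem, "bending"))
  jem3 <- jem; jem3$hours_per_8h <- c(1, 1)
  expect_equal(fold_ratio(jem3, "bending"), 1)
  jem4 <- jem; jem4$hours_per_8h[2] <- 0
  expect_warning(r <- fold_ratio(jem4, "bending"), "infinite")
  expect_equal(r, Inf)
})

test_that("four-digit views average six-digit entries within the prefix", {
  jem <- structure(
    data.frame(code = c("100010", "100020", "200010"),
               exposure = "standing", trimester = "NP",
               hours_per_8h = c(2, 4, 5),
               provenance = c("measured", "expert_only", "expert_only")),
    reference_age = 30, class = c("jem_table", "data.frame"))
  l4 <- jem_level4(jem)
  expect_equal(l4$code, c("1000", "2000"))
  expect_equal(l4$hours_per_8h, c(3, 5))
  expect_equal(l4$provenance, c("measured", "expert_only"))
})
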