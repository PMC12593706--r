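# Small in-code fixtures shared across tests.

# a measurement-day row with sensible defaults
day_row <- function(worker = "W1", job = "513110", trimester = "NP", age = 30,
                    work = 8, standing = 3, walking = 0.8, sitting = 3.5,
                    bending = 0.4, bout = NULL) {
  data.frame(worker_id = worker, job_code = job, trimester = trimester,
             bout_id = if (is.null(bout)) paste(worker, trimester, sep = ":") else bout,
             age = age, work_hours = work, standing_h = standing,
             walking_h = walking, sitting_h = sitting, bending_h = bending,
             stringsAsFactors = FALSE)
}

days_table <- function(...) do.call(rbind, list(...))

# long ratings table from a named list rater -> c(categories by group)
ratings_long <- function(values, exposure = "standing") {
  do.call(rbind, lapply(names(values), function(r) {
    v <- values[[r]]
    data.frame(group_id = names(v), rater_id = r, exposure = exposure,
               category = unname(v), stringsAsFactors = FALSE)
  }))
}

# balanced one-way layout: n_j groups x n_per replicates
one_way_data <- function(n_j, n_per, mu = 3, s2j = 1, s2e = 0.5, seed = 42) {
  set.seed(seed)
  g <- rep(sprintf("%04d", 1000 + seq_len(n_j)), each = n_per)
  u <- rep(stats::rnorm(n_j, 0, sqrt(s2j)), each = n_per)
  y <- mu + u + stats::rnorm(length(g), 0, sqrt(s2e))
  data.frame(job_code = g, worker_id = paste0("w", seq_along(g)),
             standing_h = y, stringsAsFactors = FALSE)
}

# covariate-rich model data with known generating parameters
make_model_data <- function(n_jobs = 25, workers_per_job = 3, days = 4,
                            s2j = 0.6, s2w = 0.3, s2e = 0.4,
                            beta = c(b0 = 2, bE = 0.5, bA = -0.02, bT2 = -0.2, bT3 = -0.4),
                            seed = 1) {
  set.seed(seed)
  job <- sprintf("%06d", 100010 + 10 * seq_len(n_jobs))
  E <- runif(n_jobs, 0.5, 6.5)
  u <- rnorm(n_jobs, 0, sqrt(s2j))
  w <- expand.grid(widx = seq_len(workers_per_job), jidx = seq_len(n_jobs))
  w$worker_id <- sprintf("w%04d", seq_len(nrow(w)))
  w$age <- runif(nrow(w), 20, 44)
  w$trimester <- sample(c("NP", "T2", "T3"), nrow(w), TRUE)
  v <- rnorm(nrow(w), 0, sqrt(s2w))
  d <- w[rep(seq_len(nrow(w)), each = days), ]
  bt <- c(NP = 0, T2 = beta[["bT2"]], T3 = beta[["bT3"]])[d$trimester]
  y <- beta[["b0"]] + beta[["bE"]] * E[d$jidx] + beta[["bA"]] * d$age + bt +
    u[d$jidx] + v[rep(seq_len(nrow(w)), each = days)] +
    rnorm(nrow(d), 0, sqrt(s2e))
  data.frame(job_code = job[d$jidx], worker_id = d$worker_id, age = d$age,
             trimester = d$trimester, expert_cov = E[d$jidx], standing_h = y,
             stringsAsFactors = FALSE)
}

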