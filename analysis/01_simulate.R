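#!/usr/bin/env Rscript
# Generate the study-scale synthetic cohort used by the downstream
# analysis scripts: 109 measured job codes in a 409-code universe,
# four workers per measured job (~436 workers), four workdays per
# bout. About 21% of workers are non-pregnant (one measurement week);
# pregnant workers are measured in both the 2nd and 3rd trimester and
# their 3rd-trimester week is then thinned to a 161/309 retention,
# emulating pregnancy-related absence. Fixed effects and variance
# components of the generator are the final standing-model values the
# package's recovery tests target.

library(opajem)

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

truth <- synthetic_truth(
  n_jobs = 109L, workers_per_job = 4L, days_per_worker = 4L,
  paired_bouts = TRUE, trimester_mix = c(NP = 0.21, T2 = 0.395, T3 = 0.395),
  n_unmeasured_codes = 300L, seed = 42L)

paths <- run_simulate(truth, "results/data")
m <- read_measurements(paths[["measurements"]])
m <- generate_dropout(m, t3_retention = 161 / 309, seed = 43L)
write.csv(m, paths[["measurements"]], row.names = FALSE)

bouts <- unique(m[, c("bout_id", "trimester")])
cat(sprintf("cohort: %d workers, %d measured job codes, %d workdays\n",
            length(unique(m$worker_id)), length(unique(m$job_code)), nrow(m)))
cat(sprintf("bouts by trimester: NP %d | T2 %d | T3 %d (T3 thinned by drop-out)\n",
            sum(bouts$trimester == "NP"), sum(bouts$trimester == "T2"),
            sum(bouts$trimester == "T3")))
cat("wrote", paste(basename(unname(paths)), collapse = ", "), "to results/data\n")
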