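#!/usr/bin/env Rscript
# The association battery: STAT-acute and STAT-late on PRS and wPRS
# (continuous and >90th percentile) in univariable and multivariable linear
# models, then every individual endpoint in multivariable models with
# Bonferroni correction by endpoint-family size (14 acute -> .004, 5 late
# -> .01 at display precision).

suppressMessages(library(radiotox))

scores <- read.delim("results/scores.tsv",
                     colClasses = c(sample_id = "character"))
class(scores) <- c("score_set", "data.frame")
stat <- read.delim("results/stat.tsv",
                   colClasses = c(patient_id = "character"))
summaries <- read.delim("results/endpoint_summaries.tsv",
                        colClasses = c(patient_id = "character"))
covariates <- read_covariates_tsv("results/cohort/covariates.tsv")

results <- run_battery(scores, stat, summaries, covariates,
                       site = "prostate", alpha = 0.05)
write_results(results, "results/associations.tsv")

cat(nrow(results), "association rows written to results/associations.tsv\n")
stat_rows <- results[results$outcome == "STAT", ]
cat("STAT analyses (family size 1, alpha = .05):\n")
print(stat_rows[stat_rows$model == "multivariable" &
                  stat_rows$transform == "continuous",
                c("outcome", "timing", "predictor", "beta", "ci_low",
                  "ci_high", "p")], row.names = FALSE, digits = 3)
sig <- results[results$significant, ]
if (nrow(sig) == 0) {
  cat("no endpoint passed its Bonferroni-adjusted threshold",
      "(expected under the null)\n")
} else {
  cat("rows passing Bonferroni-adjusted thresholds:\n")
  print(sig[, c("outcome", "timing", "predictor", "transform", "beta", "p",
                "alpha_adjusted")], row.names = FALSE, digits = 3)
}
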