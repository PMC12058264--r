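#!/usr/bin/env Rscript
# Build the study cohort: 500 prostate-cancer patients, 101 RA risk variants
# in Hardy-Weinberg proportions with imputation-like dosage noise, preselected
# clinical covariates, and longitudinal CTCAE records on the site's acute and
# late endpoint families. No genetic effect is planted (the null that the
# downstream analysis interrogates). All inputs land under results/cohort/.

suppressMessages(library(radiotox))

cfg <- simulation_config(n_patients = 500, n_variants = 101,
                         site = "prostate", effect_gamma = 0,
                         master_seed = 20260930)
cohort <- generate_cohort(cfg, "results/cohort")

cat("cohort written to results/cohort/\n")
cat("  patients:         ", cfg$n_patients, "\n")
cat("  variants:         ", cfg$n_variants, "\n")
cat("  toxicity records: ", nrow(cohort$records), "\n")
cat("  endpoints:        ", length(unique(cohort$records$endpoint)), "\n")
grade_tab <- prop.table(table(cohort$records$grade))
cat("  grade distribution:", paste0(names(grade_tab), ":",
                                    round(100 * grade_tab, 1), "%"),
    "\n")
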