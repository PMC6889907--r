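#!/usr/bin/env Rscript
# Step 4: simulate the intervention scenarios on top of the fitted CDE
# model: a hypothetical universal +30 min/day (scenario 1), a universal
# break-time intervention (2), active school transport (3), an after-school
# programme targeted at deprived areas (4), an indicated family-based
# intervention (5), and the proportionate-universal package combining 2-5.
# Coefficients stay fixed at their observed-data estimates; only the
# mediator values move.

library(pamsim)

seed <- 1L
cohort <- read_cohort("results/cohort.csv")
ws <- build_weights(cohort, "cde")

cde <- estimate_cde(cohort, weight_set = ws)
specs <- default_scenarios()
results <- list(observed_cde = cde)
for (nm in names(specs)) {
  results[[nm]] <- apply_scenario(cohort, specs[[nm]], seed = seed,
                                  weight_set = ws)$effects
}
results$combined <- combine_scenarios(cohort, specs[-1], seed = seed,
                                      weight_set = ws)$effects

tab <- render_table(results)
write.csv(tab, "results/04_scenarios.csv", row.names = FALSE)
print(tab, row.names = FALSE)

cat(sprintf("\nOnly the hypothetical +30 min scenario moves attainment (to %.1f%%)\n",
            100 * results$scenario1_universal_who$attainment_who))
cat("and prevalence appreciably; the realistic scenarios, alone or combined,\n")
cat("leave prevalence and both inequality measures essentially unchanged.\n")
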