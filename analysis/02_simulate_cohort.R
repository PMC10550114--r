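#!/usr/bin/env Rscript
# Simulates the study-sized cohort (894 dogs) from the default
# configuration: covariate marginals matched to the published descriptive
# tables, confounded treatment assignment for both exposures, a null
# causal effect on 30-day resolution, and a front-loaded daily escalation
# hazard. Writes the cohort, the counterfactual truth table and the
# by-arm descriptive summary.

library(vetemulate)
dir.create("results", showWarnings = FALSE)

cfg <- default_study_config(n = 894, seed = 20190101, true_rd = 0)
out <- generate_cohort(cfg)
write_cohort(out$cohort, "results/cohort.csv")
utils::write.csv(out$truth, "results/truth.csv", row.names = FALSE)

s <- summarize_cohort(out$cohort, "antimicrobial")
cat(sprintf("Cohort n = %d; antimicrobial-exposed %d (%.1f%%)\n",
            s$n, s$n_exposed, s$pct_exposed))
cat(sprintf("Nutraceutical-exposed %.1f%%; 30-day resolution %.1f%%; escalation %.1f%%\n",
            100 * mean(out$cohort$nutraceutical),
            100 * mean(out$cohort$resolved_30d),
            100 * mean(out$cohort$escalated)))
cat(sprintf("True marginal risk difference in the truth table: %.4f\n",
            mean(out$truth$y1) - mean(out$truth$y0)))
utils::write.csv(s$table, "results/descriptives_antimicrobial.csv",
                 row.names = FALSE)
cat("wrote results/cohort.csv, results/truth.csv, results/descriptives_antimicrobial.csv\n")
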