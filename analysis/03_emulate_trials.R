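#!/usr/bin/env Rscript
# Runs both emulated target trials on the simulated cohort: stabilised
# IPT weighting with the trial-specific propensity models, balance
# diagnostics, unadjusted and IPTW risk differences for 30-day clinical
# resolution, and the IP-weighted time-to-escalation analysis with
# bootstrap confidence intervals. All report tables land in
# results/emulation/.

library(vetemulate)

cfg <- emulation_config(sim_config = default_study_config(n = 894, true_rd = 0),
                        n_boot = 500, outdir = "results/emulation",
                        seed = 20190101)
res <- run_emulation(cfg)

for (ex in names(res$results)) {
  r <- res$results[[ex]]
  cat("\n==", ex, "trial ==\n")
  print(r$weights)
  print(r$balance)
  print(r$rd_unadjusted)
  print(r$rd_iptw)
  cat(sprintf("log-rank: chi-square %.3f, p = %.3f\n",
              r$logrank$chisq, r$logrank$p))
  cat("Event-free probability at 5-day intervals (IPW hazards):\n")
  print(round(r$tte$table, 2))
}
cat("\nwrote", length(res$manifest$files), "tables to results/emulation/\n")
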