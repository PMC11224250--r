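#!/usr/bin/env Rscript
## Survival analysis of the simulated strata on the synthetic cohort
## produced by 03_patient_stratification.R (rerun it first if the
## results files are missing).
suppressPackageStartupMessages(library(bcellfate))

strat <- read.csv("results/stratification.csv")
clin <- read.csv("results/synthetic_clinical.csv")
d <- merge(strat, clin, by = "sample_id")

## Kaplan-Meier curves per stratum
km_rows <- do.call(rbind, lapply(split(d, d$group), function(g) {
  km <- km_estimate(g$time_months, g$event)
  data.frame(group = g$group[1], time = km$time, surv = km$surv,
             n_risk = km$n_risk)
}))
write.csv(km_rows, "results/km_by_group.csv", row.names = FALSE)

lr <- logrank_test(d$time_months, d$event, d$group)
cat(sprintf("log-rank across %d groups: chi2 = %.2f (df %d), p = %.3g %s\n",
            length(unique(d$group)), lr$statistic, lr$df, lr$p, lr$stars))

fit <- cox_hr(d$time_months, d$event, d$group == "AAPP")
cat(sprintf("Cox HR, AAPP vs rest: %.2f (95%% CI %.2f-%.2f)\n",
            fit$hr, fit$ci[1], fit$ci[2]))

summary_df <- data.frame(
  test = c("logrank_3group", "cox_AAPP_vs_rest"),
  statistic = c(lr$statistic, fit$hr),
  lo = c(NA, fit$ci[1]), hi = c(NA, fit$ci[2]),
  p = c(lr$p, fit$p))
write.csv(summary_df, "results/survival_summary.csv", row.names = FALSE)
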