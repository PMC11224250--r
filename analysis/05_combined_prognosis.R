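#!/usr/bin/env Rscript
## Combine the model-derived AA/PP strata with clinical prognostic
## metrics (IPI, stage, prior treatment, genetic cluster) into the
## four-category stratification and test its survival separation on the
## synthetic cohort from 03_patient_stratification.R.
suppressPackageStartupMessages(library(bcellfate))

strat <- read.csv("results/stratification.csv")
clin <- read.csv("results/synthetic_clinical.csv")
d <- merge(strat, clin, by = "sample_id")

flags <- list(
  ipi_high = d$ipi >= 4,               # low IPI: 0-3
  stage4 = d$stage == 4,
  prior_treatment = as.logical(d$prior_treatment),
  poor_cluster = d$cluster %in% c("C2", "C3", "C5"))

rows <- list()
for (nm in names(flags)) {
  cat4 <- combine_strata(d$group, flags[[nm]])
  if (length(unique(cat4)) < 2) next
  lr <- logrank_test(d$time_months, d$event, cat4)
  cat(sprintf("%-16s 4-category log-rank chi2 = %.2f, p = %.3g %s\n",
              nm, lr$statistic, lr$p, lr$stars))
  rows[[nm]] <- data.frame(metric = nm, chisq = lr$statistic, df = lr$df,
                           p = lr$p)
  tab <- table(cat4)
  cat("  category sizes: ", paste(names(tab), tab, sep = "=", collapse = "  "),
      "\n")
}
write.csv(do.call(rbind, rows), "results/combined_prognosis.csv",
          row.names = FALSE)
cat("\nNote: synthetic clinical covariates are drawn independently of the\n")
cat("planted groups, so the four-category split is driven by the model\n")
cat("stratum; the combination machinery is what this driver exercises.\n")
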