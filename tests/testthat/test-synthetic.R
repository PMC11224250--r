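test_that("genomics generation respects frequencies and determinism", {
  spec <- cohort_spec(n_patients = 40, seed = 3,
                      gene_freq = c(BCL2 = 1.0, DECOY1 = 0.3))
  g <- generate_genomics(spec)
  ## frequency 1: every patient carries the BCL2 gain
  expect_identical(sort(unique(g$cna$sample_id[g$cna$gene_or_arm == "BCL2"])),
                   sprintf("P%04d", 1:40))
  ## same seed -> identical tables
  g2 <- generate_genomics(spec)
  expect_identical(g, g2)

  ## empirical frequency ~ nominal at large n (binomial tolerance)
  spec2 <- cohort_spec(n_patients = 10000, seed = 4,
                       gene_freq = c(MYC = 0.3))
  g3 <- generate_genomics(spec2)
  f_hat <- length(unique(g3$cna$sample_id[g3$cna$gene_or_arm == "MYC"])) / 10000
  expect_lt(abs(f_hat - 0.3), 0.015)
})

test_that("co-occurrence boost enriches the partner lesion", {
  spec <- cohort_spec(n_patients = 4000, seed = 6,
                      gene_freq = c(MYD88 = 0.3, CD79B = 0.1),
                      cooccurrence = list(MYD88 = c(CD79B = 3)))
  g <- generate_genomics(spec)
  has <- function(gene) {
    ids <- unique(g$mutations$sample_id[g$mutations$hugo_symbol == gene])
    sprintf("P%04d", 1:4000) %in% ids
  }
  myd <- has("MYD88"); cd <- has("CD79B")
  expect_gt(mean(cd[myd]), 2 * mean(cd[!myd]))
})

test_that("survival generation: hazards order the groups, censoring behaves", {
  spec <- cohort_spec(n_patients = 350, seed = 9, censor_rate = 0.3,
                      median_survival = 60,
                      hazard_multiplier = c(AAPP = 2.5, AA_or_PP = 1.5,
                                            Other = 1))
  groups <- setNames(sample(c("AAPP", "AA_or_PP", "Other"), 350, TRUE),
                     sprintf("P%04d", 1:350))
  cl <- generate_survival(groups, spec)
  expect_identical(nrow(cl), 350L)
  expect_true(all(cl$time_months > 0))

  ## KM curves ordered Other > AA_or_PP > AAPP at median follow-up
  med <- median(cl$time_months)
  S <- vapply(c("Other", "AA_or_PP", "AAPP"), function(gr) {
    i <- groups[cl$sample_id] == gr
    km_estimate(cl$time_months[i], cl$event[i])$S(med)
  }, numeric(1))
  expect_true(S[["Other"]] > S[["AA_or_PP"]])
  expect_true(S[["AA_or_PP"]] > S[["AAPP"]])

  ## zero censoring: every record is an event
  spec0 <- cohort_spec(n_patients = 100, seed = 2, censor_rate = 0)
  cl0 <- generate_survival(setNames(rep("Other", 100),
                                    sprintf("P%04d", 1:100)), spec0)
  expect_true(all(cl0$event == 1))

  ## all multipliers 1: the planted groups carry no survival signal
  spec1 <- cohort_spec(n_patients = 300, seed = 14,
                       hazard_multiplier = c(AAPP = 1, AA_or_PP = 1,
                                             Other = 1))
  cl1 <- generate_survival(groups[1:300], spec1)
  lr <- logrank_test(cl1$time_months, cl1$event, groups[cl1$sample_id])
  expect_gt(lr$p, 0.05)
})

test_that("a decoy-only cohort stratifies to all-Other", {
  spec <- cohort_spec(n_patients = 3, seed = 5,
                      gene_freq = c(DECOY1 = 1.0))
  g <- generate_genomics(spec)
  cohort <- load_cohort(g$mutations, g$cna)
  expect_true(all(vapply(cohort$records, nrow, integer(1)) == 0))
  expect_warning(strat <- stratify_cohort(cohort, net = ms_net()),
                 "zero variance")
  expect_true(all(strat$group == "Other"))
})

test_that("planted AA/PP labels are recovered through the full pipeline", {
  ## clean-mapping cohort: only BCL2 (AA) and MYC (PP) lesions
  spec <- cohort_spec(n_patients = 24, seed = 8,
                      gene_freq = c(BCL2 = 0.45, MYC = 0.45, DECOY1 = 0.3))
  cohort_data <- generate_cohort(spec)
  cohort <- load_cohort(cohort_data$mutations, cohort_data$cna)
  strat <- stratify_cohort(cohort, net = ms_net())
  m <- merge(strat, cohort_data$planted, by = "sample_id")
  agree_aa <- m$aa.x == m$aa.y
  agree_pp <- m$pp.x == m$pp.y
  expect_gte(mean(agree_aa & agree_pp), 0.95)
})

test_that("planted hazard structure is recovered end to end", {
  ## genomics -> modifiers -> simulation -> stratification -> Cox
  spec <- cohort_spec(n_patients = 80, seed = 12,
                      gene_freq = c(BCL2 = 0.4, MYC = 0.4, DECOY1 = 0.3),
                      hazard_multiplier = c(AAPP = 2.5, AA_or_PP = 1,
                                            Other = 1),
                      median_survival = 60, censor_rate = 0.25)
  cohort_data <- generate_cohort(spec)
  cohort <- load_cohort(cohort_data$mutations, cohort_data$cna)
  strat <- stratify_cohort(cohort, net = ms_net())
  cl <- cohort_data$clinical
  m <- merge(strat, cl, by = "sample_id")
  fit <- cox_hr(m$time_months, m$event, m$group == "AAPP")
  expect_gt(fit$hr, 1)
  expect_gt(fit$ci[2], 2.5)
  expect_lt(fit$ci[1], 2.5)
})
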