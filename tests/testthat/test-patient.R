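test_that("cohort loading filters, expands and reports correctly", {
  cohort <- load_cohort(toy_mutations(), toy_cna())
  ## S1: MYD88 + CD79B kept
  expect_identical(sort(cohort$records$S1$gene), c("CD79B", "MYD88"))
  ## S2: BCL2 SNV + BCL2 copy gain -> two records
  expect_identical(cohort$records$S2$gene, c("BCL2", "BCL2"))
  ## S4: only an unmapped gene -> retained with empty record list
  expect_identical(nrow(cohort$records$S4), 0L)
  expect_identical(unname(cohort$dropped["S4"]), 1L)
  ## S6: arm-level 1q gain expands to MCL1 and CKS1B
  expect_identical(sort(cohort$records$S6$gene), c("CKS1B", "MCL1"))

  ## non-oncogenic SNVs are dropped
  mut <- toy_mutations()
  mut$oncogenic[mut$sample_id == "S3"] <- FALSE
  c2 <- load_cohort(mut, toy_cna())
  expect_identical(nrow(c2$records$S3), 0L)

  expect_error(load_cohort(data.frame(sample_id = character(0),
                                      hugo_symbol = character(0),
                                      alteration = character(0),
                                      oncogenic = logical(0))),
               "empty cohort")
})

test_that("records map to the published fold-change rules", {
  cohort <- load_cohort(toy_mutations(), toy_cna())
  ## MYD88 + CD79B -> two 1.5-fold hits on NEMO:IKK -> net 2.25
  mods <- records_to_modifiers(cohort$records$S1)
  p <- apply_modifiers(c(nemo_act = 1), mods)
  expect_identical(p[["nemo_act"]], 2.25)
  ## a single BCL2 gain -> 1.5-fold on BCL2 transcription
  m2 <- records_to_modifiers(data.frame(gene = "BCL2", effect = "gain"))
  expect_identical(m2[[1]]$fold_change, 1.5)
  expect_identical(m2[[1]]$parameter_id, "tr_bcl2")
  ## loss of an inhibitor-mapped gene halves its parameter
  m3 <- records_to_modifiers(data.frame(gene = "CDKN2A", effect = "loss"))
  expect_identical(m3[[1]]$fold_change, 0.5)
  expect_identical(m3[[1]]$parameter_id, "ks_p27")
  ## direction = down: losing a negative regulator raises the kinase
  m4 <- records_to_modifiers(data.frame(gene = "TNFAIP3", effect = "loss"))
  expect_identical(m4[[1]]$fold_change, 1.5)
  expect_identical(m4[[1]]$parameter_id, "nemo_act")
})

test_that("the four stratification archetypes coexist in one cohort", {
  mut <- data.frame(
    sample_id = c("IKK1", "BCL2only", "MYConly"),
    hugo_symbol = c("MYD88", "BCL2", "MYC"),
    alteration = "SNV_GOF", oncogenic = TRUE)
  mut <- rbind(mut, data.frame(sample_id = c("NONE", "NONE2", "NONE3"),
                               hugo_symbol = "DECOYX",
                               alteration = "SNV_GOF", oncogenic = FALSE))
  cohort <- load_cohort(mut)
  strat <- stratify_cohort(cohort, net = ms_net())
  ## single-cell mode is bitwise deterministic
  strat2 <- stratify_cohort(cohort, net = ms_net())
  expect_identical(strat, strat2)
  rownames(strat) <- strat$sample_id
  expect_identical(strat["IKK1", "group"], "AAPP")
  expect_identical(strat["BCL2only", "group"], "AA_or_PP")
  expect_true(strat["BCL2only", "aa"] && !strat["BCL2only", "pp"])
  expect_identical(strat["MYConly", "group"], "AA_or_PP")
  expect_true(strat["MYConly", "pp"] && !strat["MYConly", "aa"])
  expect_identical(strat["NONE", "group"], "Other")

  ## IKK patients decrease Cdh1 and the pro-apoptotic readouts vs baseline
  expect_lt(strat["IKK1", "cdh1_6"], strat["NONE", "cdh1_6"])
  expect_lt(strat["IKK1", "cSmac_6"], strat["NONE", "cSmac_6"])
  expect_lt(strat["BCL2only", "cSmac_6"], strat["NONE", "cSmac_6"])
  expect_lt(strat["MYConly", "cdh1_6"], strat["NONE", "cdh1_6"])
})

test_that("an all-unmutated cohort has zero variance and lands in Other", {
  mut <- data.frame(sample_id = c("A", "B", "C"), hugo_symbol = "DECOYX",
                    alteration = "SNV_GOF", oncogenic = FALSE)
  cohort <- load_cohort(mut)
  expect_warning(strat <- stratify_cohort(cohort, net = ms_net()),
                 "zero variance")
  expect_true(all(strat$group == "Other"))
  expect_true(all(strat$z_cdh1 == 0))
})

test_that("driver mRNAs and apoptotic readouts are rank-stable over 6-12 h", {
  net <- ms_net()
  warm <- ms_baseline()
  cases <- list(list(), list(modifier("nemo_act", 1.5)),
                list(modifier("tr_bcl2", 1.5)), list(modifier("tr_myc", 1.5)),
                list(modifier("tr_bcl2", 2.25)),
                list(modifier("nemo_act", 1.5), modifier("tr_bcl2", 1.5)))
  vals <- lapply(cases, function(m) {
    p <- apply_modifiers(net$parameters, m)
    st <- multiscale_equilibrate(net, params = p, x0 = warm)
    tr <- integrate_network(net, params = p, t_span = c(0, 12),
                            phase = "dynamic", x0 = st, rtol = 1e-7)
    sapply(c("BCL2t", "MYCt", "cSmac", "cCytoC"), function(sp)
      trace_at(tr, sp, c(6, 9, 12)))
  })
  for (sp in c("BCL2t", "MYCt", "cSmac", "cCytoC")) {
    r6 <- vapply(vals, function(v) v[1, sp], numeric(1))
    r9 <- vapply(vals, function(v) v[2, sp], numeric(1))
    r12 <- vapply(vals, function(v) v[3, sp], numeric(1))
    expect_gte(cor(r6, r9, method = "spearman"), 0.9)
    expect_gte(cor(r6, r12, method = "spearman"), 0.9)
  }
})

test_that("a second hit on the same parameter never pulls z-scores toward zero", {
  mut <- data.frame(
    sample_id = c("ONEHIT", "TWOHIT", "N1", "N2"),
    hugo_symbol = c("BCL2", "BCL2", "DECOYX", "DECOYY"),
    alteration = "SNV_GOF",
    oncogenic = c(TRUE, TRUE, FALSE, FALSE))
  cna <- data.frame(sample_id = "TWOHIT", gene_or_arm = "BCL2", copy_state = 1)
  cohort <- load_cohort(mut, cna)
  strat <- stratify_cohort(cohort, net = ms_net())
  rownames(strat) <- strat$sample_id
  expect_lte(strat["TWOHIT", "z_cSmac"], strat["ONEHIT", "z_cSmac"])
  expect_lt(strat["ONEHIT", "z_cSmac"], 0)
})

test_that("simulation-based and presence-based classifications disagree on antagonists", {
  ## TP53 gain raises the pro-apoptotic activator (pro-death); BCL2 gain
  ## buffers it.  Presence-based counting sees two apoptosis-network hits;
  ## the simulation sees them cancel.
  mut <- data.frame(
    sample_id = c("ANTAG", "ANTAG", "BCL2P", "N1", "N2"),
    hugo_symbol = c("TP53", "BCL2", "BCL2", "DECOYX", "DECOYX"),
    alteration = c("SNV_GOF", "SNV_GOF", "SNV_GOF", "SNV_GOF", "SNV_GOF"),
    oncogenic = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  cohort <- load_cohort(mut)
  strat <- stratify_cohort(cohort, net = ms_net())
  pres <- mutation_presence_control(cohort)
  rownames(strat) <- strat$sample_id
  rownames(pres) <- pres$sample_id
  ## presence flags ANTAG as apoptosis-network-mutated...
  expect_true(pres["ANTAG", "apoptosis_hit"])
  ## ...but the simulated readout sits near baseline (the two lesions
  ## antagonise), unlike the clean BCL2 patient
  expect_gt(strat["ANTAG", "cSmac_6"], strat["BCL2P", "cSmac_6"])
  disagree <- (pres$group != strat[pres$sample_id, "group"])
  expect_gt(mean(disagree), 0)
})

test_that("presence control classifies by network membership only", {
  cohort <- load_cohort(toy_mutations(), toy_cna())
  pres <- mutation_presence_control(cohort)
  rownames(pres) <- pres$sample_id
  ## NF-kB-input lesions feed both networks
  expect_identical(pres["S1", "group"], "AAPP")
  ## BCL2 only -> apoptosis-network only
  expect_identical(pres["S2", "group"], "AA_or_PP")
  ## no mapped lesions -> none
  expect_identical(pres["S4", "group"], "Other")
})
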