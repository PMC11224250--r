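## Synthetic cohort generator: DLBCL-like genomics with planted AA/PP
## structure and censored survival whose hazard depends on the planted
## group.

#' Specification of a synthetic cohort
#'
#' Default gene frequencies loosely follow DLBCL recurrence (MYD88 ~0.2,
#' CD79B ~0.1, BCL2 ~0.2, MYC ~0.1, 1q gain ~0.1, plus unmappable decoy
#' genes); they are configuration values, not biological claims.  A
#' co-occurrence boost inflates the probability of CD79B lesions in
#' MYD88-mutant patients.  Survival times are exponential with hazard
#' `log(2) / median_survival * multiplier(group)` and independent
#' uniform censoring over the accrual window; clinical covariates are
#' drawn independently of the planted group by default, with an optional
#' dependence knob.
#'
#' @param n_patients cohort size.
#' @param gene_freq named vector of per-patient alteration
#'   probabilities; names are genes (or `"gain1q"` for the arm event and
#'   `"DECOY<i>"` for unmappable genes).
#' @param cooccurrence named list, e.g.
#'   `list(MYD88 = c(CD79B = 3))`: given a MYD88 lesion, the CD79B
#'   probability is multiplied by 3 (capped at 1).
#' @param hazard_multiplier named vector over groups
#'   (`AAPP`, `AA_or_PP`, `Other`).
#' @param median_survival baseline median survival (months) of the
#'   `Other` group.
#' @param censor_rate approximate fraction censored (0 <= c < 1).
#' @param accrual window (months) over which censoring times are
#'   uniform.
#' @param covariate_dependence 0 (default) draws IPI/stage/cluster
#'   independently of the planted group; positive values tilt poor
#'   covariates toward poor groups.
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 350,
                        gene_freq = c(MYD88 = 0.20, CD79B = 0.10,
                                      CARD11 = 0.05, BCL2 = 0.20,
                                      MCL1 = 0.05, MYC = 0.10,
                                      CKS1B = 0.05, BCL6 = 0.10,
                                      TP53 = 0.15, CDKN2A = 0.10,
                                      gain1q = 0.10,
                                      DECOY1 = 0.30, DECOY2 = 0.30),
                        cooccurrence = list(MYD88 = c(CD79B = 3)),
                        hazard_multiplier = c(AAPP = 2.5, AA_or_PP = 1.5,
                                              Other = 1),
                        median_survival = 80,
                        censor_rate = 0.3,
                        accrual = 120,
                        covariate_dependence = 0,
                        seed = 1) {
  stopifnot(all(gene_freq >= 0 & gene_freq <= 1),
            all(hazard_multiplier > 0),
            censor_rate >= 0, censor_rate < 1)
  structure(list(n_patients = n_patients, gene_freq = gene_freq,
                 cooccurrence = cooccurrence,
                 hazard_multiplier = hazard_multiplier,
                 median_survival = median_survival,
                 censor_rate = censor_rate, accrual = accrual,
                 covariate_dependence = covariate_dependence,
                 seed = seed),
            class = "cohort_spec")
}

#' Generate synthetic genomics tables
#'
#' Independent Bernoulli draws per gene and patient, with the spec's
#' co-occurrence adjustment; SNV-type lesions are emitted for signalling
#' genes (flagged oncogenic), copy-number rows for BCL2/MCL1/MYC-class
#' gains, losses for tumour suppressors, and an arm-level `1q` gain
#' covering MCL1 and CKS1B.  Decoy genes yield non-oncogenic SNVs that
#' the pipeline must drop.
#'
#' @param spec a [cohort_spec()].
#' @return List with `mutations` and `cna` data frames in the dialect
#'   [load_cohort()] consumes.
#' @export
generate_genomics <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_patients
  ids <- sprintf("P%04d", seq_len(n))
  freq <- spec$gene_freq

  hit <- matrix(FALSE, n, length(freq), dimnames = list(ids, names(freq)))
  for (g in names(freq)) hit[, g] <- runif(n) < freq[g]
  ## co-occurrence boost: re-draw the boosted gene where the driver hit
  for (drv in intersect(names(spec$cooccurrence), names(freq))) {
    boosts <- spec$cooccurrence[[drv]]
    for (tgt in intersect(names(boosts), names(freq))) {
      p_boost <- pmin(freq[tgt] * boosts[tgt], 1)
      idx <- hit[, drv]
      hit[idx, tgt] <- runif(sum(idx)) < p_boost
    }
  }

  snv_gof <- c("MYD88", "CD79B", "CARD11")
  cna_gain <- c("BCL2", "MCL1", "MYC", "CKS1B", "BCL6")
  snv_lof <- c("TP53", "CDKN2A")
  decoys <- grep("^DECOY", names(freq), value = TRUE)

  mut <- list(); cna <- list()
  for (i in seq_len(n)) {
    for (g in intersect(names(freq)[hit[i, ]], snv_gof)) {
      mut[[length(mut) + 1]] <- data.frame(
        sample_id = ids[i], hugo_symbol = g, alteration = "SNV_GOF",
        oncogenic = TRUE)
    }
    for (g in intersect(names(freq)[hit[i, ]], snv_lof)) {
      mut[[length(mut) + 1]] <- data.frame(
        sample_id = ids[i], hugo_symbol = g, alteration = "SNV_LOF",
        oncogenic = TRUE)
    }
    for (g in intersect(names(freq)[hit[i, ]], decoys)) {
      mut[[length(mut) + 1]] <- data.frame(
        sample_id = ids[i], hugo_symbol = g, alteration = "SNV_GOF",
        oncogenic = FALSE)
    }
    for (g in intersect(names(freq)[hit[i, ]], cna_gain)) {
      cna[[length(cna) + 1]] <- data.frame(
        sample_id = ids[i], gene_or_arm = g, copy_state = 1)
    }
    if ("gain1q" %in% names(freq) && hit[i, "gain1q"]) {
      cna[[length(cna) + 1]] <- data.frame(
        sample_id = ids[i], gene_or_arm = "1q", copy_state = 1)
    }
  }
  mutations <- if (length(mut)) do.call(rbind, mut) else
    data.frame(sample_id = character(0), hugo_symbol = character(0),
               alteration = character(0), oncogenic = logical(0))
  ## ensure every patient appears at least once so the cohort is complete
  missing <- setdiff(ids, unique(c(mutations$sample_id,
                                   vapply(cna, function(d) d$sample_id[1],
                                          character(1)))))
  if (length(missing)) {
    mutations <- rbind(mutations, data.frame(
      sample_id = missing, hugo_symbol = "DECOY0",
      alteration = "SNV_GOF", oncogenic = FALSE))
  }
  cna_df <- if (length(cna)) do.call(rbind, cna) else
    data.frame(sample_id = character(0), gene_or_arm = character(0),
               copy_state = numeric(0))
  list(mutations = mutations, cna = cna_df)
}

#' Generate synthetic censored survival and clinical covariates
#'
#' Event times are exponential with per-group hazards; censoring is
#' independent and uniform, calibrated to the requested censoring rate.
#'
#' @param groups character vector of planted (or assigned) groups per
#'   patient, with names as sample ids; levels must appear in the
#'   spec's `hazard_multiplier`.
#' @param spec a [cohort_spec()].
#' @return Data frame `sample_id`, `time_months`, `event`, `ipi`,
#'   `stage`, `prior_treatment`, `cluster`, `coo`.
#' @export
generate_survival <- function(groups, spec) {
  n <- length(groups)
  ids <- names(groups)
  if (is.null(ids)) ids <- sprintf("P%04d", seq_len(n))
  stopifnot(all(groups %in% names(spec$hazard_multiplier)))
  set.seed(spec$seed + 1L)
  h0 <- log(2) / spec$median_survival
  haz <- h0 * unname(spec$hazard_multiplier[groups])
  t_event <- rexp(n, rate = haz)
  ## uniform censoring over (0, c_max) tuned to the target censor rate:
  ## for exponential events, P(censored) ~ E[1 - exp(-h c)]/(h c); use the
  ## accrual window scaled so the empirical rate approximates the target.
  if (spec$censor_rate > 0) {
    c_max <- spec$accrual
    t_cens <- runif(n, 0, c_max)
    ## thin censoring to approach the requested rate
    keep_cens <- t_cens < t_event
    frac <- mean(keep_cens)
    if (frac > spec$censor_rate) {
      demote <- which(keep_cens)
      n_keep <- round(spec$censor_rate * n)
      if (length(demote) > n_keep) {
        drop <- sample(demote, length(demote) - n_keep)
        t_cens[drop] <- Inf
      }
    }
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  } else {
    time <- t_event
    event <- rep(1L, n)
  }
  time <- pmax(time, 0.1)

  dep <- spec$covariate_dependence
  poor_lean <- (groups == "AAPP") * dep
  ipi <- pmin(5, pmax(0, rbinom(n, 5, 0.45 + 0.2 * poor_lean)))
  stage <- 1 + pmin(3, rbinom(n, 3, 0.5 + 0.2 * poor_lean))
  prior <- runif(n) < (0.3 + 0.3 * poor_lean)
  cluster <- sample(paste0("C", 1:5), n, replace = TRUE)
  coo <- sample(c("GCB", "ABC", "UNC"), n, replace = TRUE,
                prob = c(0.45, 0.4, 0.15))
  data.frame(sample_id = ids, time_months = time, event = event,
             ipi = ipi, stage = stage, prior_treatment = prior,
             cluster = cluster, coo = coo)
}

#' Generate a complete synthetic cohort
#'
#' Genomics via [generate_genomics()]; planted groups derived from the
#' lesions each patient carries (any apoptosis-network lesion plants AA,
#' any proliferation-network lesion plants PP, NF-kB-input lesions plant
#' both); survival via [generate_survival()] with hazards set by the
#' planted group.
#'
#' @param spec a [cohort_spec()].
#' @param map gene-to-parameter map used for planting.
#' @return List with `mutations`, `cna`, `clinical`, `planted` (data
#'   frame `sample_id`, `aa`, `pp`, `group`).
#' @export
generate_cohort <- function(spec, map = default_gene_map()) {
  g <- generate_genomics(spec)
  cohort <- load_cohort(g$mutations, g$cna, map = map)
  planted <- do.call(rbind, lapply(names(cohort$records), function(s) {
    r <- cohort$records[[s]]
    nets <- map$network[match(r$gene, map$gene)]
    dirs <- map$direction[match(r$gene, map$gene)]
    ## a planted hit must push the lesion in the harmful direction:
    ## gains of "up" genes or losses of "down"-less genes both map to
    ## 1.5-fold; losses of "up" suppressors (TP53, CDKN1B) push the
    ## protective parameter down, which is also harmful.
    aa <- any(nets %in% c("apoptosis", "both"))
    pp <- any(nets %in% c("proliferation", "both"))
    data.frame(sample_id = s, aa = aa, pp = pp,
               group = if (aa && pp) "AAPP"
                       else if (aa || pp) "AA_or_PP" else "Other")
  }))
  groups <- setNames(planted$group, planted$sample_id)
  clinical <- generate_survival(groups, spec)
  list(mutations = g$mutations, cna = g$cna, clinical = clinical,
       planted = planted)
}
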