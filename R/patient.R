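## Patient pipeline: cohort genomics -> parameter modifiers -> personalised
## simulations -> 6-h readouts -> AA/PP stratification.

#' Built-in gene-to-parameter map
#'
#' Maps recurrently altered genes to multi-scale model parameters.
#' `direction` gives the sense of a *gain* of the gene on the parameter
#' (`up` = a gain raises it); `network` annotates which fate network the
#' parameter feeds (`apoptosis`, `proliferation`, `both`, `other`), used
#' only by the no-simulation presence control.  Genes not modelled
#' directly are assigned to the closest modelled species (MCL1 acts as
#' BCL2 overexpression; CARD11/MYD88/CD79B raise NEMO:IKK activity;
#' CDKN2A stands on the p27 axis; TP53 on the pro-apoptotic activator).
#' The map ships as an editable CSV
#' (`system.file("extdata", "gene_parameter_map.csv", package = "bcellfate")`).
#'
#' @return Data frame with columns `gene`, `parameter_id`, `direction`,
#'   `network`, `proxy_note`.
#' @export
default_gene_map <- function() {
  path <- system.file("extdata", "gene_parameter_map.csv",
                      package = "bcellfate")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Built-in chromosome-arm membership table
#'
#' Minimal arm-to-gene table used to expand arm-level copy-number events
#' to every mappable gene on the arm (e.g. 1q gains cover MCL1 and
#' CKS1B).
#'
#' @return Data frame with columns `arm`, `gene`.
#' @export
default_arm_map <- function() {
  path <- system.file("extdata", "gene_arm_map.csv", package = "bcellfate")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Load a cohort's genomic alterations
#'
#' Parses a mutation table and a copy-number table, restricts records to
#' genes that map to model parameters, keeps only oncogenic-flagged
#' SNVs, and expands arm-level events via the arm table.  Patients whose
#' alterations all fall outside the map are retained with empty record
#' lists (their simulations are the unmutated baseline).
#'
#' @param mutations data frame or TSV path with columns `sample_id`,
#'   `hugo_symbol`, `alteration` (`SNV_GOF` or `SNV_LOF`), `oncogenic`
#'   (logical).
#' @param cna data frame or TSV path with columns `sample_id`,
#'   `gene_or_arm`, `copy_state` (-2, -1, 1, 2; arm identifiers such as
#'   `"1q"` refer to the arm table).
#' @param map gene-to-parameter map (default [default_gene_map()]).
#' @param arm_map arm membership table (default [default_arm_map()]).
#' @return List with `records` (named list per patient of data frames
#'   `gene`, `effect` in `c("gain", "loss")`), and `dropped` (per
#'   patient count of discarded records).
#' @export
load_cohort <- function(mutations, cna = NULL, map = default_gene_map(),
                        arm_map = default_arm_map()) {
  read_tab <- function(x) {
    if (is.character(x)) read.delim(x, stringsAsFactors = FALSE) else x
  }
  mut <- read_tab(mutations)
  need <- c("sample_id", "hugo_symbol", "alteration", "oncogenic")
  if (!all(need %in% names(mut))) {
    stop("mutation table must have columns: ", paste(need, collapse = ", "))
  }
  cna <- if (is.null(cna)) {
    data.frame(sample_id = character(0), gene_or_arm = character(0),
               copy_state = numeric(0))
  } else read_tab(cna)

  samples <- unique(c(mut$sample_id, cna$sample_id))
  if (length(samples) == 0) stop("empty cohort")

  records <- setNames(vector("list", length(samples)), samples)
  dropped <- setNames(integer(length(samples)), samples)
  mappable <- map$gene

  for (s in samples) {
    recs <- data.frame(gene = character(0), effect = character(0))
    ## SNVs: oncogenic-only, mappable-only
    ms <- mut[mut$sample_id == s, , drop = FALSE]
    for (k in seq_len(nrow(ms))) {
      r <- ms[k, ]
      ok <- isTRUE(as.logical(r$oncogenic)) && r$hugo_symbol %in% mappable &&
        r$alteration %in% c("SNV_GOF", "SNV_LOF")
      if (!ok) { dropped[s] <- dropped[s] + 1L; next }
      recs <- rbind(recs, data.frame(
        gene = r$hugo_symbol,
        effect = if (r$alteration == "SNV_GOF") "gain" else "loss"))
    }
    ## CNAs: gene- or arm-level
    cs <- cna[cna$sample_id == s, , drop = FALSE]
    for (k in seq_len(nrow(cs))) {
      r <- cs[k, ]
      state <- suppressWarnings(as.numeric(r$copy_state))
      if (is.na(state) || state == 0) { dropped[s] <- dropped[s] + 1L; next }
      effect <- if (state > 0) "gain" else "loss"
      if (r$gene_or_arm %in% arm_map$arm) {
        genes <- intersect(arm_map$gene[arm_map$arm == r$gene_or_arm], mappable)
        if (length(genes) == 0) { dropped[s] <- dropped[s] + 1L; next }
        recs <- rbind(recs, data.frame(gene = genes, effect = effect))
      } else if (r$gene_or_arm %in% mappable) {
        recs <- rbind(recs, data.frame(gene = r$gene_or_arm, effect = effect))
      } else {
        dropped[s] <- dropped[s] + 1L
      }
    }
    records[[s]] <- recs
  }
  list(records = records, dropped = dropped)
}

#' Convert alteration records to parameter modifiers
#'
#' Gains of a gene change its mapped parameter by 1.5-fold in the map's
#' direction (half of normal expression per gene copy); losses halve it
#' (mirrored when the map direction is `down`).  Several lesions hitting
#' one parameter combine multiplicatively on application.
#'
#' @param records data frame with `gene`, `effect` for one patient.
#' @param map gene-to-parameter map.
#' @return List of [modifier()] objects (possibly empty).
#' @export
records_to_modifiers <- function(records, map = default_gene_map()) {
  mods <- list()
  for (k in seq_len(nrow(records))) {
    gene <- records$gene[k]; effect <- records$effect[k]
    row <- map[map$gene == gene, , drop = FALSE]
    if (nrow(row) == 0) next
    for (j in seq_len(nrow(row))) {
      up <- identical(row$direction[j], "up")
      fold <- if ((effect == "gain") == up) 1.5 else 0.5
      mods[[length(mods) + 1]] <- modifier(row$parameter_id[j], fold)
    }
  }
  mods
}

#' Simulate one patient and extract fate readouts
#'
#' Builds the personalised model (base multi-scale parameters times the
#' patient's modifiers), equilibrates it, runs the 12-hour dynamic
#' phase, and reads the pro-proliferative (Cdh1) and pro-apoptotic
#' (cytoplasmic Smac and cytochrome c) abundances at exactly 6 h by
#' linear interpolation.  In `single_cell` mode the simulation is fully
#' deterministic and identical base parameters are used for every
#' patient.  In `mean_of_100` mode readouts are averaged over `n_cells`
#' heterogeneous cells drawn once per cohort seed (common random
#' numbers, so patients remain comparable).  Cells are checked not to
#' have divided or died before the readout time; a removal before 6 h
#' raises an error rather than applying a carry-forward rule.
#'
#' @param net a [multiscale_network()].
#' @param modifiers list of [modifier()] objects for this patient.
#' @param mode `"single_cell"` or `"mean_of_100"`.
#' @param seed cohort seed for the heterogeneous cell draws.
#' @param n_cells cells averaged in `mean_of_100` mode.
#' @param readout_times times (hours) at which readouts are taken.
#' @param t_sim length of the dynamic phase.
#' @param warm_state optional equilibrated state of a related model
#'   (typically the unmutated baseline) used as the starting point of
#'   this patient's equilibration, which shortens it considerably.
#' @return Named numeric vector `cdh1_<t>`, `cSmac_<t>`, `cCytoC_<t>`
#'   for each readout time.
#' @export
simulate_patient <- function(net, modifiers = list(),
                             mode = c("single_cell", "mean_of_100"),
                             seed = 1, n_cells = 100,
                             readout_times = 6, t_sim = 12,
                             warm_state = NULL) {
  mode <- match.arg(mode)
  params <- apply_modifiers(net$parameters, modifiers)
  base_state <- multiscale_equilibrate(net, params = params,
                                       x0 = warm_state)
  if (isTRUE(attr(base_state, "arrested"))) {
    stop("patient model failed to reach a cycling equilibrium")
  }

  one_cell <- function(p) {
    tr <- integrate_network(net, params = p, t_span = c(0, t_sim),
                            phase = "dynamic", x0 = base_state,
                            rtol = 1e-7, atol = 1e-9,
                            n_out = 40 * t_sim)
    ## no division or death before the first readout time
    t0 <- min(readout_times)
    pre <- tr$times <= t0
    cdh1 <- tr$values[, "Cdh1"]
    crossed_up <- any(diff(cdh1[pre] > 0.1) > 0)
    died <- any(tr$values[pre, "cPARP"] > params[["death_threshold"]])
    if (crossed_up || died) {
      stop("cell removed (division/death) before the readout time; ",
           "6-h readouts are undefined at these parameters")
    }
    vapply(readout_times, function(tt) {
      c(trace_at(tr, "Cdh1", tt), trace_at(tr, "cSmac", tt),
        trace_at(tr, "cCytoC", tt))
    }, numeric(3))
  }

  if (mode == "single_cell") {
    vals <- one_cell(params)
  } else {
    het <- net$heterogeneity
    set.seed(seed)
    sdl <- sqrt(log(1 + 0.25^2))
    mult <- matrix(exp(rnorm(n_cells * length(het), 0, sdl)),
                   nrow = n_cells, dimnames = list(NULL, het))
    acc <- 0
    for (i in seq_len(n_cells)) {
      p <- params
      p[het] <- p[het] * mult[i, ]
      acc <- acc + one_cell(p)
    }
    vals <- acc / n_cells
  }
  out <- as.vector(vals)
  names(out) <- as.vector(vapply(readout_times, function(tt)
    paste0(c("cdh1_", "cSmac_", "cCytoC_"), tt), character(3)))
  out
}

#' Stratify a cohort by simulated AA/PP signalling
#'
#' Runs (or takes) per-patient 6-h readouts, z-scores each readout
#' across the cohort, and labels patients: pro-proliferative (PP) when
#' Cdh1 lies below the cohort mean (z < 0), anti-apoptotic (AA) when
#' both cytoplasmic Smac and cytochrome c lie below their means, and
#' groups them as `AAPP` (both), `AA_or_PP` (exactly one), or `Other`.
#' Identical readouts across the whole cohort (zero variance) yield
#' z = 0 and `Other` for everyone, with a warning.
#'
#' @param cohort result of [load_cohort()], or a data frame of
#'   precomputed readouts with columns `sample_id`, `cdh1_6`,
#'   `cSmac_6`, `cCytoC_6`.
#' @param net a [multiscale_network()] (needed unless readouts are
#'   precomputed).
#' @param map gene-to-parameter map.
#' @param mode simulation mode passed to [simulate_patient()].
#' @param seed cohort seed.
#' @param n_cells cells per patient in `mean_of_100` mode.
#' @return Data frame with readouts, z-scores, `pp`, `aa` flags and the
#'   3-level `group`.
#' @export
stratify_cohort <- function(cohort, net = NULL, map = default_gene_map(),
                            mode = "single_cell", seed = 1, n_cells = 100) {
  if (is.data.frame(cohort)) {
    ro <- cohort
  } else {
    if (is.null(net)) stop("a multiscale network is required")
    recs <- cohort$records
    if (length(recs) < 2) stop("need at least 2 patients to stratify")
    ## cache simulations by modifier signature; warm-start every patient
    ## equilibration from the unmutated baseline
    cache <- new.env()
    warm <- multiscale_equilibrate(net)
    ro <- do.call(rbind, lapply(names(recs), function(s) {
      mods <- records_to_modifiers(recs[[s]], map)
      sig <- paste(sort(vapply(mods, function(m)
        sprintf("%s:%g", m$parameter_id, m$fold_change), character(1))),
        collapse = ";")
      key <- paste0("k|", sig)
      if (!exists(key, envir = cache)) {
        assign(key, simulate_patient(net, mods, mode = mode, seed = seed,
                                     n_cells = n_cells, warm_state = warm),
               envir = cache)
      }
      v <- get(key, envir = cache)
      data.frame(sample_id = s, cdh1_6 = v[["cdh1_6"]],
                 cSmac_6 = v[["cSmac_6"]], cCytoC_6 = v[["cCytoC_6"]])
    }))
  }
  degenerate <- FALSE
  zs <- function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) {
      degenerate <<- TRUE
      return(rep(0, length(x)))
    }
    (x - mean(x)) / s
  }
  ro$z_cdh1 <- zs(ro$cdh1_6)
  ro$z_cSmac <- zs(ro$cSmac_6)
  ro$z_cCytoC <- zs(ro$cCytoC_6)
  if (degenerate) {
    warning("zero variance in a readout; affected z-scores set to 0")
  }
  ro$pp <- ro$z_cdh1 < 0
  ro$aa <- ro$z_cSmac < 0 & ro$z_cCytoC < 0
  ro$group <- ifelse(ro$pp & ro$aa, "AAPP",
                     ifelse(ro$pp | ro$aa, "AA_or_PP", "Other"))
  ro
}

#' Mutation-presence control classification (no simulation)
#'
#' Stratifies patients purely by whether they carry at least one
#' alteration mapping to the apoptosis network and/or the proliferation
#' network, mirroring the no-modelling comparison arm.
#'
#' @param cohort result of [load_cohort()].
#' @param map gene-to-parameter map with a `network` column
#'   (`apoptosis`, `proliferation`, `both`, `other`).
#' @return Data frame with `sample_id`, `apoptosis_hit`,
#'   `proliferation_hit`, `group` (`AAPP`, `AA_or_PP`, `Other`).
#' @export
mutation_presence_control <- function(cohort, map = default_gene_map()) {
  recs <- cohort$records
  out <- do.call(rbind, lapply(names(recs), function(s) {
    r <- recs[[s]]
    nets <- map$network[match(r$gene, map$gene)]
    apo <- any(nets %in% c("apoptosis", "both"))
    pro <- any(nets %in% c("proliferation", "both"))
    data.frame(sample_id = s, apoptosis_hit = apo, proliferation_hit = pro,
               group = if (apo && pro) "AAPP"
                       else if (apo || pro) "AA_or_PP" else "Other")
  }))
  out
}
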