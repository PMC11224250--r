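## Isolated cell-cycle network: limit cycle, phases, arrest, MYC dose.

#' Load the cell-cycle network
#'
#' Reads the reduced mass-coupled cell-cycle oscillator from its YAML
#' definition and checks the mandatory structure: CycD/CycE/CycA, a
#' mitotic driver (CycB), Cdh1, p27, and a growing mass that halves at
#' division.  The MYC transcription fold (`tr_myc`) and the Cks1-linked
#' p27-degradation fold (`cks1b_act`) are the mutation targets.
#'
#' @param config path to a YAML network definition; defaults to the
#'   packaged reduced network.
#' @return A [reaction_network()].
#' @export
cellcycle_network <- function(config = NULL) {
  if (is.null(config)) {
    config <- system.file("extdata", "networks", "cellcycle.yaml",
                          package = "bcellfate")
  }
  net <- read_network(config)
  required <- c("mass", "CycB", "Cdh1", "CycD", "CycE", "CycA", "p27")
  missing <- setdiff(required, net$species)
  if (length(missing)) {
    stop("cell-cycle network config lacks mandatory species: ",
         paste(missing, collapse = ", "))
  }
  for (par in c("tr_myc", "cks1b_act")) {
    if (!par %in% names(net$parameters)) {
      stop(sprintf("cell-cycle config does not define parameter '%s'", par))
    }
  }
  if (!"division" %in% names(net$events)) {
    stop("cell-cycle config must declare a division event")
  }
  net
}

#' Single-cell limit-cycle length
#'
#' Equilibrates the cell onto its limit cycle (mass at division constant
#' to three decimals over five consecutive cycles) and returns the
#' settled period.
#'
#' @param net a [cellcycle_network()].
#' @param params optional parameter overrides.
#' @param ... passed to [limit_cycle_equilibrate()].
#' @return Period in hours (`NA` if the cell arrests).
#' @export
cycle_length <- function(net, params = NULL, ...) {
  eq <- limit_cycle_equilibrate(net, params = params, ...)
  eq$period
}

#' Durations of G1, S and G2/M on the settled cycle
#'
#' Phase boundaries follow marker conventions: G1 runs from division to
#' the collapse of Cdh1 below 0.1; S from there to CycA rising through
#' `theta_cyca`; G2/M to the next division (Cdh1 back through 0.1).
#'
#' @param net a [cellcycle_network()].
#' @param params optional parameter overrides.
#' @param theta_cyca CycA threshold marking the S/G2 boundary.
#' @return Named numeric: `G1`, `S`, `G2M`, `total` (hours).
#' @export
phase_durations <- function(net, params = NULL, theta_cyca = 2.0) {
  eq <- limit_cycle_equilibrate(net, params = params)
  if (eq$arrested || !eq$converged) stop("cell is arrested; phases undefined")
  tr <- integrate_network(net, params = params,
                          t_span = c(0, eq$period * 1.4),
                          x0 = eq$state, rtol = 1e-7,
                          n_out = ceiling(eq$period * 1.4 * 100))
  cdh1 <- tr$values[, "Cdh1"]; cyca <- tr$values[, "CycA"]; tt <- tr$times
  i_g1 <- which(cdh1 < 0.1)[1]
  if (is.na(i_g1)) stop("no Cdh1 collapse found within one period")
  g1_end <- tt[i_g1]
  i_s <- which(cyca > theta_cyca & tt > g1_end)[1]
  s_end <- if (is.na(i_s)) g1_end else tt[i_s]
  i_div <- which(cdh1 > 0.1 & tt > g1_end)[1]
  div <- tt[i_div]
  c(G1 = g1_end, S = s_end - g1_end, G2M = div - s_end, total = div)
}

#' Arrest detection over a fixed horizon
#'
#' A cell is arrested when it completes no division within the horizon
#' (default 60 h, five nominal cycles).
#'
#' @param net a [cellcycle_network()].
#' @param params optional parameter overrides.
#' @param x0 starting state (defaults to the network's initial state).
#' @param horizon observation window in hours.
#' @return `TRUE` if no division occurs within the horizon.
#' @export
detect_arrest <- function(net, params = NULL, x0 = NULL, horizon = 60) {
  r <- simulate_agent(net, params = params, x0 = x0, t_end = horizon,
                      rtol = 1e-6, atol = 1e-8, dt = 2)
  length(r$divisions) == 0
}

#' Baseline cycling state shared by population studies
#'
#' Equilibrates the reference (wild-type) cell and returns the state
#' just after a division: the common starting point from which
#' heterogeneous cells are simulated.
#'
#' @param net a [cellcycle_network()].
#' @return Named state vector.
#' @export
cellcycle_baseline_state <- function(net) {
  eq <- limit_cycle_equilibrate(net)
  if (eq$arrested || !eq$converged) stop("reference cell failed to equilibrate")
  eq$state
}

#' Heterogeneous cell-cycle population study
#'
#' Samples `n` cells (lognormal multipliers, cv `cv`, on the network's
#' declared synthesis-rate subset), runs each from the common baseline
#' cycling state for `horizon` hours at the wild-type and at a given MYC
#' fold, and records division counts and settled cycle durations (mean
#' of the last three inter-division intervals; requires at least three
#' divisions).  Arrested cells (no division at wild type) are
#' re-simulated from their end state under the MYC fold to score rescue.
#'
#' @param net a [cellcycle_network()].
#' @param n number of cells.
#' @param myc_fold the perturbed MYC expression fold (default 1.5).
#' @param cv coefficient of variation of the multipliers.
#' @param seed seed for the multiplier draws.
#' @param horizon observation window (hours).
#' @param rescue if `TRUE` (default), re-simulate wild-type-arrested
#'   cells under the MYC fold and record whether they divide.
#' @return List with `cells` (data frame: multipliers, `ndiv_wt`,
#'   `len_wt`, `ndiv_myc`, `len_myc`, `arrested_wt`, `rescued`,
#'   `t_first_div_rescue`), `baseline_state`, and the arguments used.
#' @export
cellcycle_population <- function(net, n = 500, myc_fold = 1.5, cv = 0.25,
                                 seed = 1, horizon = 60, rescue = TRUE) {
  het <- net$heterogeneity
  base_state <- cellcycle_baseline_state(net)
  set.seed(seed)
  sdl <- sqrt(log(1 + cv^2))
  mult <- matrix(exp(rnorm(n * length(het), 0, sdl)), nrow = n,
                 dimnames = list(NULL, het))
  cells <- data.frame(cell = seq_len(n))
  cells$ndiv_wt <- NA_integer_; cells$len_wt <- NA_real_
  cells$ndiv_myc <- NA_integer_; cells$len_myc <- NA_real_
  cells$rescued <- NA
  cells$t_first_div_rescue <- NA_real_
  end_states <- vector("list", n)

  settled_len <- function(divs) {
    if (length(divs) < 3) return(NA_real_)
    mean(tail(diff(divs), 3))
  }
  for (i in seq_len(n)) {
    p <- net$parameters
    p[het] <- p[het] * mult[i, ]
    r_wt <- simulate_agent(net, params = p, x0 = base_state,
                           t_end = horizon, rtol = 1e-6, atol = 1e-8, dt = 2)
    cells$ndiv_wt[i] <- length(r_wt$divisions)
    cells$len_wt[i] <- settled_len(r_wt$divisions)
    cells$p27_end_wt[i] <- r_wt$state[["p27"]]
    end_states[[i]] <- r_wt$state

    p_m <- p
    p_m["tr_myc"] <- p_m["tr_myc"] * myc_fold
    r_m <- simulate_agent(net, params = p_m, x0 = base_state,
                          t_end = horizon, rtol = 1e-6, atol = 1e-8, dt = 2)
    cells$ndiv_myc[i] <- length(r_m$divisions)
    cells$len_myc[i] <- settled_len(r_m$divisions)
  }
  cells$arrested_wt <- cells$ndiv_wt == 0
  if (rescue) {
    for (i in which(cells$arrested_wt)) {
      p_m <- net$parameters
      p_m[het] <- p_m[het] * mult[i, ]
      p_m["tr_myc"] <- p_m["tr_myc"] * myc_fold
      r <- simulate_agent(net, params = p_m, x0 = end_states[[i]],
                          t_end = horizon, rtol = 1e-6, atol = 1e-8, dt = 2)
      cells$rescued[i] <- length(r$divisions) >= 1
      cells$t_first_div_rescue[i] <-
        if (length(r$divisions)) r$divisions[1] else NA_real_
    }
  }
  list(cells = cells, multipliers = mult, baseline_state = base_state,
       myc_fold = myc_fold, cv = cv, horizon = horizon, seed = seed)
}

#' Summary statistics of a cell-cycle population study
#'
#' @param pop result of [cellcycle_population()].
#' @return Named list: `arrested_pct` (percentage of wild-type cells
#'   with no division in the horizon), `rescued_pct` (percentage of
#'   those that divide at the MYC fold), `mean_len_wt` and
#'   `mean_len_myc` (hours, over cells cycling in the respective
#'   condition), `mean_shortening_min` (minutes).
#' @export
summarise_cellcycle_population <- function(pop) {
  cells <- pop$cells
  arrested_pct <- 100 * mean(cells$arrested_wt)
  resc <- cells$rescued[cells$arrested_wt]
  rescued_pct <- if (length(resc)) 100 * mean(resc, na.rm = TRUE) else NA_real_
  m_wt <- mean(cells$len_wt, na.rm = TRUE)
  m_my <- mean(cells$len_myc, na.rm = TRUE)
  list(arrested_pct = arrested_pct, rescued_pct = rescued_pct,
       mean_len_wt = m_wt, mean_len_myc = m_my,
       mean_shortening_min = 60 * (m_wt - m_my))
}
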