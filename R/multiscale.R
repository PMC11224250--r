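## Multi-scale agent-based population model: NF-kB input, fate events,
## weighted lineage bookkeeping.

#' Load the multi-scale B-cell network
#'
#' Reads the composite network (NF-kB signalling driving CYCD, MYC, IRF4
#' and BCL2; cell-cycle and apoptosis modules; BCL6/Blimp1
#' differentiation switch) from its YAML definition.  Division fires
#' when Cdh1 rises through 0.1 (mass halves); apoptosis removes the cell
#' when cleaved PARP exceeds 2500.
#'
#' @param config path to a YAML network definition; defaults to the
#'   packaged reduced network.
#' @return A [reaction_network()].
#' @export
multiscale_network <- function(config = NULL) {
  if (is.null(config)) {
    config <- system.file("extdata", "networks", "multiscale.yaml",
                          package = "bcellfate")
  }
  net <- read_network(config)
  required <- c("NFkB", "MYCt", "Myc", "IRF4", "Blimp1", "Bcl6",
                "mass", "Cdh1", "CycD", "CycE", "BCL2t", "cPARP")
  missing <- setdiff(required, net$species)
  if (length(missing)) {
    stop("multi-scale network config lacks mandatory species: ",
         paste(missing, collapse = ", "))
  }
  if (!all(c("division", "death") %in% names(net$events))) {
    stop("multi-scale config must declare division and death events")
  }
  net
}

#' IKK stimulus profile
#'
#' The NEMO:IKK input of the dynamic phase: a saturating pulse decaying
#' exponentially back to the basal level, clamped exactly to basal from
#' `return_to_basal_time` onwards.
#'
#' @param t time(s) in hours.
#' @param basal basal IKK activity.
#' @param peak initial pulse amplitude.
#' @param half_life decay half-life (hours).
#' @param return_to_basal_time time after which activity is exactly
#'   basal (hours).
#' @return IKK activity at `t`.
#' @export
stimulus_profile <- function(t, basal = 0.05, peak = 1.0, half_life = 12,
                             return_to_basal_time = 72) {
  ifelse(t >= return_to_basal_time, basal,
         basal + (peak - basal) * 2^(-t / half_life))
}

#' Equilibrate the multi-scale cell
#'
#' Runs the equilibration phase (basal IKK, enforced survival signal)
#' with division events until the mass-at-division criterion is met, and
#' returns the state just after a division.
#'
#' @param net a [multiscale_network()].
#' @param params optional parameter overrides (e.g. patient modifiers).
#' @param ... passed to [limit_cycle_equilibrate()].
#' @return Named state vector (just after division), with attributes
#'   `period` and `arrested`.
#' @export
multiscale_equilibrate <- function(net, params = NULL, ...) {
  eq <- limit_cycle_equilibrate(net, params = params,
                                phase = "equilibration", ...)
  st <- eq$state
  attr(st, "period") <- eq$period
  attr(st, "arrested") <- eq$arrested
  st
}

## Population trajectory container ------------------------------------------

new_population_trajectory <- function(event_time, event_weight, event_type,
                                      agent, generation, n_founders, t_end,
                                      truncated = FALSE) {
  o <- order(event_time)
  structure(list(events = data.frame(time = event_time[o],
                                     dweight = event_weight[o],
                                     type = event_type[o],
                                     agent = agent[o],
                                     generation = generation[o]),
                 n_founders = n_founders, t_end = t_end,
                 truncated = truncated),
            class = "population_trajectory")
}

#' @export
print.population_trajectory <- function(x, ...) {
  cat(sprintf("<population_trajectory> %d founders, %d events to t = %g h, final count %d%s\n",
              x$n_founders, nrow(x$events), x$t_end,
              population_count(x, x$t_end),
              if (x$truncated) " (truncated: runaway growth)" else ""))
  invisible(x)
}

#' Weighted live-cell count at given times
#'
#' The population count is piecewise constant between events: a division
#' doubles the lineage weight (adding `2^(divisions-1)` cells), a death
#' removes the lineage's current weight.
#'
#' @param traj a `population_trajectory`.
#' @param t time(s) in hours.
#' @return Integer count(s).
#' @export
population_count <- function(traj, t) {
  vapply(t, function(tt) {
    traj$n_founders + sum(traj$events$dweight[traj$events$time <= tt])
  }, numeric(1))
}

#' Simulate a weighted multi-scale cell population
#'
#' Each founder lineage is simulated as a single cell; at each division
#' the mother is replaced by one simulation standing for all daughters,
#' with lineage weight `2^(generation - 1)` per notional daughter pair,
#' so the lineage's count contribution doubles at every division (2
#' cells after the first division, 4 after the second, and so on).
#' Death removes the lineage's whole current weight.  Founders start
#' from the equilibrated state and differ by lognormal parameter
#' multipliers on the network's declared heterogeneity subset.
#'
#' @param net a [multiscale_network()].
#' @param modifiers list of [modifier()] objects (mutation fold
#'   changes), applied to every founder.
#' @param n_founders number of founder lineages.
#' @param cv cell-to-cell variability (lognormal cv; 0 = identical).
#' @param t_end simulated time (hours).
#' @param seed seed for the heterogeneity draws.
#' @param weight_cap population-weight cap; runs whose count would
#'   exceed it are truncated and flagged rather than aborted.
#' @param baseline_state optional pre-computed equilibrated state (from
#'   [multiscale_equilibrate()] with the same modifiers).
#' @return A `population_trajectory`.
#' @export
simulate_population <- function(net, modifiers = list(), n_founders = 30,
                                cv = 0.25, t_end = 96, seed = 1,
                                weight_cap = 1e6, baseline_state = NULL) {
  stopifnot(n_founders >= 1)
  params <- apply_modifiers(net$parameters, modifiers)
  if (is.null(baseline_state)) {
    baseline_state <- multiscale_equilibrate(net, params = params)
  }
  het <- net$heterogeneity
  set.seed(seed)
  sdl <- sqrt(log(1 + cv^2))
  mult <- matrix(exp(rnorm(n_founders * length(het), 0, sdl)),
                 nrow = n_founders, dimnames = list(NULL, het))

  ev_t <- numeric(0); ev_w <- numeric(0); ev_type <- character(0)
  ev_agent <- integer(0); ev_gen <- integer(0)
  truncated <- FALSE
  total_weight <- n_founders
  for (i in seq_len(n_founders)) {
    p <- params
    if (cv > 0) p[het] <- p[het] * mult[i, ]
    r <- simulate_agent(net, params = p, x0 = baseline_state,
                        t_end = t_end, phase = "dynamic",
                        rtol = 1e-6, atol = 1e-8, dt = 1)
    w <- 1
    gen <- 0L
    for (td in r$divisions) {
      gen <- gen + 1L
      ev_t <- c(ev_t, td); ev_w <- c(ev_w, w)
      ev_type <- c(ev_type, "division")
      ev_agent <- c(ev_agent, i); ev_gen <- c(ev_gen, gen)
      total_weight <- total_weight + w
      w <- 2 * w
      if (total_weight > weight_cap) { truncated <- TRUE; break }
    }
    if (!truncated && !is.na(r$death)) {
      ev_t <- c(ev_t, r$death); ev_w <- c(ev_w, -w)
      ev_type <- c(ev_type, "death")
      ev_agent <- c(ev_agent, i); ev_gen <- c(ev_gen, gen)
      total_weight <- total_weight - w
    }
    if (truncated) break
  }
  new_population_trajectory(ev_t, ev_w, ev_type, ev_agent, ev_gen,
                            n_founders, t_end, truncated)
}

#' Brute-force population simulation spawning both daughters
#'
#' Reference implementation for validating the weighted single-lineage
#' bookkeeping: every division spawns two independently simulated
#' daughter cells (identical state, mass halved).  Only feasible for a
#' handful of generations; used with `cv = 0` the resulting counts must
#' equal the weighted simulation exactly.
#'
#' @param net a [multiscale_network()].
#' @param modifiers list of [modifier()] objects.
#' @param t_end simulated time (hours).
#' @param max_cells safety cap on the number of simulated cells.
#' @param baseline_state optional pre-computed equilibrated state.
#' @return A list with `events` (time, dcount) and `count_at(t)` usable
#'   via [population_count()]-like summation.
#' @export
simulate_population_bruteforce <- function(net, modifiers = list(),
                                           t_end = 96, max_cells = 256,
                                           baseline_state = NULL) {
  params <- apply_modifiers(net$parameters, modifiers)
  if (is.null(baseline_state)) {
    baseline_state <- multiscale_equilibrate(net, params = params)
  }
  ## queue of (state, start time)
  queue <- list(list(x = baseline_state, t0 = 0))
  ev_t <- numeric(0); ev_d <- numeric(0)
  n_sim <- 0
  while (length(queue) > 0) {
    item <- queue[[1]]; queue <- queue[-1]
    n_sim <- n_sim + 1
    if (n_sim > max_cells) stop("brute-force population exceeded max_cells")
    r <- simulate_agent(net, params = params, x0 = item$x,
                        t_start = item$t0, t_end = t_end,
                        phase = "dynamic", rtol = 1e-6, atol = 1e-8,
                        dt = 1, stop_at_division = TRUE)
    if (length(r$divisions) >= 1) {
      td <- r$divisions[1]
      ev_t <- c(ev_t, td); ev_d <- c(ev_d, 1)    # one mother -> two daughters
      xd <- r$state                              # post-division (mass halved)
      queue <- c(queue, list(list(x = xd, t0 = td), list(x = xd, t0 = td)))
    } else if (!is.na(r$death)) {
      ev_t <- c(ev_t, r$death); ev_d <- c(ev_d, -1)
    }
  }
  o <- order(ev_t)
  list(events = data.frame(time = ev_t[o], dcount = ev_d[o]),
       n_founders = 1,
       count_at = function(t) 1 + sum(ev_d[o][ev_t[o] <= t]))
}
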