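## Isolated apoptosis network: construction, death readouts, dose response.

#' Load the apoptosis network
#'
#' Reads the reduced intrinsic-apoptosis network (Bcl2-buffered MOMP
#' switch) from its YAML definition and checks the mandatory structure:
#' BCL2 mRNA and protein, a pro-apoptotic activator, mitochondrial and
#' cytoplasmic cytochrome-c and Smac pools, a caspase, and a conserved
#' PARP/cleaved-PARP pair.  An alternative definition file (for example
#' a fuller published topology) can be supplied as `config`.
#'
#' @param config path to a YAML network definition; defaults to the
#'   packaged reduced network.
#' @param bcl2_param name of the BCL2 transcription-rate parameter (the
#'   mutation target).
#' @return A [reaction_network()].
#' @export
apoptosis_network <- function(config = NULL, bcl2_param = "tr_bcl2") {
  if (is.null(config)) {
    config <- system.file("extdata", "networks", "apoptosis.yaml",
                          package = "bcellfate")
  }
  net <- read_network(config)
  required <- c("BCL2t", "Bcl2", "Act", "CytoCm", "cCytoC", "Smacm",
                "cSmac", "Casp3", "PARP", "cPARP")
  missing <- setdiff(required, net$species)
  if (length(missing)) {
    stop("apoptosis network config lacks mandatory species: ",
         paste(missing, collapse = ", "))
  }
  if (!bcl2_param %in% names(net$parameters)) {
    stop(sprintf("apoptosis config does not define the BCL2 transcription parameter '%s'",
                 bcl2_param))
  }
  net
}

#' Time to death from a simulation trace
#'
#' Death is the first time at which more than `threshold` (default 10%)
#' of total PARP is cleaved; the crossing is linearly interpolated
#' between output points.  Returns `Inf` ("survived") when the fraction
#' never crosses within the trace.
#'
#' @param trace a `sim_trace` containing `PARP` and `cPARP`.
#' @param threshold cleaved fraction defining death.
#' @return Time of death in hours, or `Inf` if the cell survives.
#' @export
time_to_death <- function(trace, threshold = 0.10) {
  if (!all(c("PARP", "cPARP") %in% colnames(trace$values))) {
    stop("trace lacks PARP / cPARP")
  }
  frac <- cleaved_fraction(trace)
  above <- frac > threshold
  if (!any(above)) return(Inf)
  i <- which(above)[1]
  if (i == 1) return(trace$times[1])
  t1 <- trace$times[i - 1]; t2 <- trace$times[i]
  f1 <- frac[i - 1]; f2 <- frac[i]
  t1 + (threshold - f1) / (f2 - f1) * (t2 - t1)
}

#' Cleaved-PARP fraction over a trace
#'
#' @param trace a `sim_trace` containing `PARP` and `cPARP`.
#' @return Numeric vector of cleaved fractions in `[0, 1]`.
#' @export
cleaved_fraction <- function(trace) {
  cp <- trace$values[, "cPARP"]
  tot <- cp + trace$values[, "PARP"]
  cp / tot
}

#' Simulate the apoptosis network through both phases
#'
#' Equilibrates under the enforced survival signal, then runs the
#' death-permissive dynamic phase from the equilibrium state.
#'
#' @param net an [apoptosis_network()].
#' @param params optional named parameter overrides (already including
#'   any mutation fold changes).
#' @param horizon length of the dynamic phase (hours).
#' @param stop_at_death if `TRUE`, stop integrating once the death
#'   threshold is crossed (faster for population scans); the returned
#'   trace then ends shortly after death.
#' @param threshold cleaved fraction defining death.
#' @param rtol,atol solver tolerances.
#' @return A `sim_trace` of the dynamic phase (time 0 = start of the
#'   dynamic phase).
#' @export
simulate_apoptosis <- function(net, params = NULL, horizon = 140,
                               stop_at_death = FALSE, threshold = 0.10,
                               rtol = 1e-6, atol = 1e-9) {
  xeq <- run_to_steady_state(net, params = params, phase = "equilibration",
                             max_t = 600, derivative_tol = 1e-7)
  p <- phase_params(net, params, "dynamic")
  set_params(net, p)
  times <- seq(0, horizon, by = 0.25)
  if (stop_at_death) {
    i_p <- match("PARP", net$species); i_cp <- match("cPARP", net$species)
    rootf <- function(t, x, parms) x[i_cp] / (x[i_cp] + x[i_p]) - threshold
    out <- deSolve::lsodar(xeq, times, net$compiled$deriv, parms = NULL,
                           rootfunc = rootf, rtol = rtol, atol = atol)
  } else {
    out <- deSolve::lsoda(xeq, times, net$compiled$deriv, parms = NULL,
                          rtol = rtol, atol = atol)
  }
  vals <- out[, -1, drop = FALSE]
  colnames(vals) <- net$species
  new_trace(out[, 1], vals, p)
}

#' BCL2 gene-dose response of the time to death
#'
#' Each extra gene copy contributes half of the normal expression rate,
#' so `d` extra copies correspond to a `1 + d/2`-fold BCL2 transcription
#' rate.  Cells whose cleaved-PARP fraction never crosses 10% within the
#' horizon are reported as survivors (`Inf`).
#'
#' @param net an [apoptosis_network()].
#' @param extra_copies numeric vector of extra BCL2 copies (>= 0).
#' @param horizon dynamic-phase length in hours (default the 140-h
#'   simulation window).
#' @param bcl2_param name of the BCL2 transcription parameter.
#' @return Data frame with `extra_copies`, `fold`, `time_to_death`.
#' @export
bcl2_dose_response <- function(net, extra_copies = 0:6, horizon = 140,
                               bcl2_param = "tr_bcl2") {
  stopifnot(all(extra_copies >= 0))
  folds <- 1 + extra_copies / 2
  ttd <- vapply(folds, function(f) {
    mods <- list(modifier(bcl2_param, f))
    p <- apply_modifiers(net$parameters, mods)
    tr <- simulate_apoptosis(net, params = p, horizon = horizon,
                             stop_at_death = TRUE)
    time_to_death(tr)
  }, numeric(1))
  data.frame(extra_copies = extra_copies, fold = folds,
             time_to_death = ttd)
}

#' Heterogeneous-population death times
#'
#' Samples `n` cells with lognormal parameter multipliers (median 1,
#' coefficient of variation `cv`, applied to the network's declared
#' synthesis/degradation subset) and computes each cell's time to death
#' at a given BCL2 transcription fold.  With a fixed seed the same `n`
#' cells are drawn for every fold, so conditions are paired cell by
#' cell.
#'
#' @param net an [apoptosis_network()].
#' @param n number of cells.
#' @param bcl2_fold BCL2 transcription fold (scalar or vector; one
#'   column per fold is returned).
#' @param cv coefficient of variation of the multipliers.
#' @param seed seed for the multiplier draws.
#' @param horizon dynamic-phase length (hours).
#' @return Data frame with one row per cell: `cell`, and a
#'   `ttd_<fold>` column per requested fold (hours; `Inf` = survived).
#' @export
apoptosis_population <- function(net, n = 1000, bcl2_fold = c(1, 1.5),
                                 cv = 0.25, seed = 1, horizon = 140) {
  het <- net$heterogeneity
  set.seed(seed)
  sdl <- sqrt(log(1 + cv^2))
  mult <- matrix(exp(rnorm(n * length(het), 0, sdl)), nrow = n,
                 dimnames = list(NULL, het))
  out <- data.frame(cell = seq_len(n))
  for (f in bcl2_fold) {
    ttd <- numeric(n)
    for (i in seq_len(n)) {
      p <- net$parameters
      p[het] <- p[het] * mult[i, ]
      p["tr_bcl2"] <- p["tr_bcl2"] * f
      tr <- simulate_apoptosis(net, params = p, horizon = horizon,
                               stop_at_death = TRUE)
      ttd[i] <- time_to_death(tr)
    }
    out[[sprintf("ttd_%g", f)]] <- ttd
  }
  out
}
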