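## Integration engine: parameter modifiers, trace container, steady state,
## event-aware agent simulation, limit-cycle equilibration.

#' Parameter modifier
#'
#' A `(parameter, fold-change)` pair describing the effect of one genetic
#' lesion on one model parameter.  Fold changes must be strictly positive;
#' several modifiers hitting the same parameter combine multiplicatively,
#' so application order never matters.
#'
#' @param parameter_id name of the target parameter.
#' @param fold_change positive multiplicative change.
#' @return An object of class `param_modifier`.
#' @export
modifier <- function(parameter_id, fold_change) {
  stopifnot(is.character(parameter_id), length(parameter_id) == 1)
  fold_change <- as.numeric(fold_change)
  if (!is.finite(fold_change) || fold_change <= 0) {
    stop("fold_change must be a positive number")
  }
  structure(list(parameter_id = parameter_id, fold_change = fold_change),
            class = "param_modifier")
}

#' Apply parameter modifiers to a base parameter set
#'
#' Each modifier multiplies its target parameter by its fold change;
#' modifiers sharing a target combine multiplicatively (two 1.5-fold
#' activating lesions on the same kinase yield a 2.25-fold increase).
#' Unlisted parameters are returned unchanged.
#'
#' @param base named numeric vector of parameters.
#' @param mods list of [modifier()] objects (possibly empty).
#' @return Modified named parameter vector.
#' @export
apply_modifiers <- function(base, mods) {
  stopifnot(is.numeric(base), !is.null(names(base)))
  out <- base
  if (length(mods) == 0) return(out)
  ids <- character(length(mods))
  folds <- numeric(length(mods))
  for (k in seq_along(mods)) {
    m <- mods[[k]]
    if (!inherits(m, "param_modifier")) {
      m <- modifier(m$parameter_id, m$fold_change)
    }
    if (!m$parameter_id %in% names(out)) {
      stop(sprintf("modifier targets unknown parameter '%s' (stale gene map?)",
                   m$parameter_id))
    }
    ids[k] <- m$parameter_id
    folds[k] <- m$fold_change
  }
  ## canonical (sorted) multiplication order, so that any permutation of
  ## the same modifier multiset yields a bitwise-identical result
  for (id in unique(ids)) {
    f <- sort(folds[ids == id])
    out[id] <- out[id] * prod(f)
  }
  out
}

## Simulation trace ----------------------------------------------------------

new_trace <- function(times, values, params) {
  structure(list(times = times, values = values, params_used = params),
            class = "sim_trace")
}

#' @export
print.sim_trace <- function(x, ...) {
  cat(sprintf("<sim_trace> %d species x %d time points, t in [%g, %g] h\n",
              ncol(x$values), length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Interpolate a species abundance at arbitrary times
#'
#' Linear interpolation within the simulated time range.
#'
#' @param trace a `sim_trace` from [integrate_network()].
#' @param species species name.
#' @param t time(s) in hours, within the trace range.
#' @return Numeric vector of abundances.
#' @export
trace_at <- function(trace, species, t) {
  if (!species %in% colnames(trace$values)) {
    stop(sprintf("species '%s' not in trace", species))
  }
  if (any(t < min(trace$times) - 1e-9) || any(t > max(trace$times) + 1e-9)) {
    stop("interpolation time outside trace range")
  }
  approx(trace$times, trace$values[, species], xout = t, rule = 2)$y
}

#' Integrate a reaction network
#'
#' Solves the network ODEs with a stiff-capable solver (`deSolve::lsoda`)
#' on a dense output grid.  Abundances are reported as solved; tiny
#' negative excursions within solver tolerance are clipped to zero in the
#' returned trace only.
#'
#' @param net a [reaction_network()].
#' @param params optional named overrides of network parameters.
#' @param t_span numeric length-2, start and end time in hours.
#' @param rtol,atol solver tolerances.
#' @param n_out number of output points (default gives interpolation
#'   error well below `10 * atol` for the reference networks).
#' @param phase optional phase name whose parameter overrides to apply.
#' @param x0 optional initial state (defaults to the network's).
#' @return A `sim_trace` with `times`, species `values` and the resolved
#'   parameter set.
#' @export
integrate_network <- function(net, params = NULL, t_span = c(0, 12),
                              rtol = 1e-6, atol = 1e-9, n_out = NULL,
                              phase = NULL, x0 = NULL) {
  stopifnot(length(t_span) == 2, t_span[2] > t_span[1])
  if (is.null(x0)) x0 <- net$initial_state else force(x0)
  p <- phase_params(net, params, phase)
  set_params(net, p)
  if (is.null(n_out)) n_out <- max(200L, ceiling((t_span[2] - t_span[1]) * 20))
  times <- seq(t_span[1], t_span[2], length.out = n_out)
  out <- deSolve::lsoda(x0, times, net$compiled$deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) {
    stop(sprintf("integration of '%s' failed at t = %.4g h",
                 net$name, out[nrow(out), 1]))
  }
  vals <- out[, -1, drop = FALSE]
  vals[vals < 0 & vals > -atol * 10] <- 0
  colnames(vals) <- net$species
  new_trace(out[, 1], vals, p)
}

#' Run a network to steady state
#'
#' Integrates in chunks until the largest relative rate of change
#' `|dx/dt| / (|x| + atol)` drops below `derivative_tol`, or `max_t` is
#' reached (in which case the result carries a `converged = FALSE`
#' attribute and a warning is raised).  Intended for non-oscillatory
#' phases (the cell-cycle module uses [limit_cycle_equilibrate()]
#' instead).
#'
#' @param net a [reaction_network()].
#' @param params optional parameter overrides.
#' @param max_t maximum simulated time (hours).
#' @param derivative_tol convergence threshold on the relative derivative.
#' @param phase optional phase name (typically `"equilibration"`).
#' @param x0 optional initial state.
#' @param atol absolute tolerance (also used in the convergence test).
#' @return Named state vector at steady state, with attribute `converged`.
#' @export
run_to_steady_state <- function(net, params = NULL, max_t = 1000,
                                derivative_tol = 1e-6, phase = NULL,
                                x0 = NULL, atol = 1e-9) {
  x <- if (is.null(x0)) net$initial_state else x0
  p <- phase_params(net, params, phase)
  set_params(net, p)
  t_now <- 0
  chunk <- max_t / 20
  repeat {
    out <- deSolve::lsoda(x, c(t_now, t_now + chunk), net$compiled$deriv,
                          parms = NULL, rtol = 1e-8, atol = atol)
    x <- out[nrow(out), -1]
    t_now <- t_now + chunk
    dx <- unlist(net$compiled$deriv(t_now, x, NULL))
    rel <- max(abs(dx) / (abs(x) + atol))
    if (rel < derivative_tol) {
      names(x) <- net$species
      attr(x, "converged") <- TRUE
      return(x)
    }
    if (t_now >= max_t) {
      warning(sprintf("steady state of '%s' not reached by t = %g (max rel. derivative %.3g)",
                      net$name, max_t, rel))
      names(x) <- net$species
      attr(x, "converged") <- FALSE
      return(x)
    }
  }
}

## Event-aware simulation ----------------------------------------------------

#' Simulate one cell with fate events
#'
#' Integrates the network while locating the roots of the event
#' expressions declared in the network config (e.g. division when Cdh1
#' rises through 0.1, death when cleaved PARP exceeds its threshold).
#' Roots are located by the solver's own root finder (bisection on the
#' trigger expression between steps), not by grid sampling.  On a
#' division event the configured reset (mass halving) is applied and the
#' integration restarts; a death event terminates the cell.  If death and
#' division would fire simultaneously, death takes precedence.
#'
#' @param net a [reaction_network()] with an `events` block.
#' @param params optional parameter overrides.
#' @param x0 initial state (defaults to the network's).
#' @param t_end end of simulation (hours).
#' @param phase optional phase name.
#' @param rtol,atol solver tolerances.
#' @param record if `TRUE`, keep the dense trace (slower).
#' @param dt output grid spacing when `record = TRUE`.
#' @param t_start absolute start time (hours); time-dependent inputs
#'   (the IKK stimulus) see absolute time, so daughter cells spawned
#'   mid-simulation pass their birth time here.
#' @param stop_at_division if `TRUE`, return immediately after the first
#'   division (reset applied), leaving `state` ready to seed daughters.
#' @return List with `divisions` (absolute times), `death` (absolute
#'   time or `NA`), `state` (end, death, or post-division state), and
#'   optionally `trace`.
#' @export
simulate_agent <- function(net, params = NULL, x0 = NULL, t_end = 96,
                           phase = NULL, rtol = 1e-6, atol = 1e-8,
                           record = FALSE, dt = 0.5, t_start = 0,
                           stop_at_division = FALSE) {
  if (is.null(net$compiled$root_fun)) stop("network declares no events")
  x <- if (is.null(x0)) net$initial_state else x0
  p <- phase_params(net, params, phase)
  set_params(net, p)
  ev_names <- net$compiled$event_names
  ev_dir <- vapply(net$events, function(e) e$direction %||% "up", character(1))
  is_death <- vapply(net$events, function(e) isTRUE(e$terminal), logical(1))

  t_now <- t_start
  divisions <- numeric(0)
  death <- NA_real_
  traj <- NULL
  repeat {
    tt <- seq(t_now, t_end, by = dt)
    if (length(tt) < 2 || tail(tt, 1) < t_end) tt <- c(tt, t_end)
    set_params(net, p)   # guard against nested integrations of this net
    out <- deSolve::lsodar(x, tt, net$compiled$deriv, parms = NULL,
                           rootfunc = net$compiled$root_fun,
                           rtol = rtol, atol = atol)
    if (record) traj <- rbind(traj, out[-nrow(out), , drop = FALSE])
    t_last <- out[nrow(out), 1]
    x <- out[nrow(out), -1]
    if (t_last >= t_end - 1e-9) break

    ## identify which root fired and its direction
    g <- net$compiled$root_fun(t_last, x, NULL)
    dx <- unlist(net$compiled$deriv(t_last, x, NULL))
    ir <- attr(out, "iroot")
    fired <- if (!is.null(ir) && any(ir == 1)) which(ir == 1) else {
      f <- which(abs(g) < 1e-6)
      if (length(f) == 0) which.min(abs(g)) else f
    }
    handled <- FALSE
    ## death takes precedence when several roots coincide
    fired <- fired[order(!is_death[fired])]
    for (k in fired) {
      ## direction of crossing from the root-expression time derivative
      eps <- 1e-4
      g2 <- net$compiled$root_fun(t_last + eps, x + dx * eps, NULL)
      rising <- g2[k] > g[k]
      want <- ev_dir[k]
      if ((want == "up" && !rising) || (want == "down" && rising)) next
      if (is_death[k]) {
        death <- t_last
        handled <- TRUE
        break
      }
      divisions <- c(divisions, t_last)
      rs <- net$compiled$resets[[ev_names[k]]]
      if (!is.null(rs)) x <- rs(x)
      handled <- TRUE
      break
    }
    if (!is.na(death)) break
    if (stop_at_division && length(divisions) > 0) break
    t_now <- t_last + 1e-6
    if (t_now >= t_end) break
  }
  names(x) <- net$species
  res <- list(divisions = divisions, death = death, state = x)
  if (record && !is.null(traj)) {
    vals <- traj[, -1, drop = FALSE]
    colnames(vals) <- net$species
    res$trace <- new_trace(traj[, 1], vals, p)
  }
  res
}

#' Equilibrate a dividing cell onto its limit cycle
#'
#' Runs the network with division events until the mass reached just
#' before each division is identical (to `digits` decimal places) for
#' `n_consecutive` consecutive cycles.  Returns the state just after a
#' division on the settled cycle, its period, and an `arrested` flag if
#' no division occurs within `max_t`.
#'
#' @param net a [reaction_network()] whose events include `division` with
#'   a mass-halving reset; the mass species is named in
#'   `net$events$division$mass` (default `"mass"`).
#' @param params optional parameter overrides.
#' @param x0 optional starting state.
#' @param max_cycles maximum number of divisions before giving up.
#' @param digits decimal places for the mass criterion.
#' @param n_consecutive number of consecutive equal masses required.
#' @param max_t simulation-time cap (hours); reached without any division
#'   means an arrest verdict.
#' @param phase optional phase name.
#' @return List with `state` (just after division), `period` (hours),
#'   `mass_at_division`, `arrested` (logical), `converged` (logical).
#' @export
limit_cycle_equilibrate <- function(net, params = NULL, x0 = NULL,
                                    max_cycles = 60, digits = 3,
                                    n_consecutive = 5, max_t = 900,
                                    phase = NULL) {
  if (!"division" %in% names(net$events)) {
    stop("network has no 'division' event")
  }
  x <- if (is.null(x0)) net$initial_state else x0
  p <- phase_params(net, params, phase)
  set_params(net, p)
  mass_name <- net$events$division$mass %||% "mass"
  k_div <- match("division", net$compiled$event_names)
  ev_dir <- net$events$division$direction %||% "up"

  t_now <- 0
  masses <- numeric(0)
  div_times <- numeric(0)
  repeat {
    tt <- seq(t_now, min(t_now + 40, max_t), by = 0.5)
    if (length(tt) < 2) break
    set_params(net, p)
    out <- deSolve::lsodar(x, tt, net$compiled$deriv, parms = NULL,
                           rootfunc = net$compiled$root_fun,
                           rtol = 1e-7, atol = 1e-9)
    t_last <- out[nrow(out), 1]
    x <- out[nrow(out), -1]
    if (t_last >= max_t - 1e-9) break
    if (t_last >= tail(tt, 1) - 1e-9) { t_now <- t_last; next }
    g <- net$compiled$root_fun(t_last, x, NULL)
    dx <- unlist(net$compiled$deriv(t_last, x, NULL))
    if (abs(g[k_div]) < 1e-6) {
      eps <- 1e-4
      g2 <- net$compiled$root_fun(t_last + eps, x + dx * eps, NULL)
      rising <- g2[k_div] > g[k_div]
      ok <- (ev_dir == "up" && rising) || (ev_dir == "down" && !rising)
      if (ok) {
        masses <- c(masses, x[[match(mass_name, net$species)]])
        div_times <- c(div_times, t_last)
        rs <- net$compiled$resets[["division"]]
        if (!is.null(rs)) x <- rs(x)
        n <- length(masses)
        if (n >= n_consecutive) {
          recent <- round(tail(masses, n_consecutive), digits)
          if (diff(range(recent)) == 0) {
            names(x) <- net$species
            return(list(state = x,
                        period = mean(tail(diff(div_times), n_consecutive - 1)),
                        mass_at_division = tail(masses, 1),
                        arrested = FALSE, converged = TRUE))
          }
        }
        if (n >= max_cycles) {
          stop(sprintf("limit cycle of '%s' still drifting after %d cycles",
                       net$name, max_cycles))
        }
      }
    }
    t_now <- t_last + 1e-6
  }
  names(x) <- net$species
  list(state = x, period = NA_real_, mass_at_division = NA_real_,
       arrested = length(div_times) == 0, converged = FALSE)
}

#' Sample cell-to-cell variability multipliers
#'
#' Draws independent lognormal multipliers (median 1, coefficient of
#' variation `cv`) for the selected parameters, mirroring the
#' distributed-parameter representation of cell-to-cell variability.
#' With `cv = 0` the base parameters are returned unchanged.
#'
#' @param base named parameter vector.
#' @param cv coefficient of variation of the multipliers (default 0.25).
#' @param which parameter names to distribute (defaults to the network's
#'   `heterogeneity` list when called through higher-level wrappers).
#' @param n number of parameter sets to draw.
#' @param seed optional seed for reproducibility.
#' @return If `n == 1`, a modified parameter vector; otherwise a list of
#'   parameter vectors.
#' @export
sample_heterogeneous_parameters <- function(base, cv = 0.25, which,
                                            n = 1, seed = NULL) {
  stopifnot(cv >= 0, all(which %in% names(base)))
  if (!is.null(seed)) set.seed(seed)
  draw1 <- function() {
    if (cv == 0) return(base)
    sdl <- sqrt(log(1 + cv^2))
    mult <- exp(rnorm(length(which), 0, sdl))
    out <- base
    out[which] <- out[which] * mult
    out
  }
  if (n == 1) draw1() else replicate(n, draw1(), simplify = FALSE)
}
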