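#' @importFrom stats rnorm runif rexp rbinom setNames quantile median sd approx pchisq pnorm coef stepfun
#' @importFrom utils read.csv write.csv read.delim head tail
NULL

## Helper kinetic laws available inside rate expressions ---------------------

#' Hill activation term
#'
#' Convenience kinetic law `x^n / (K^n + x^n)` usable inside network rate
#' expressions.
#'
#' @param x activator abundance.
#' @param K half-saturation constant.
#' @param n Hill coefficient.
#' @return Value in `[0, 1]`.
#' @export
hill <- function(x, K, n) {
  xn <- x^n
  xn / (K^n + xn)
}

#' Tight-binding complex concentration
#'
#' Amount of complex formed between two partners in rapid binding
#' equilibrium with dissociation constant `K` (the standard quadratic
#' solution, numerically safe for `K` much smaller than the pools).
#'
#' @param L,R total abundances of the two partners.
#' @param K dissociation constant.
#' @return Complex abundance, `<= min(L, R)`.
#' @export
bound_pair <- function(L, R, K) {
  s <- L + R + K
  (s - sqrt(s * s - 4 * L * R)) / 2
}

## names usable in rate expressions beyond species/parameters/inputs
.rate_builtins <- c("hill", "bound_pair", "min", "max", "pmin", "pmax",
                    "exp", "log", "sqrt", "abs", "ifelse", "t", "pi")

## ReactionNetwork -----------------------------------------------------------

#' Build a reaction network
#'
#' A `reaction_network` is a declarative description of one signalling
#' module: named species with initial abundances, named nonnegative
#' parameters, a list of rate terms (text expressions over species,
#' parameters and inputs) with stoichiometries, optional time-dependent
#' input expressions, named simulation phases (parameter overrides, e.g.
#' an equilibration phase with an enforced survival signal), and optional
#' event definitions (root expressions with reset rules) used by the
#' agent-based simulator.
#'
#' Networks are normally loaded from YAML with [read_network()]; this
#' constructor validates and compiles an already-parsed description.
#'
#' @param spec a list with elements `name`, `species`, `parameters`,
#'   `rates`, and optionally `inputs`, `phases`, `events`,
#'   `heterogeneity`, `conserved`, `readouts`.
#' @return An object of class `reaction_network`.
#' @export
reaction_network <- function(spec) {
  stopifnot(is.list(spec), !is.null(spec$name), !is.null(spec$species),
            !is.null(spec$parameters), !is.null(spec$rates))

  sp_names <- vapply(spec$species, function(s) s$name, character(1))
  x0 <- vapply(spec$species, function(s) as.numeric(s$initial), numeric(1))
  names(x0) <- sp_names
  if (anyDuplicated(sp_names)) stop("duplicate species names")
  if (any(x0 < 0)) stop("negative initial abundance")

  par_names <- vapply(spec$parameters, function(p) p$name, character(1))
  pars <- vapply(spec$parameters, function(p) as.numeric(p$value), numeric(1))
  names(pars) <- par_names
  if (anyDuplicated(par_names)) stop("duplicate parameter names")
  if (any(pars < 0)) stop("negative parameter value")
  if (any(sp_names %in% par_names)) stop("species/parameter name collision")

  input_names <- character(0)
  if (!is.null(spec$inputs)) {
    input_names <- vapply(spec$inputs, function(i) i$name, character(1))
  }

  known <- c(sp_names, par_names, input_names, .rate_builtins)
  check_expr <- function(txt, where) {
    vars <- all.names(parse(text = txt)[[1]])
    bad <- setdiff(vars, c(known,
                           c("+", "-", "*", "/", "^", "(", "c", "<", ">",
                             "<=", ">=", "==", "if")))
    if (length(bad) > 0) {
      stop(sprintf("unresolved symbol(s) in %s: %s",
                   where, paste(bad, collapse = ", ")))
    }
  }
  if (!is.null(spec$inputs)) {
    for (i in spec$inputs) check_expr(i$expr, paste("input", i$name))
  }
  for (k in seq_along(spec$rates)) {
    r <- spec$rates[[k]]
    check_expr(r$expr, paste("rate", k))
    if (!all(names(r$stoich) %in% sp_names)) {
      stop(sprintf("rate %d: stoichiometry names unknown species", k))
    }
  }
  if (!is.null(spec$events)) {
    for (ev in names(spec$events)) {
      check_expr(spec$events[[ev]]$root, paste("event", ev))
      for (rs in names(spec$events[[ev]]$reset %||% list())) {
        check_expr(spec$events[[ev]]$reset[[rs]], paste("reset of", ev))
      }
    }
  }
  if (!is.null(spec$heterogeneity) &&
      !all(unlist(spec$heterogeneity) %in% par_names)) {
    stop("heterogeneity lists unknown parameters")
  }

  net <- structure(
    list(name = spec$name,
         species = sp_names,
         initial_state = x0,
         parameters = pars,
         rates = spec$rates,
         inputs = spec$inputs %||% list(),
         phases = lapply(spec$phases %||% list(), function(ph)
           unlist(ph)),
         events = spec$events %||% list(),
         heterogeneity = unlist(spec$heterogeneity %||% character(0)),
         conserved = spec$conserved %||% list(),
         readouts = unlist(spec$readouts %||% character(0))),
    class = "reaction_network")
  net$compiled <- compile_network(net)
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a reaction network from a YAML definition file
#'
#' @param path path to a YAML network definition (see the files under
#'   `system.file("extdata/networks", package = "bcellfate")` for the
#'   format).
#' @return A [reaction_network()] object.
#' @export
read_network <- function(path) {
  spec <- yaml::read_yaml(path)
  reaction_network(spec)
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %s: %d species, %d parameters, %d rate terms\n",
              x$name, length(x$species), length(x$parameters),
              length(x$rates)))
  if (length(x$phases)) {
    cat("  phases:", paste(names(x$phases), collapse = ", "), "\n")
  }
  if (length(x$events)) {
    cat("  events:", paste(names(x$events), collapse = ", "), "\n")
  }
  invisible(x)
}

## Compilation ---------------------------------------------------------------

## Generate a fast derivative function: species are unpacked by index,
## parameters live in the enclosing environment (reassigned cheaply on
## each parameter change), rate expressions are substituted inline and
## the state derivative assembled from the stoichiometry.
compile_network <- function(net) {
  nsp <- length(net$species)
  env <- new.env(parent = asNamespace("bcellfate"))
  for (nm in names(net$parameters)) assign(nm, net$parameters[[nm]], envir = env)

  unpack <- paste(sprintf("%s <- x[%d]", net$species, seq_len(nsp)),
                  collapse = "\n    ")
  input_lines <- ""
  if (length(net$inputs)) {
    input_lines <- paste(
      vapply(net$inputs, function(i) sprintf("%s <- (%s)", i$name, i$expr),
             character(1)),
      collapse = "\n    ")
  }

  ## per-species derivative as a sum of stoich * rate
  terms <- rep("0", nsp)
  names(terms) <- net$species
  rate_lines <- character(length(net$rates))
  for (k in seq_along(net$rates)) {
    r <- net$rates[[k]]
    rate_lines[k] <- sprintf(".r%d <- (%s)", k, r$expr)
    for (sp in names(r$stoich)) {
      coef <- as.numeric(r$stoich[[sp]])
      piece <- if (coef == 1) sprintf(".r%d", k)
               else if (coef == -1) sprintf("- .r%d", k)
               else sprintf("%g * .r%d", coef, k)
      terms[sp] <- if (terms[sp] == "0") {
        if (coef == -1) piece else piece
      } else paste(terms[sp], if (coef < 0) piece else paste("+", piece))
    }
  }
  body_txt <- sprintf(
    "function(t, x, parms) {\n    x <- unname(x)\n    %s\n    %s\n    %s\n    list(c(%s))\n  }",
    unpack, input_lines, paste(rate_lines, collapse = "\n    "),
    paste(terms, collapse = ",\n          "))
  deriv <- compiler::cmpfun(eval(parse(text = body_txt), envir = env))

  ## event root functions (vector of root expressions, fixed order);
  ## only the species and algebraic inputs the root expressions actually
  ## reference are evaluated -- root functions are called at every solver
  ## step, so this matters for speed
  root_fun <- NULL
  ev_names <- names(net$events)
  if (length(ev_names)) {
    roots <- vapply(ev_names, function(e) net$events[[e]]$root, character(1))
    input_names <- vapply(net$inputs, function(i) i$name, character(1))
    need <- unique(unlist(lapply(roots, function(r)
      all.vars(parse(text = r)[[1]]))))
    ## transitively pull in referenced inputs and their dependencies
    repeat {
      more <- unique(unlist(lapply(net$inputs[input_names %in% need],
                                   function(i)
                                     all.vars(parse(text = i$expr)[[1]]))))
      new <- setdiff(more, need)
      if (length(new) == 0) break
      need <- c(need, new)
    }
    sp_idx <- which(net$species %in% need)
    unpack_r <- if (length(sp_idx)) {
      paste(sprintf("%s <- x[%d]", net$species[sp_idx], sp_idx),
            collapse = "\n    ")
    } else ""
    inputs_r <- if (any(input_names %in% need)) {
      paste(vapply(net$inputs[input_names %in% need],
                   function(i) sprintf("%s <- (%s)", i$name, i$expr),
                   character(1)),
            collapse = "\n    ")
    } else ""
    root_txt <- sprintf(
      "function(t, x, parms) {\n    x <- unname(x)\n    %s\n    %s\n    c(%s)\n  }",
      unpack_r, inputs_r, paste(roots, collapse = ",\n      "))
    root_fun <- compiler::cmpfun(eval(parse(text = root_txt), envir = env))
  }

  ## reset functions: state -> state
  resets <- list()
  for (e in ev_names) {
    rs <- net$events[[e]]$reset
    if (is.null(rs)) next
    lines <- vapply(names(rs), function(sp) {
      sprintf("x[%d] <- (%s)", match(sp, net$species), rs[[sp]])
    }, character(1))
    txt <- sprintf("function(x) {\n    %s\n    %s\n    x\n  }",
                   unpack, paste(lines, collapse = "\n    "))
    resets[[e]] <- compiler::cmpfun(eval(parse(text = txt), envir = env))
  }

  list(env = env, deriv = deriv, root_fun = root_fun, resets = resets,
       event_names = ev_names)
}

## Push a parameter vector into the compiled environment.
set_params <- function(net, params) {
  env <- net$compiled$env
  for (nm in names(params)) assign(nm, params[[nm]], envir = env)
  invisible(env)
}

## Resolve the parameter set for a phase (base params + phase overrides).
phase_params <- function(net, params = NULL, phase = NULL) {
  p <- net$parameters
  if (!is.null(params)) p[names(params)] <- params
  if (!is.null(phase)) {
    if (!phase %in% names(net$phases)) {
      stop(sprintf("unknown phase '%s'", phase))
    }
    ov <- net$phases[[phase]]
    p[names(ov)] <- ov
  }
  p
}
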