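test_that("modifier application is multiplicative, commutative and exact", {
  base <- c(nemo_act = 2, tr_bcl2 = 1, other = 0.5)

  two_hits <- list(modifier("nemo_act", 1.5), modifier("nemo_act", 1.5))
  expect_identical(apply_modifiers(base, two_hits)[["nemo_act"]], 2 * 2.25)

  expect_identical(apply_modifiers(base, list()), base)

  mixed <- list(modifier("tr_bcl2", 1.5), modifier("tr_bcl2", 0.5))
  expect_equal(apply_modifiers(base, mixed)[["tr_bcl2"]], 0.75)

  expect_error(apply_modifiers(base, list(modifier("nope", 2))), "nope")
  expect_error(modifier("x", 0))
  expect_error(modifier("x", -1))

  ## any permutation of the same modifier multiset is bitwise identical
  set.seed(42)
  mods <- lapply(1:6, function(i)
    modifier(sample(names(base), 1), exp(rnorm(1))))
  ref <- apply_modifiers(base, mods)
  for (k in 1:5) {
    perm <- sample(mods)
    expect_identical(apply_modifiers(base, perm), ref)
  }
})

toy_decay <- reaction_network(list(
  name = "decay",
  species = list(list(name = "x", initial = 1)),
  parameters = list(list(name = "k", value = 1)),
  rates = list(list(expr = "k * x", stoich = list(x = -1)))))

toy_proddeg <- reaction_network(list(
  name = "proddeg",
  species = list(list(name = "x", initial = 0)),
  parameters = list(list(name = "s", value = 2), list(name = "k", value = 1)),
  rates = list(list(expr = "s", stoich = list(x = 1)),
               list(expr = "k * x", stoich = list(x = -1)))))

test_that("integration reproduces closed forms", {
  tr <- integrate_network(toy_decay, t_span = c(0, 1))
  expect_equal(trace_at(tr, "x", 1), exp(-1), tolerance = 1e-5)

  ## identity: modifiers at x1 leave the trace unchanged
  p <- apply_modifiers(toy_decay$parameters,
                       list(modifier("k", 1), modifier("k", 1)))
  tr2 <- integrate_network(toy_decay, params = p, t_span = c(0, 1))
  expect_identical(tr2$values, tr$values)

  ss <- run_to_steady_state(toy_proddeg, max_t = 200)
  expect_equal(unname(ss[["x"]]), 2, tolerance = 1e-5)

  ## already at steady state: returned unchanged within tolerance
  ss2 <- run_to_steady_state(toy_proddeg, x0 = c(x = 2), max_t = 50)
  expect_equal(unname(ss2[["x"]]), 2, tolerance = 1e-6)
})

test_that("bistable switch settles into the starting basin's fixed point", {
  ## dx/dt = a + V x^2/(K^2+x^2) - d x  (cubic nullcline, two stable roots)
  toy <- reaction_network(list(
    name = "switch",
    species = list(list(name = "x", initial = 0)),
    parameters = list(list(name = "a", value = 0.05),
                      list(name = "V", value = 1),
                      list(name = "K", value = 0.5),
                      list(name = "d", value = 1)),
    rates = list(list(expr = "a + V * hill(x, K, 2)", stoich = list(x = 1)),
                 list(expr = "d * x", stoich = list(x = -1)))))
  f <- function(x) 0.05 + x^2 / (0.25 + x^2) - x
  lo <- uniroot(f, c(0, 0.12))$root    # independent root-finding oracle
  hi <- uniroot(f, c(0.5, 0.95))$root
  s_lo <- run_to_steady_state(toy, x0 = c(x = 0.01), max_t = 400)
  s_hi <- run_to_steady_state(toy, x0 = c(x = 1.5), max_t = 400)
  expect_equal(unname(s_lo[["x"]]), lo, tolerance = 1e-2)
  expect_equal(unname(s_hi[["x"]]), hi, tolerance = 1e-2)
})

test_that("network validation catches unresolved symbols and bad stoichiometry", {
  bad <- list(name = "bad",
              species = list(list(name = "x", initial = 1)),
              parameters = list(list(name = "k", value = 1)),
              rates = list(list(expr = "k * y", stoich = list(x = -1))))
  expect_error(reaction_network(bad), "unresolved")
  bad2 <- list(name = "bad2",
               species = list(list(name = "x", initial = 1)),
               parameters = list(list(name = "k", value = 1)),
               rates = list(list(expr = "k * x", stoich = list(z = -1))))
  expect_error(reaction_network(bad2), "unknown species")
})

test_that("mass-action totals are conserved along apoptosis traces", {
  net <- apo_net()
  tr <- simulate_apoptosis(net, horizon = 40)
  for (pair in net$conserved) {
    tot <- rowSums(tr$values[, pair, drop = FALSE])
    expect_lt(diff(range(tot)) / tot[1], 1e-6)
  }
})

test_that("tightening solver tolerances changes readouts by less than 0.1%", {
  net <- apo_net()
  t1 <- time_to_death(simulate_apoptosis(net, horizon = 60,
                                         rtol = 1e-6, atol = 1e-9))
  t2 <- time_to_death(simulate_apoptosis(net, horizon = 60,
                                         rtol = 1e-7, atol = 1e-10))
  expect_lt(abs(t1 - t2) / t1, 1e-3)
})

test_that("trace interpolation is linear between grid points and bounded", {
  tr <- integrate_network(toy_decay, t_span = c(0, 1), n_out = 11)
  mid <- trace_at(tr, "x", 0.05)
  expect_equal(unname(mid),
               unname(tr$values[1, "x"] + tr$values[2, "x"]) / 2,
               tolerance = 1e-12)
  expect_error(trace_at(tr, "x", 2), "outside")
  expect_error(trace_at(tr, "nope", 0.5), "not in trace")
})
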