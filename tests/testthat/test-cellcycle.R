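test_that("the reference cell settles on a ~12-hour limit cycle", {
  eq <- limit_cycle_equilibrate(cc_net())
  expect_false(eq$arrested)
  expect_true(eq$converged)
  expect_lt(abs(eq$period - 12), 0.6)
  ## re-equilibrating from the settled state is idempotent
  eq2 <- limit_cycle_equilibrate(cc_net(), x0 = eq$state)
  expect_equal(eq2$period, eq$period, tolerance = 1e-3)
  expect_equal(eq2$mass_at_division, eq$mass_at_division, tolerance = 1e-3)
})

test_that("MYC shortens the cycle monotonically with saturation beyond 5-fold", {
  net <- cc_net()
  folds <- c(1, 1.5, 3, 5, 8)
  per <- vapply(folds, function(f) {
    cycle_length(net, params = apply_modifiers(net$parameters,
                                               list(modifier("tr_myc", f))))
  }, numeric(1))
  expect_true(all(diff(per[1:4]) < 0))
  expect_equal(per[4], per[5], tolerance = 1e-6)  # flat beyond the cap
  ## the x1.5 shortening is of the order of minutes, not hours
  expect_lt((per[1] - per[2]) * 60, 20)
  expect_gt((per[1] - per[2]) * 60, 2)
})

test_that("growth and p27 control arrest", {
  net <- cc_net()
  ## no mass growth -> the division checkpoint is unreachable
  p <- net$parameters; p["mu"] <- 0
  eq <- limit_cycle_equilibrate(net, params = p, max_t = 120)
  expect_true(eq$arrested)
  expect_true(detect_arrest(net, params = p, horizon = 60))

  ## a 10-fold p27 synthesis increase arrests the reference cell;
  ## coarse bifurcation scan: divisions cease beyond some fold and
  ## never resume at higher folds
  arrested_at <- vapply(c(1, 2, 5, 10), function(f) {
    pp <- apply_modifiers(net$parameters, list(modifier("ks_p27", f)))
    detect_arrest(net, params = pp,
                  x0 = cellcycle_baseline_state(net), horizon = 60)
  }, logical(1))
  expect_false(arrested_at[1])
  expect_true(arrested_at[4])
  expect_true(all(diff(arrested_at) >= 0))  # monotone transition

  ## cycling wild-type single cell is not arrested
  expect_false(detect_arrest(net, x0 = cellcycle_baseline_state(net),
                             horizon = 60))
})

test_that("G1 dominates the cycle and takes the brunt of the MYC effect", {
  net <- cc_net()
  ph_wt <- phase_durations(net)
  expect_gt(ph_wt[["G1"]], ph_wt[["S"]])
  expect_gt(ph_wt[["G1"]], ph_wt[["G2M"]])
  expect_equal(ph_wt[["G1"]] + ph_wt[["S"]] + ph_wt[["G2M"]],
               ph_wt[["total"]], tolerance = 1e-8)

  p <- apply_modifiers(net$parameters, list(modifier("tr_myc", 1.5)))
  ph_m <- phase_durations(net, params = p)
  d_g1 <- ph_wt[["G1"]] - ph_m[["G1"]]
  d_rest <- abs((ph_wt[["S"]] + ph_wt[["G2M"]]) -
                (ph_m[["S"]] + ph_m[["G2M"]]))
  expect_gt(d_g1, 0)
  expect_gt(d_g1, d_rest)

  expect_error(phase_durations(net, params = {
    p0 <- net$parameters; p0["mu"] <- 0; p0
  }), "arrested")
})

test_that("a heterogeneous population shows minority arrest with high p27, MYC rescue", {
  pop <- cellcycle_population(cc_net(), n = 120, seed = 3)
  cells <- pop$cells
  arr_pct <- 100 * mean(cells$arrested_wt)
  expect_gt(arr_pct, 2)
  expect_lt(arr_pct, 25)

  ## arrested cells carry elevated p27 relative to the cycling median
  expect_gt(median(cells$p27_end_wt[cells$arrested_wt]),
            median(cells$p27_end_wt[!cells$arrested_wt]))

  ## the majority of arrested cells resume cycling at 1.5-fold MYC
  resc <- cells$rescued[cells$arrested_wt]
  expect_gt(mean(resc, na.rm = TRUE), 0.5)

  ## rescued cells divide promptly: typically within half a nominal
  ## cycle of MYC induction (mass banked in arrest makes them the most
  ## rapidly dividing cells at that moment); stragglers stay well under
  ## two cycles
  tfirst <- cells$t_first_div_rescue[cells$arrested_wt & !is.na(cells$rescued) &
                                     cells$rescued]
  expect_lt(median(tfirst), 6)
  expect_true(all(tfirst < 24))

  ## division-time distribution: unimodal-ish positive skew
  lens <- cells$len_wt[!is.na(cells$len_wt)]
  skew <- function(x) mean((x - mean(x))^3) / sd(x)^3
  expect_gt(skew(lens), 0)

  ## population mean shortening at x1.5 MYC is of the order of minutes
  s <- summarise_cellcycle_population(pop)
  expect_gt(s$mean_shortening_min, 3)
  expect_lt(s$mean_shortening_min, 30)
})

test_that("rescue from arrest grows with the MYC dose", {
  net <- cc_net()
  base_state <- cellcycle_baseline_state(net)
  het <- net$heterogeneity
  set.seed(3)
  sdl <- sqrt(log(1 + 0.25^2))
  mult <- matrix(exp(rnorm(120 * length(het), 0, sdl)), nrow = 120,
                 dimnames = list(NULL, het))
  ## identify arrested cells once (same criterion as cellcycle_population)
  arrested <- which(vapply(seq_len(120), function(i) {
    p <- net$parameters; p[het] <- p[het] * mult[i, ]
    detect_arrest(net, params = p, x0 = base_state, horizon = 60)
  }, logical(1)))
  expect_gt(length(arrested), 3)
  rescued_frac <- vapply(c(1.25, 2.0), function(f) {
    mean(vapply(arrested, function(i) {
      p <- net$parameters; p[het] <- p[het] * mult[i, ]
      p["tr_myc"] <- f
      !detect_arrest(net, params = p, x0 = base_state, horizon = 60)
    }, logical(1)))
  }, numeric(1))
  expect_gte(rescued_frac[2], rescued_frac[1])
})
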