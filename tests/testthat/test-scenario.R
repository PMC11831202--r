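test_that("with no improved-variety gains the counterfactual equals baseline", {
  mw <- small_fixture()
  shocks <- lapply(mw$shocks, function(s) {
    s$cells$tau_g <- 0
    s
  })
  base <- run_scenario(mw$world, shocks, "baseline")
  cf <- run_scenario(mw$world, shocks, "no_iv")
  for (p in seq_along(shocks)) {
    expect_equal(cf$states[[p]]$cells$L, base$states[[p]]$cells$L,
                 tolerance = 1e-10)
    expect_equal(cf$states[[p]]$prices$P_world,
                 base$states[[p]]$prices$P_world, tolerance = 1e-10)
  }
  cmp <- compare_scenarios(base, cf)
  expect_equal(cmp$cumulative$d_cropland_ha, 0, tolerance = 1e-6)
  expect_equal(cmp$cumulative$d_price_pct, 0, tolerance = 1e-8)
})

test_that("chaining zero-shock periods leaves the world unchanged", {
  mw <- small_fixture()
  z <- list(zero_shocks(mw$world, "P1"), zero_shocks(mw$world, "P2"))
  run <- run_scenario(mw$world, z)
  for (p in 1:2) {
    expect_equal(run$states[[p]]$cells$L, mw$world$cells$L0,
                 tolerance = 1e-8)
    expect_equal(run$states[[p]]$prices$P_world, 1, tolerance = 1e-8)
  }
})

test_that("a re-based solved state is a fixed point of the zero-shock solve", {
  mw <- small_fixture()
  eq <- solve_equilibrium(mw$world, mw$shocks$P1)
  w2 <- rebase_world(eq)
  eq2 <- solve_equilibrium(w2)
  expect_equal(eq2$convergence$iterations, 0L)
  expect_equal(eq2$cells$L, eq$cells$L, tolerance = 1e-9)
  expect_equal(eq2$prices$P_world, eq$prices$P_world, tolerance = 1e-10)
})

test_that("comparison differences are additive across cells and periods", {
  mw <- small_fixture()
  base <- run_scenario(mw$world, mw$shocks, "baseline")
  cf <- run_scenario(mw$world, mw$shocks, "no_iv")
  cmp <- compare_scenarios(base, cf)
  # per-cell totals sum to the global cumulative difference
  expect_equal(sum(cmp$per_cell$dL_total), cmp$cumulative$d_cropland_ha,
               tolerance = 1e-10 * max(1, abs(cmp$cumulative$d_cropland_ha)))
  # period increments sum to the end-of-horizon difference, recomputed
  # independently from the final states
  end_diff <- sum(cf$states[[3]]$cells$L) - sum(base$states[[3]]$cells$L)
  expect_equal(sum(cmp$per_period$d_cropland_ha), end_diff,
               tolerance = 1e-8 * max(1, abs(end_diff)))
  expect_equal(cmp$cumulative$d_cropland_ha, end_diff,
               tolerance = 1e-8 * max(1, abs(end_diff)))
  # regional increments aggregate the cells exactly
  for (p in cmp$periods) {
    inc <- cmp$per_cell[[paste0("dL_", p)]]
    reg <- tapply(inc, cmp$per_cell$region_id, sum)
    got <- cmp$regional[cmp$regional$period == p, ]
    expect_equal(as.numeric(reg[got$region_id]), got$d_cropland_ha,
                 tolerance = 1e-10)
  }
})

test_that("identical runs compare to an all-zero difference", {
  mw <- small_fixture()
  base <- run_scenario(mw$world, mw$shocks, "baseline")
  cmp <- compare_scenarios(base, base)
  expect_true(all(cmp$per_cell$dL_total == 0))
  expect_equal(cmp$cumulative$d_output_t, 0)
  expect_equal(cmp$cumulative$d_price_pct, 0)
})

test_that("removing nonnegative TFP gains never lowers the world price", {
  for (seed in c(7, 42)) {
    mw <- make_world(synth_spec(n_regions = 2, cells_per_region = 25,
                                seed = seed))
    base <- run_scenario(mw$world, mw$shocks, "baseline")
    cf <- run_scenario(mw$world, mw$shocks, "no_iv")
    cg <- run_scenario(mw$world, mw$shocks, "no_cgiar_iv")
    for (p in 1:3) {
      expect_gte(cf$states[[p]]$prices$P_world,
                 base$states[[p]]$prices$P_world)
      # partial (CGIAR-only) removal lies between baseline and full removal
      expect_gte(cg$states[[p]]$prices$P_world,
                 base$states[[p]]$prices$P_world)
      expect_lte(cg$states[[p]]$prices$P_world,
                 cf$states[[p]]$prices$P_world + 1e-10)
    }
  }
})

test_that("scenario bookkeeping rejects malformed inputs", {
  mw <- small_fixture()
  expect_error(run_scenario(mw$world, list(), "baseline"), "at least one")
  expect_error(run_scenario(mw$world, list(1, 2)), "shock_set")
  bad <- mw$shocks$P1
  bad$regional <- bad$regional[-1, ]
  expect_error(run_scenario(mw$world, list(bad)), "missing regions")
  base <- run_scenario(mw$world, mw$shocks[1:2], "baseline")
  cf <- run_scenario(mw$world, mw$shocks, "no_iv")
  expect_error(compare_scenarios(base, cf), "period lists differ")
  other <- make_world(synth_spec(n_regions = 2, cells_per_region = 10,
                                 seed = 3))
  ob <- run_scenario(other$world, other$shocks, "baseline")
  expect_error(compare_scenarios(ob, cf), "different worlds")
})

test_that("cropland_difference accessors agree with the comparison table", {
  mw <- small_fixture()
  base <- run_scenario(mw$world, mw$shocks, "baseline")
  cf <- run_scenario(mw$world, mw$shocks, "no_iv")
  cmp <- compare_scenarios(base, cf)
  inc2 <- cropland_difference(cmp, "P2", incremental = TRUE)
  end2 <- cropland_difference(cmp, "P2", incremental = FALSE)
  end1 <- cropland_difference(cmp, "P1", incremental = FALSE)
  expect_equal(unname(end2 - end1), unname(inc2), tolerance = 1e-10)
  expect_equal(unname(cropland_difference(cmp, "total")),
               unname(cropland_difference(cmp, "P3", incremental = FALSE)),
               tolerance = 1e-10)
  expect_error(cropland_difference(cmp, "P9"), "unknown period")
})
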