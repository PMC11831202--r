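make_layers <- function(n = 20, seed = 5, hot_frac = 0.3) {
  set.seed(seed)
  cells <- data.frame(
    cell_id = sprintf("C%03d", 1:n), lon = runif(n), lat = runif(n),
    c_veg = rlnorm(n, log(80), 0.5), c_soil = rlnorm(n, log(60), 0.4),
    ecoregion = sample(c("E1", "E2", "E3"), n, replace = TRUE),
    country = sample(c("AA", "BB", "CC"), n, replace = TRUE),
    hotspot = ifelse(runif(n) < hot_frac, "H1", NA),
    stringsAsFactors = FALSE
  )
  cf <- expand.grid(ecoregion = c("E1", "E2", "E3"), taxon = env_taxa(),
                    stringsAsFactors = FALSE)
  cf$cf <- rlnorm(nrow(cf), log(1e-5), 1)
  env_layers(cells, cf)
}

test_that("LUC emissions follow the one-time stock accounting", {
  ly <- make_layers()
  n <- nrow(ly$cells)
  expect_equal(luc_emissions(rep(0, n), ly), rep(0, n))
  # 1 ha conversion, 100 tC/ha vegetation + 25% of 60 tC/ha soil
  one <- env_layers(
    data.frame(cell_id = "C1", lon = 0, lat = 0, c_veg = 100, c_soil = 60,
               ecoregion = "E1", country = "AA", hotspot = NA),
    data.frame(ecoregion = "E1", taxon = env_taxa(), cf = 1e-5)
  )
  expect_equal(luc_emissions(1, one, soil_fraction = 0.25),
               115 * 44 / 12)
  expect_equal(round(luc_emissions(1, one, 0.25), 2), 421.67)
  # signed: contraction gives negative emissions
  expect_lt(luc_emissions(-1, one), 0)
  expect_error(luc_emissions(1, one, soil_fraction = 1.2), "soil_fraction")
  bad <- one
  bad$cells$c_veg <- -5
  expect_error(env_layers(bad$cells, bad$cf), "nonnegative")
})

test_that("species loss applies ecoregion factors and partitions by country", {
  ly <- make_layers()
  n <- nrow(ly$cells)
  z <- species_loss(rep(0, n), ly)
  expect_equal(unname(z$total), rep(0, 5))
  # single-cell hand calculation
  one <- env_layers(
    data.frame(cell_id = "C1", lon = 0, lat = 0, c_veg = 1, c_soil = 1,
               ecoregion = "E1", country = "AA", hotspot = NA),
    data.frame(ecoregion = "E1", taxon = env_taxa(),
               cf = c(1e-4, 1e-6, 1e-6, 1e-6, 1e-6))
  )
  s1 <- species_loss(1000, one)
  expect_equal(unname(s1$total["plants"]), 0.1)
  # randomized layers: country totals partition the global total exactly
  set.seed(8)
  dL <- rnorm(n, 0, 50)
  sp <- species_loss(dL, ly)
  for (t in env_taxa()) {
    expect_equal(sum(sp$by_country[[t]]), unname(sp$total[[t]]),
                 tolerance = 1e-12)
  }
  # missing factors are reported with the ecoregion named
  ly2 <- ly
  ly2$cf <- ly$cf[ly$cf$ecoregion != "E2", ]
  expect_error(species_loss(dL, ly2), "E2")
})

test_that("environmental accounting operators are linear", {
  ly <- make_layers()
  n <- nrow(ly$cells)
  set.seed(13)
  d1 <- rnorm(n, 10, 30)
  d2 <- rnorm(n, -5, 20)
  expect_equal(luc_emissions(d1 + d2, ly),
               luc_emissions(d1, ly) + luc_emissions(d2, ly),
               tolerance = 1e-9)
  s12 <- species_loss(d1 + d2, ly)$total
  s1 <- species_loss(d1, ly)$total
  s2 <- species_loss(d2, ly)$total
  expect_equal(s12, s1 + s2, tolerance = 1e-12)
})

test_that("hotspot share covers the full, empty and mixed mask cases", {
  ly <- make_layers(hot_frac = 1)
  n <- nrow(ly$cells)
  imp <- abs(rnorm(n))
  expect_equal(hotspot_share(imp, ly)$share, 1)
  ly0 <- make_layers(hot_frac = 0)
  expect_equal(hotspot_share(imp, ly0)$share, 0)
  expect_equal(hotspot_share(imp, ly0)$hotspots_touched, 0)
  lym <- make_layers(hot_frac = 0.4, seed = 17)
  hs <- hotspot_share(imp, lym)
  expect_gte(hs$share, 0)
  expect_lte(hs$share, 1)
  # complementary share
  outside <- sum(imp[is.na(lym$cells$hotspot)]) / sum(imp)
  expect_equal(hs$share, 1 - outside, tolerance = 1e-12)
  expect_warning(z <- hotspot_share(rep(0, n), lym), "zero global impact")
  expect_true(is.na(z$share))
})

test_that("the impact report aggregates a comparison consistently", {
  mw <- small_fixture()
  base <- run_scenario(mw$world, mw$shocks, "baseline")
  cf <- run_scenario(mw$world, mw$shocks, "no_iv")
  cmp <- compare_scenarios(base, cf)
  rep <- impact_report(cmp, mw$layers)
  # cumulative emissions equal the sum of the period increments, and equal
  # the one-shot accounting of the end-of-horizon difference
  expect_equal(rep$emissions$cumulative,
               cumulative_impact(rep$emissions$per_period))
  direct <- sum(luc_emissions(cropland_difference(cmp, "total"), mw$layers))
  expect_equal(rep$emissions$cumulative, direct, tolerance = 1e-8)
  # taxon additivity of the grand total
  expect_equal(rep$species$grand_total, species_total(rep$species$total))
  # per-period species increments sum to the totals per taxon
  expect_equal(colSums(rep$species$per_period), rep$species$total,
               tolerance = 1e-9)
  # regional emission aggregates partition the global figure
  expect_equal(sum(rep$emissions$by_region), rep$emissions$cumulative,
               tolerance = 1e-8)
})
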