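test_that("regional demand reproduces its calibration point and closed form", {
  expect_equal(regional_demand(1, 5000, 1e6, 0.2, 5000, 1, 0.4, -0.5), 2e5)
  # zero price elasticity: doubling the price changes nothing
  expect_equal(regional_demand(2, 5000, 1e6, 0.2, 5000, 1, 0.4, 0),
               regional_demand(1, 5000, 1e6, 0.2, 5000, 1, 0.4, 0))
  # eps_p = -0.5 and a fourfold price: demand halves
  expect_equal(regional_demand(4, 5000, 1e6, 0.2, 5000, 1, 0, -0.5), 1e5)
  expect_error(regional_demand(1, 5000, 1e6, 0.2, 5000, 1, -0.1, -0.5),
               "income elasticity")
})

test_that("elasticity lookup interpolates monotonically and validates", {
  tab <- synth_elasticity_table()
  e <- demand_elasticities(c(1000, 3000, 10000, 50000, 1e6), tab, "crops")
  expect_true(all(diff(e$eps_y) <= 0))
  expect_true(all(diff(e$eps_p) >= 0))
  expect_equal(e$eps_y[1], 0.50)   # at and below the lowest income knot
  expect_equal(e$eps_p[4], -0.25)  # at the top knot (and flat beyond)
  bad <- tab
  bad$eps_p[bad$commodity == "crops"] <- c(-0.2, -0.4, -0.3)
  expect_error(demand_elasticities(2000, bad, "crops"), "monotone")
})

test_that("Armington split conserves tons and has the Leontief limit", {
  sp <- armington_split(100, 1, 1, c(0.7, 0.3), 2)
  expect_equal(sp$from_domestic, 70)
  expect_equal(sp$from_world, 30)
  # sigma_A = 0: fixed quantity shares whatever the prices
  sp0 <- armington_split(100, 3, 0.5, c(0.7, 0.3), 0)
  expect_equal(sp0$from_domestic, 70)
  # sigma_A = 2, domestic 10% dearer: share falls, matches hand arithmetic
  sp2 <- armington_split(100, 1.1, 1, c(0.7, 0.3), 2)
  wd <- 0.7 * 1.1^-2
  expect_equal(sp2$share_domestic, wd / (wd + 0.3))
  expect_lt(sp2$share_domestic, 0.7)
  expect_equal(sp2$from_domestic + sp2$from_world, 100)
  expect_error(armington_split(1, 1, 1, c(0.7, 0.3), -1), "sigma_A")
  expect_error(armington_split(1, 1, 1, c(0.7, 0.4), 2), "sum to 1")
})

test_that("price indices equal 1 at base prices and respond to both markets", {
  expect_equal(armington_price_index(1, 1, c(0.6, 0.4), 2), 1)
  expect_equal(cet_price_index(1, 1, c(0.8, 0.2), 1.5), 1)
  expect_gt(armington_price_index(1.2, 1, c(0.6, 0.4), 2), 1)
  expect_gt(cet_price_index(1, 1.2, c(0.8, 0.2), 1.5), 1)
  # homogeneity: joint scaling of prices and anchors leaves indices relative
  expect_equal(armington_price_index(2.4, 2, c(0.6, 0.4), 2, P0 = c(2, 2)),
               armington_price_index(1.2, 1, c(0.6, 0.4), 2))
})

test_that("CET sales split conserves output and favors the dearer market", {
  sp <- cet_split(100, 1, 1.3, c(0.8, 0.2), 2)
  expect_equal(sp$to_domestic + sp$to_world, 100)
  expect_gt(sp$share_world, 0.2)
})

test_that("cell supply reproduces its calibration point exactly", {
  mw <- synth_fixture()
  cl <- mw$world$cells
  cs <- cell_supply(1, cl)
  expect_equal(cs$r, cl$r0, tolerance = 1e-12)
  expect_equal(cs$L, cl$L0, tolerance = 1e-12)
  expect_equal(cs$Q, cl$Q0, tolerance = 1e-12)
  expect_false(any(cs$corner))
})

test_that("cell rent solves zero profit (root-finder oracle) and output rises
          with price and TFP", {
  mw <- synth_fixture()
  cl <- mw$world$cells[1:20, ]
  set.seed(31)
  for (k in 1:20) {
    P <- exp(runif(1, -0.3, 0.5))
    cs <- cell_supply(P, cl)
    for (i in c(1, 7, 19)) {
      root <- uniroot(function(r) {
        ces_unit_cost(c(r, 1), c(cl$theta_L[i], 1 - cl$theta_L[i]),
                      cl$sigma[i], a = cl$a[i],
                      w0 = c(cl$r0[i], 1)) - P
      }, c(1e-8, 1e8), tol = 1e-12)$root
      expect_equal(cs$r[i], root, tolerance = 1e-6)
    }
  }
  base <- cell_supply(1, cl)
  up_p <- cell_supply(1.1, cl)
  cl2 <- cl
  cl2$a <- cl$a * 1.1
  up_a <- cell_supply(1, cl2)
  expect_true(all(up_p$Q > base$Q))
  expect_true(all(up_p$r > base$r))
  expect_true(all(up_a$Q > base$Q))
  expect_true(all(up_a$r > base$r))
})

test_that("cell cost exhaustion holds away from the calibration point", {
  mw <- synth_fixture()
  cl <- mw$world$cells
  for (P in c(0.85, 1, 1.6)) {
    cs <- cell_supply(P, cl)
    value <- P * cs$Q
    cost <- cs$r * cs$L + cs$N
    expect_lt(max(abs(value - cost) / value), 1e-8)
  }
})

test_that("a price below attainable unit cost puts the cell at a corner", {
  cl <- data.frame(id = "c1", region_id = "R1", lon = 0, lat = 0,
                   L0 = 100, Lambda = 200, Q0 = 300, theta_L = 0.3,
                   sigma = 0.5, eta0 = 0.3, a = 1)
  cl$r0 <- cl$theta_L * cl$Q0 / cl$L0
  cv <- land_supply_curve(cl$L0, cl$Lambda, cl$r0, cl$eta0)
  cl$gamma <- cv$gamma
  cl$kappa <- cv$kappa
  # minimum unit cost as rent -> 0 is theta_N^(1/(1-sigma)) = 0.7^2 = 0.49
  cs <- cell_supply(0.4, cl)
  expect_true(cs$corner)
  expect_equal(cs$L, 0)
  expect_equal(cs$Q, 0)
  expect_equal(attr(cs, "corner_cells"), "c1")
  ok <- cell_supply(0.6, cl)
  expect_false(ok$corner)
  expect_gt(ok$Q, 0)
})
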