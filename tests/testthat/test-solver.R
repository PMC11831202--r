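test_that("the zero-shock solve returns the calibrated base state", {
  mw <- small_fixture()
  eq <- solve_equilibrium(mw$world)
  expect_equal(eq$convergence$iterations, 0L)
  expect_lt(max(abs(eq$cells$L - mw$world$cells$L0) / mw$world$cells$L0),
            1e-8)
  expect_lt(max(abs(eq$cells$Q - mw$world$cells$Q0) / mw$world$cells$Q0),
            1e-8)
  expect_equal(eq$prices$P_world, 1, tolerance = 1e-10)
})

test_that("Newton matches brute-force price bisection on the two-cell world", {
  tw <- make_two_cell_oracle_world()
  w <- tw$world
  # the autarky world has exactly one active market residual
  eq0 <- solve_equilibrium(w)
  expect_equal(sum(eq0$convergence$active), 1L)
  # +20% TFP in one cell, solved by Newton vs scalar bisection
  w$cells$a[1] <- 1.2
  eq <- solve_equilibrium(w)
  p_star <- bisect_price(w)
  expect_equal(unname(eq$prices$P_dom), p_star, tolerance = 1e-6)
  cs <- cell_supply(p_star, w$cells)
  expect_equal(eq$cells$L, cs$L, tolerance = 1e-6)
  expect_gt(eq$cells$Q[1], w$cells$Q0[1])  # the improved cell expands
})

test_that("a tiny uniform TFP shock matches the one-step linearization", {
  mw <- small_fixture()
  w <- mw$world
  sh <- zero_shocks(w)
  sh$regional$tfp_crops <- 0.001
  eq <- solve_equilibrium(w, sh)
  # Johansen-style one-step: residual gradient at base prices
  shocked <- apply_shocks(w, sh)
  R <- nrow(w$regions)
  base_prices <- function(x) {
    list(P_dom = exp(x[seq_len(R)]), P_ls = exp(x[R + seq_len(R)]),
         P_pr = exp(x[2 * R + seq_len(R)]), P_world = exp(x[3 * R + 1]))
  }
  f <- function(x) market_residuals(shocked, base_prices(x))$scaled
  n <- 3 * R + 1
  x0 <- rep(0, n)
  f0 <- f(x0)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    xj <- x0
    xj[j] <- 1e-7
    J[, j] <- (f(xj) - f0) / 1e-7
  }
  x_lin <- solve(J, -f0)
  p_lin <- exp(x_lin[3 * R + 1])
  # agreement to second order in the (0.1%) shock size
  expect_equal(eq$prices$P_world, p_lin, tolerance = 1e-5)
})

test_that("the solution is invariant to cell ordering", {
  mw <- small_fixture()
  w <- mw$world
  sh <- mw$shocks$P1
  eq1 <- solve_equilibrium(w, sh)
  w2 <- w
  perm <- rev(seq_len(nrow(w$cells)))
  w2$cells <- w$cells[perm, ]
  sh2 <- sh
  eq2 <- solve_equilibrium(w2, sh2)
  m <- match(eq1$cells$id, eq2$cells$id)
  expect_equal(eq1$cells$L, eq2$cells$L[m], tolerance = 1e-9)
  expect_equal(eq1$prices$P_world, eq2$prices$P_world, tolerance = 1e-10)
})

test_that("a symmetric two-region world yields a mirrored solution", {
  # two identical regions trading through the world pool
  cells <- data.frame(
    id = c("C1", "C2"), region_id = c("Ra", "Rb"),
    lon = c(0, 10), lat = 0, cropland = 100, asymptote = 300,
    output = 400, land_cost_share = 0.3, substitution_elasticity = 0.5,
    land_supply_elasticity = 0.3
  )
  regions <- data.frame(
    id = c("Ra", "Rb"), population = 1e6, pc_income = 4000,
    biofuel_demand = 10,
    dem_crops = 400 - 10 - 45 - 65, dem_livestock = 100, dem_processed = 100
  )
  shares <- rbind(
    data.frame(region_id = c("Ra", "Rb"), sector = "livestock",
               crop_share = 0.45, noncrop_share = 0.55, output = 100,
               substitution_elasticity = 0.5),
    data.frame(region_id = c("Ra", "Rb"), sector = "processed",
               crop_share = 0.65, noncrop_share = 0.35, output = 100,
               substitution_elasticity = 0.5)
  )
  trade <- data.frame(
    region_id = c("Ra", "Rb"), sell_domestic = 0.8, sell_world = 0.2,
    source_domestic = 0.8, source_world = 0.2,
    armington_elasticity = 2, cet_elasticity = 2
  )
  raw <- list(regions = regions, cells = cells, shares = shares,
              trade = trade,
              config = list(elasticity_table = synth_elasticity_table()))
  w <- calibrate(raw)
  sh <- zero_shocks(w)
  sh$regional$tfp_crops <- 0.2
  sh$regional$pop_growth <- 0.3
  eq <- solve_equilibrium(w, sh)
  expect_equal(unname(eq$prices$P_dom["Ra"]), unname(eq$prices$P_dom["Rb"]),
               tolerance = 1e-9)
  expect_equal(eq$cells$L[1], eq$cells$L[2], tolerance = 1e-9)
})

test_that("regional net-export residuals sum to minus the world residual", {
  mw <- small_fixture()
  w <- apply_shocks(mw$world, mw$shocks$P1)
  R <- nrow(w$regions)
  pr <- list(P_dom = c(1.05, 0.97), P_ls = c(1.1, 0.9),
             P_pr = c(1.02, 1.01), P_world = 1.07)
  out <- market_residuals(w, pr)
  st <- out$state$regions
  expect_equal(sum(st$S_w - st$Qm), unname(out$residuals["world"]),
               tolerance = 1e-9)
})

test_that("raising one regional price creates excess supply there", {
  mw <- small_fixture()
  w <- mw$world
  R <- nrow(w$regions)
  pr <- list(P_dom = rep(1, R), P_ls = rep(1, R), P_pr = rep(1, R),
             P_world = 1)
  pr$P_dom[1] <- 1.05
  out <- market_residuals(w, pr)
  expect_gt(out$residuals[[paste0("crops_", w$regions$id[1])]], 0)
  pr2 <- list(P_dom = rep(1, R), P_ls = c(1.05, 1), P_pr = rep(1, R),
              P_world = 1)
  out2 <- market_residuals(w, pr2)
  expect_gt(out2$residuals[[paste0("livestock_", w$regions$id[1])]], 0)
})

test_that("multistep solving is path-independent for within-period shocks", {
  mw <- small_fixture()
  sh <- mw$shocks$P1
  eq1 <- solve_multistep(mw$world, sh, 1)
  expect_equal(eq1$prices$P_world,
               solve_equilibrium(mw$world, sh)$prices$P_world,
               tolerance = 1e-12)
  eq4 <- solve_multistep(mw$world, sh, 4)
  expect_equal(eq4$prices$P_world, eq1$prices$P_world, tolerance = 1e-8)
  expect_lt(max(abs(eq4$cells$L - eq1$cells$L) /
                  pmax(eq1$cells$L, 1)), 1e-6)
  expect_error(solve_multistep(mw$world, sh, 0), "n_steps")
})

test_that("land never exceeds the asymptote in solved or perturbed states", {
  mw <- small_fixture()
  for (p in names(mw$shocks)) {
    eq <- solve_equilibrium(mw$world, mw$shocks[[p]], "no_iv")
    lam <- eq$world$cells$Lambda
    expect_true(all(eq$cells$L < lam))
  }
})
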