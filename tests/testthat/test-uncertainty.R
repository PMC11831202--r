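test_that("Latin-hypercube draws occupy every stratum exactly once", {
  sp <- parameter_space(data.frame(
    path = c("cells:sigma", "layers:carbon"), dist = "uniform",
    lower = 0, upper = 1
  ))
  for (n in c(4, 25)) {
    x <- lhs_sample(sp, n, seed = 99)
    for (j in seq_len(ncol(x))) {
      expect_setequal(floor(x[, j] * n), 0:(n - 1))
    }
  }
})

test_that("sampling is deterministic in the seed and leaves the RNG alone", {
  sp <- default_parameter_space()
  a <- lhs_sample(sp, 10, seed = 5)
  b <- lhs_sample(sp, 10, seed = 5)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a, lhs_sample(sp, 10, seed = 6))))
  set.seed(123)
  u1 <- runif(1)
  set.seed(123)
  invisible(lhs_sample(sp, 5, seed = 42))
  expect_identical(runif(1), u1)
})

test_that("grouped entries share one underlying draw", {
  sp <- parameter_space(data.frame(
    path = c("layers:cf_plants", "layers:cf_animals"),
    dist = "uniform", lower = 0.5, upper = 1.5,
    group = "cf_all"
  ))
  x <- lhs_sample(sp, 8, seed = 1)
  expect_equal(x[, 1], x[, 2])
})

test_that("the 375-draw sample mean is close to the distribution mean", {
  sp <- parameter_space(data.frame(
    path = "cells:sigma", dist = "uniform", lower = 2, upper = 6
  ))
  x <- lhs_sample(sp, 375, seed = 31)
  se <- (6 - 2) / sqrt(12 * 375)
  expect_lt(abs(mean(x) - 4), 3 * se)
})

test_that("triangular quantiles invert the distribution", {
  q <- qtriangular(c(0, 1), 1, 5, 2)
  expect_equal(q, c(1, 5))
  expect_equal(qtriangular(0.25, 0, 2, 1), sqrt(0.5))  # F(x)=x^2/2 below mode
  # degenerate width
  expect_equal(qtriangular(c(0.2, 0.8), 3, 3, 3), c(3, 3))
  sp <- parameter_space(data.frame(
    path = "cells:sigma", dist = "triangular", lower = 0.8, upper = 1.2,
    mode = 1
  ))
  x <- lhs_sample(sp, 50, seed = 2)
  expect_true(all(x >= 0.8 & x <= 1.2))
})

test_that("parameter spaces validate paths, dists and bounds", {
  expect_error(parameter_space(data.frame(
    path = "nope:thing", dist = "uniform", lower = 0, upper = 1
  )), "unknown parameter path")
  expect_error(parameter_space(data.frame(
    path = "cells:sigma", dist = "gaussian", lower = 0, upper = 1
  )), "uniform")
  expect_error(parameter_space(data.frame(
    path = "cells:sigma", dist = "uniform", lower = 2, upper = 1
  )), "bounds")
  expect_error(parameter_space(data.frame(
    path = "cells:sigma", dist = "triangular", lower = 0, upper = 1,
    mode = 2
  )), "mode")
})

test_that("environmental-factor uncertainty leaves the economy untouched", {
  mw <- small_fixture()
  eco <- data.frame(path = c("cells:eta0", "demand:eps_p"),
                    dist = "uniform", lower = 0.8, upper = 1.2)
  narrow <- parameter_space(rbind(eco, data.frame(
    path = "layers:cf_plants", dist = "uniform", lower = 0.95, upper = 1.05)))
  wide <- parameter_space(rbind(eco, data.frame(
    path = "layers:cf_plants", dist = "uniform", lower = 0.3, upper = 1.7)))
  a <- run_uncertainty(mw$world, mw$shocks, mw$layers, narrow, n = 5,
                       seed = 11)
  b <- run_uncertainty(mw$world, mw$shocks, mw$layers, wide, n = 5,
                       seed = 11)
  # identical economic draws -> identical cropland samples
  expect_equal(a$samples$cropland_saving_ha, b$samples$cropland_saving_ha,
               tolerance = 1e-10)
  width <- function(r, m) {
    s <- r$summary
    s$p97.5[s$metric == m] - s$p2.5[s$metric == m]
  }
  expect_equal(width(a, "cropland_saving_ha"), width(b, "cropland_saving_ha"),
               tolerance = 1e-8)
  expect_gt(width(b, "species_saved_plants"), width(a, "species_saved_plants"))
})

test_that("a degenerate parameter space gives zero-width intervals", {
  mw <- small_fixture()
  sp <- parameter_space(data.frame(
    path = c("cells:sigma", "layers:carbon"), dist = "uniform",
    lower = 1, upper = 1
  ))
  r <- run_uncertainty(mw$world, mw$shocks, mw$layers, sp, n = 4, seed = 3)
  expect_equal(r$summary$p2.5, r$summary$p97.5, tolerance = 1e-9)
  expect_equal(r$summary$mean, r$summary$p2.5, tolerance = 1e-9)
})

test_that("reported percentiles match an independent order-statistic rule", {
  mw <- small_fixture()
  r <- run_uncertainty(mw$world, mw$shocks, mw$layers,
                       default_parameter_space(), n = 8, seed = 21)
  v <- sort(r$samples$cropland_saving_ha)
  n <- length(v)
  manual <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    v[lo] + (h - lo) * (v[min(lo + 1, n)] - v[lo])
  }
  s <- r$summary[r$summary$metric == "cropland_saving_ha", ]
  expect_equal(s$p2.5, manual(0.025), tolerance = 1e-10)
  expect_equal(s$p97.5, manual(0.975), tolerance = 1e-10)
  # percentile operator is permutation-invariant and monotone
  expect_lte(s$p2.5, s$p97.5)
})
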