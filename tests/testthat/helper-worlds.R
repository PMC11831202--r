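# Shared fixtures, built once per test run.

# the standard 3-region / 300-cell synthetic study world
synth_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_world(synth_spec(seed = 42))
    cache
  }
})

# a small world for quick solver exercises
small_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_world(synth_spec(n_regions = 2, cells_per_region = 25,
                                      seed = 7))
    }
    cache
  }
})

# independent CES oracle: numerical cost minimization on the isoquant of the
# primal CES Q = a * (theta1^(1/s) x1^rho + theta2^(1/s) x2^rho)^(1/rho)
# (the technology dual to ces_unit_cost); never calls the package's demand.
ces_oracle_min <- function(Q, w, theta, sigma, a = 1) {
  x2_on_isoquant <- function(x1) {
    if (abs(sigma - 1) < 1e-12) {
      # sigma -> 1 limit of this CES family: Q = a * prod((x_i/theta_i)^theta_i)
      theta[2] * exp((log(Q / a) - theta[1] * log(x1 / theta[1])) / theta[2])
    } else {
      rho <- (sigma - 1) / sigma
      rest <- (Q / a)^rho - theta[1]^(1 / sigma) * x1^rho
      if (rho > 0 && rest <= 0) return(NA_real_)
      (rest / theta[2]^(1 / sigma))^(1 / rho)
    }
  }
  cost <- function(lx1) {
    x1 <- exp(lx1)
    x2 <- x2_on_isoquant(x1)
    if (!is.finite(x2) || x2 <= 0) return(1e30)
    w[1] * x1 + w[2] * x2
  }
  opt <- stats::optimize(cost, lower = log(Q) - 12, upper = log(Q) + 12,
                         tol = 1e-12)
  x1 <- exp(opt$minimum)
  c(x1 = x1, x2 = x2_on_isoquant(x1), cost = opt$objective)
}

# brute-force bisection oracle for a single-market (autarky) world: finds the
# domestic crop price at which the market residual vanishes
bisect_price <- function(world, lo = 0.05, hi = 20, tol = 1e-12) {
  resid_at <- function(p) {
    pr <- list(P_dom = p, P_ls = 1, P_pr = 1, P_world = 1)
    market_residuals(world, pr)$residuals[1]
  }
  stopifnot(resid_at(lo) < 0 || resid_at(hi) > 0)  # excess supply rises in p
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    if (resid_at(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}
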