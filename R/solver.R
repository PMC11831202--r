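#' Solve one period's market-clearing system
#'
#' Damped Newton iteration on log prices over the (up to) 3R+1 market
#' prices: the per-region domestic crop, livestock and processed-food
#' prices plus the world crop pool price. Per-cell rents are resolved
#' analytically inside every residual evaluation (cell problems are
#' independent given the regional producer price), so the outer system
#' stays small regardless of the number of grid cells. Markets with zero
#' base quantity (e.g. the world pool in an autarky world, or an absent
#' sector) are pinned at their base price and excluded from the system.
#'
#' The Jacobian is computed by forward finite differences on the scaled
#' residuals; steps are halved when the residual norm fails to decrease
#' (up to `options$max_halvings`). The solver is fully deterministic.
#'
#' @param world a calibrated `agland_world`.
#' @param shocks a [shock_set()] (default: zero shocks).
#' @param variant scenario variant passed to [apply_shocks()].
#' @param options list: `tol` (max scaled residual, default 1e-8),
#'   `max_iter` (default 200), `fd_eps` (default 1e-7), `max_halvings`
#'   (default 40).
#' @return object of class `agland_equilibrium`: prices, per-cell and
#'   per-region quantity state, convergence report, and the shocked world
#'   (attribute `world`) used for re-basing.
#' @export
solve_equilibrium <- function(world, shocks = NULL, variant = "baseline",
                              options = list()) {
  opt <- utils::modifyList(list(tol = 1e-8, max_iter = 200L, fd_eps = 1e-7,
                                max_halvings = 40L), options)
  if (is.null(shocks)) shocks <- zero_shocks(world)
  shocked <- apply_shocks(world, shocks, variant = variant)
  .solve_shocked(shocked, opt)
}

.solve_shocked <- function(shocked, opt) {
  rg <- shocked$regions
  R <- nrow(rg)
  active <- c(rep(TRUE, R),                       # domestic crop markets
              rg$ls_output0 > 0,                  # livestock markets
              rg$pr_output0 > 0,                  # processed markets
              sum(rg$sell_w * rg$Qsup0) > 1e-12)  # world pool
  if (any(rg$ls_output0 <= 0 & rg$D0_livestock > 0) ||
      any(rg$pr_output0 <= 0 & rg$D0_processed > 0)) {
    stop("solve: a region demands a sector good it cannot produce")
  }
  nm <- c(paste0("crops_", rg$id), paste0("livestock_", rg$id),
          paste0("processed_", rg$id), "world")

  unpack <- function(x_act) {
    full <- rep(0, 3 * R + 1)       # log relative price; 0 => anchor level
    full[active] <- x_act
    p <- exp(full)
    list(P_dom = p[seq_len(R)] * rg$P_d0,
         P_ls = p[R + seq_len(R)] * rg$P_l0,
         P_pr = p[2 * R + seq_len(R)] * rg$P_p0,
         P_world = p[3 * R + 1] * shocked$P_w0)
  }
  fres <- function(x_act) {
    market_residuals(shocked, unpack(x_act))
  }

  n <- sum(active)
  x <- rep(0, n)
  ev <- fres(x)
  fx <- ev$scaled[active]
  norm0 <- max(abs(fx))
  it <- 0L
  trace <- norm0
  while (max(abs(fx)) > opt$tol && it < opt$max_iter) {
    it <- it + 1L
    J <- matrix(0, n, n)
    h <- opt$fd_eps
    for (j in seq_len(n)) {
      xj <- x
      xj[j] <- xj[j] + h
      J[, j] <- (fres(xj)$scaled[active] - fx) / h
    }
    dx <- tryCatch(solve(J, -fx), error = function(e) {
      solve(J + diag(1e-10, n), -fx)
    })
    # cap the log-price step to keep iterates in a sane range
    mx <- max(abs(dx))
    if (mx > 2) dx <- dx * 2 / mx
    lam <- 1
    repeat {
      xn <- x + lam * dx
      evn <- fres(xn)
      fn <- evn$scaled[active]
      if (max(abs(fn)) < max(abs(fx)) || lam < 2^(-opt$max_halvings)) break
      lam <- lam / 2
    }
    if (max(abs(fn)) >= max(abs(fx))) {
      stop("solve: Newton stalled at iteration ", it,
           "; residual trace: ", paste(signif(trace, 4), collapse = " -> "))
    }
    x <- xn
    ev <- evn
    fx <- fn
    trace <- c(trace, max(abs(fx)))
  }
  if (max(abs(fx)) > opt$tol) {
    stop("solve: no convergence after ", it, " iterations; residual trace: ",
         paste(signif(trace, 4), collapse = " -> "))
  }
  p <- unpack(x)
  structure(list(
    prices = list(P_dom = stats::setNames(p$P_dom, rg$id),
                  P_ls = stats::setNames(p$P_ls, rg$id),
                  P_pr = stats::setNames(p$P_pr, rg$id),
                  P_world = p$P_world),
    cells = ev$state$cells,
    regions = ev$state$regions,
    convergence = list(iterations = it,
                       residual_norm = max(abs(fx)),
                       residuals = ev$residuals,
                       active = stats::setNames(active, nm),
                       converged = TRUE),
    world = shocked
  ), class = "agland_equilibrium")
}

#' @export
print.agland_equilibrium <- function(x, ...) {
  cat("<agland_equilibrium> ", nrow(x$regions), " regions, ",
      nrow(x$cells), " cells; P_world = ", signif(x$prices$P_world, 6),
      "; converged in ", x$convergence$iterations, " iteration(s), max |res| = ",
      signif(x$convergence$residual_norm, 3), "\n", sep = "")
  invisible(x)
}

#' Solve a period in equal sub-shocks
#'
#' Homotopy-style stepping for large shocks: the period's gross shocks are
#' split into `n_steps` equal multiplicative sub-shocks, each solved and
#' re-based before the next is applied. For this constant-returns economy
#' with period-fixed demand elasticities, re-basing at a solved point
#' reproduces the same behavioral curves, so the endpoint is independent of
#' the number of steps (checked in the test suite).
#'
#' @inheritParams solve_equilibrium
#' @param n_steps number of equal sub-shocks, >= 1.
#' @return the final `agland_equilibrium`.
#' @export
solve_multistep <- function(world, shocks, n_steps = 1L,
                            variant = "baseline", options = list()) {
  if (n_steps < 1) stop("solve_multistep: n_steps must be >= 1")
  opt <- utils::modifyList(list(tol = 1e-8, max_iter = 200L, fd_eps = 1e-7,
                                max_halvings = 40L), options)
  w <- world
  state <- NULL
  sr <- shocks$regional[match(world$regions$id, shocks$regional$region_id), ]
  target_income <- world$regions$pc_income * (1 + sr$income_growth)
  for (k in seq_len(n_steps)) {
    shocked <- apply_shocks(w, shocks, variant = variant,
                            fraction = 1 / n_steps,
                            elasticity_income = target_income)
    state <- .solve_shocked(shocked, opt)
    if (k < n_steps) w <- rebase_world(state)
  }
  state
}
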