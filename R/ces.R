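#' CES unit cost
#'
#' Dual unit-cost function of a constant-returns CES technology in calibrated
#' share form. At the calibration point (all prices equal to `w0`, TFP
#' `a = 1`) the unit cost equals `c0`. Hicks-neutral productivity scales
#' cost as `1/a`. The Cobb-Douglas case `sigma = 1` is evaluated with its
#' analytic limit, not a numerical approach to 1.
#'
#' @param w numeric vector (or matrix, inputs in columns) of input prices,
#'   all > 0.
#' @param theta cost shares at the calibration point, each in (0,1), summing
#'   to 1 (same length as `w`, or matrix conformable with it).
#' @param sigma elasticity of substitution, > 0 (scalar or vector recycled
#'   over rows).
#' @param a Hicks-neutral TFP relative to the calibration point (default 1).
#' @param w0 calibration-point input prices (default 1).
#' @param c0 calibration-point unit cost (default 1).
#' @return unit cost (currency per unit output), scalar or vector.
#' @examples
#' ces_unit_cost(c(1, 1), c(0.5, 0.5), sigma = 0.5)  # 1
#' ces_unit_cost(c(1, 2), c(0.3, 0.7), sigma = 0.5)
#' @export
ces_unit_cost <- function(w, theta, sigma, a = 1, w0 = 1, c0 = 1) {
  m <- .ces_args(w, theta, sigma, w0)
  if (any(m$w <= 0)) stop("ces_unit_cost: input prices must be positive")
  if (any(m$sigma <= 0)) stop("ces_unit_cost: sigma must be positive")
  rel <- m$w / m$w0
  cd <- abs(m$sigma - 1) < 1e-12
  out <- numeric(nrow(m$w))
  if (any(cd)) {
    out[cd] <- exp(rowSums(m$theta[cd, , drop = FALSE] *
                             log(rel[cd, , drop = FALSE])))
  }
  if (any(!cd)) {
    s <- m$sigma[!cd]
    B <- rowSums(m$theta[!cd, , drop = FALSE] *
                   rel[!cd, , drop = FALSE]^(1 - s))
    out[!cd] <- B^(1 / (1 - s))
  }
  drop(c0 * out / a)
}

#' CES cost-minimizing input demand
#'
#' Conditional input demands of the CES technology dual to
#' [ces_unit_cost()], by Shephard's lemma. Constant returns to scale make
#' the demands linear in output `Q`; they are homogeneous of degree zero in
#' prices, and exhaust cost: `sum(w * x) == Q * ces_unit_cost(w, ...)`.
#'
#' @inheritParams ces_unit_cost
#' @param Q output quantity, >= 0.
#' @return matrix of input quantities (rows = cases, columns = inputs), or a
#'   named-free numeric vector for a single case.
#' @examples
#' ces_input_demand(1, c(1, 1), c(0.5, 0.5), sigma = 0.5)  # 0.5 0.5
#' @export
ces_input_demand <- function(Q, w, theta, sigma, a = 1, w0 = 1, c0 = 1) {
  m <- .ces_args(w, theta, sigma, w0)
  if (any(m$w <= 0)) stop("ces_input_demand: input prices must be positive")
  if (any(Q < 0)) stop("ces_input_demand: Q must be nonnegative")
  cc <- ces_unit_cost(m$w, m$theta, m$sigma, a = a, w0 = m$w0, c0 = c0)
  rel <- m$w / m$w0
  cd <- abs(m$sigma - 1) < 1e-12
  x <- matrix(NA_real_, nrow(m$w), ncol(m$w))
  if (any(cd)) {
    x[cd, ] <- (Q * cc)[cd] * m$theta[cd, , drop = FALSE] /
      m$w[cd, , drop = FALSE]
  }
  if (any(!cd)) {
    s <- m$sigma[!cd]
    # x_i = Q * dc/dw_i = Q * (c0/a) * (c a / c0)^sigma * theta_i *
    #       (w_i/w0_i)^(-sigma) / w0_i
    fac <- Q * (c0 / a) * (cc * a / c0)^m$sigma
    x[!cd, ] <- fac[!cd] * m$theta[!cd, , drop = FALSE] *
      rel[!cd, , drop = FALSE]^(-s) / m$w0[!cd, , drop = FALSE]
  }
  if (nrow(x) == 1L) drop(x) else x
}

# Recycle price/share/sigma arguments into row-conformable matrices.
.ces_args <- function(w, theta, sigma, w0) {
  if (!is.matrix(w)) w <- matrix(w, nrow = 1)
  if (!is.matrix(theta)) theta <- matrix(theta, nrow(w), ncol(w), byrow = TRUE)
  if (!is.matrix(w0)) {
    w0 <- if (length(w0) == ncol(w) && ncol(w) != 1L) {
      matrix(w0, nrow(w), ncol(w), byrow = TRUE)
    } else {
      matrix(w0, nrow(w), ncol(w))
    }
  }
  if (ncol(theta) != ncol(w)) stop("theta and w must have the same length")
  bad <- abs(rowSums(theta) - 1) > 1e-8
  if (any(bad)) stop("CES cost shares must sum to 1")
  if (any(theta <= 0 | theta >= 1)) stop("CES cost shares must lie in (0,1)")
  list(w = w, theta = theta, sigma = rep_len(sigma, nrow(w)), w0 = w0)
}
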