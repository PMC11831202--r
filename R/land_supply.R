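#' Calibrate a saturating cropland supply curve
#'
#' Cropland supplied in a grid cell responds to the cropland rental rate but
#' saturates at the cell's cultivable-land asymptote `Lambda` (the maximum
#' physically cultivable area). The curve
#' \deqn{L(r) = \Lambda r^\gamma / (r^\gamma + \kappa)}
#' passes through the calibration point (`r0`, `L0`) with point elasticity
#' `eta0` there, via
#' \deqn{\gamma = \eta_0 / (1 - L_0/\Lambda), \qquad
#'       \kappa = r_0^\gamma (\Lambda - L_0)/L_0.}
#' The implied point elasticity declines linearly in land use,
#' \eqn{\eta(L) = \gamma (1 - L/\Lambda)}, reaching zero at the asymptote:
#' physical land limits bind progressively.
#'
#' @param L0 base cropland (ha), 0 < L0 < Lambda.
#' @param Lambda cropland supply asymptote (ha).
#' @param r0 base rental rate (currency/ha), > 0.
#' @param eta0 base point elasticity of land supply, >= 0.
#' @return object of class `land_supply_curve` with fields `gamma`, `kappa`,
#'   `Lambda`, `r0`, `L0`. All fields are vectorized over cells.
#' @export
land_supply_curve <- function(L0, Lambda, r0, eta0) {
  if (any(eta0 < 0)) stop("land supply calibration: eta0 must be >= 0")
  if (any(L0 <= 0)) stop("land supply calibration: L0 must be positive")
  if (any(L0 >= Lambda)) {
    bad <- which(L0 >= Lambda)
    stop("land supply calibration: L0 must be strictly below the asymptote ",
         "Lambda (violated for ", length(bad), " cell(s), first index ",
         bad[1], ")")
  }
  if (any(r0 <= 0)) stop("land supply calibration: r0 must be positive")
  gamma <- eta0 / (1 - L0 / Lambda)
  kappa <- r0^gamma * (Lambda - L0) / L0
  structure(list(gamma = gamma, kappa = kappa, Lambda = Lambda,
                 r0 = r0, L0 = L0),
            class = "land_supply_curve")
}

#' Cropland supplied at a rental rate
#'
#' Evaluates the saturating land supply curve. Strictly increasing in the
#' rent (for `eta0 > 0`), equal to `L0` at `r0`, and approaching `Lambda`
#' from below as the rent grows without bound.
#'
#' @param r rental rate (currency/ha), > 0. Vectorized with the curve.
#' @param curve a [land_supply_curve()].
#' @return cropland (ha).
#' @export
land_supply <- function(r, curve) {
  stopifnot(inherits(curve, "land_supply_curve"))
  if (any(r <= 0)) stop("land_supply: rent must be positive")
  # log-space ratio avoids overflow of r^gamma for extreme rents
  z <- curve$gamma * (log(r) - log(curve$r0))
  # L = Lambda / (1 + kappa / r^gamma); kappa/r^gamma = (kappa/r0^gamma) e^-z
  k0 <- curve$kappa / curve$r0^curve$gamma  # = (Lambda - L0)/L0
  curve$Lambda / (1 + k0 * exp(-z))
}

#' Point elasticity of land supply at a land level
#'
#' \eqn{\eta(L) = \gamma (1 - L/\Lambda)}: declines linearly to zero as the
#' cell fills up toward its cultivable asymptote.
#'
#' @param L cropland (ha), 0 < L < Lambda.
#' @param curve a [land_supply_curve()].
#' @return elasticity (dimensionless).
#' @export
land_supply_elasticity <- function(L, curve) {
  stopifnot(inherits(curve, "land_supply_curve"))
  curve$gamma * (1 - L / curve$Lambda)
}
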