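#' Armington sourcing split
#'
#' Allocates a region's total crop requirement between domestically produced
#' and world-market crops, which are imperfect substitutes (Armington). The
#' sourcing shares respond to relative prices with elasticity `sigma_A`:
#' \deqn{\omega_d \propto b_d (P_d/P_{d0})^{-\sigma_A}, \qquad
#'       \omega_w \propto b_w (P_w/P_{w0})^{-\sigma_A},}
#' normalized to sum to one, so the two sourced quantities always sum
#' exactly to the composite requirement (tons are conserved through the
#' aggregation). As `sigma_A -> 0` the split collapses to the fixed base
#' quantity shares (Leontief sourcing).
#'
#' @param total total composite crop requirement (corn-equivalent tons).
#' @param P_dom,P_world current domestic and world crop prices, > 0.
#' @param shares numeric length-2 vector `c(domestic, world)` of base
#'   sourcing shares, each in (0,1), summing to 1.
#' @param sigma_A Armington substitution elasticity, > 0 (0 allowed as the
#'   Leontief limit).
#' @param P0 length-2 base prices (default both 1).
#' @return list with `from_domestic`, `from_world` (tons) and the shares
#'   used.
#' @export
armington_split <- function(total, P_dom, P_world, shares, sigma_A,
                            P0 = c(1, 1)) {
  .check_two_shares(shares, "armington_split")
  if (any(sigma_A < 0)) stop("armington_split: sigma_A must be >= 0")
  if (any(P_dom <= 0) || any(P_world <= 0)) {
    stop("armington_split: prices must be positive")
  }
  wd <- shares[1] * (P_dom / P0[1])^(-sigma_A)
  ww <- shares[2] * (P_world / P0[2])^(-sigma_A)
  s <- wd / (wd + ww)
  list(from_domestic = total * s, from_world = total * (1 - s),
       share_domestic = s, share_world = 1 - s)
}

#' Armington composite price index
#'
#' CES dual price index of the domestic/world crop composite, used as the
#' price to which regional crop demand responds. Equals 1 at base prices.
#'
#' @inheritParams armington_split
#' @return composite price index (base = 1).
#' @export
armington_price_index <- function(P_dom, P_world, shares, sigma_A,
                                  P0 = c(1, 1)) {
  .check_two_shares(shares, "armington_price_index")
  if (any(P_dom <= 0) || any(P_world <= 0)) {
    stop("armington_price_index: prices must be positive")
  }
  rd <- P_dom / P0[1]
  rw <- P_world / P0[2]
  if (abs(sigma_A - 1) < 1e-12) {
    rd^shares[1] * rw^shares[2]
  } else {
    (shares[1] * rd^(1 - sigma_A) + shares[2] * rw^(1 - sigma_A))^(1 / (1 - sigma_A))
  }
}

#' Producer sales split between domestic and world markets
#'
#' Constant-elasticity-of-transformation style allocation of a region's
#' crop output between the domestic market and the world pool. Shares rise
#' in the relatively better-paying market with elasticity `sigma_T`:
#' \deqn{v_d \propto s_d (P_d/P_{d0})^{\sigma_T}}, normalized so the two
#' sales quantities sum exactly to output.
#'
#' @param output regional crop output (tons).
#' @param P_dom,P_world domestic and world prices, > 0.
#' @param shares base selling shares `c(domestic, world)`.
#' @param sigma_T transformation elasticity, >= 0.
#' @param P0 base prices.
#' @return list with `to_domestic`, `to_world`, and shares.
#' @export
cet_split <- function(output, P_dom, P_world, shares, sigma_T, P0 = c(1, 1)) {
  .check_two_shares(shares, "cet_split")
  if (any(sigma_T < 0)) stop("cet_split: sigma_T must be >= 0")
  vd <- shares[1] * (P_dom / P0[1])^sigma_T
  vw <- shares[2] * (P_world / P0[2])^sigma_T
  s <- vd / (vd + vw)
  list(to_domestic = output * s, to_world = output * (1 - s),
       share_domestic = s, share_world = 1 - s)
}

#' Producer price index over domestic and world sales
#'
#' Revenue-per-ton index faced by the region's crop producers given their
#' base selling shares: the CET dual, equal to 1 at base prices. Grid cells
#' respond to this index through their zero-profit condition.
#'
#' @inheritParams cet_split
#' @return producer price index (base = 1).
#' @export
cet_price_index <- function(P_dom, P_world, shares, sigma_T, P0 = c(1, 1)) {
  .check_two_shares(shares, "cet_price_index")
  rd <- P_dom / P0[1]
  rw <- P_world / P0[2]
  (shares[1] * rd^(1 + sigma_T) + shares[2] * rw^(1 + sigma_T))^(1 / (1 + sigma_T))
}

.check_two_shares <- function(shares, where) {
  if (length(shares) != 2L) stop(where, ": shares must have length 2")
  if (any(shares < 0) || any(shares > 1) || abs(sum(shares) - 1) > 1e-8) {
    stop(where, ": shares must lie in [0,1] and sum to 1")
  }
}
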