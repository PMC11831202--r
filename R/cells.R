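#' Grid-cell crop supply at a producer price
#'
#' Solves each cell's zero-profit condition for the cropland rent and reads
#' quantities off the CES technology and the land supply curve. With the
#' nonland input supplied perfectly elastically at the numeraire price
#' (w_N = 1), the rent solving `unit_cost(r, 1) / A = P` has a closed form:
#' for `sigma != 1`
#' \deqn{(r/r_0)^{1-\sigma} = \frac{(aP)^{1-\sigma} - \theta_N}{\theta_L}}
#' and for the Cobb-Douglas limit `r = r_0 (aP)^{1/\theta_L}`. Land then
#' follows from the supply curve, nonland and output from Shephard's lemma.
#' Under constant returns this pins down the whole cell supply curve:
#' output rises in both the producer price and TFP.
#'
#' If the price is below the minimum attainable unit cost (possible for
#' `sigma < 1`, where land is essential), the cell is at a corner: land,
#' nonland and output are zero and the `corner` flag is set.
#'
#' @param P producer crop price faced by the cell(s) relative to the cell's
#'   base unit cost anchor (1 at the calibration point), > 0 (scalar or
#'   vector recycled over cells).
#' @param cells data.frame of calibrated cells (columns `theta_L`, `sigma`,
#'   `a`, `r0`, `L0`, `Lambda`, `gamma`, `kappa`), as in an `agland_world`.
#' @param c0 base unit cost level per cell (currency/ton; the regional base
#'   producer price; 1 at initial calibration).
#' @return data.frame with columns `r` (rent), `L` (ha), `N`, `Q`
#'   (corn-equivalent tons) and logical `corner`.
#' @export
cell_supply <- function(P, cells, c0 = 1) {
  n <- nrow(cells)
  P <- rep_len(P, n)
  c0 <- rep_len(c0, n)
  if (any(P <= 0)) stop("cell_supply: producer price must be positive")
  a <- cells$a
  thL <- cells$theta_L
  thN <- 1 - thL
  sg <- cells$sigma
  r0 <- cells$r0
  aP <- a * P

  r <- rep(NA_real_, n)
  corner <- rep(FALSE, n)
  cd <- abs(sg - 1) < 1e-12
  if (any(cd)) {
    r[cd] <- r0[cd] * aP[cd]^(1 / thL[cd])
  }
  if (any(!cd)) {
    i <- which(!cd)
    rhs <- (aP[i]^(1 - sg[i]) - thN[i]) / thL[i]
    ok <- rhs > 0
    corner[i[!ok]] <- TRUE
    j <- i[ok]
    r[j] <- r0[j] * rhs[ok]^(1 / (1 - sg[j]))
  }

  L <- N <- Q <- numeric(n)
  live <- !corner
  if (any(live)) {
    curve <- structure(list(gamma = cells$gamma[live],
                            kappa = cells$kappa[live],
                            Lambda = cells$Lambda[live],
                            r0 = r0[live], L0 = cells$L0[live]),
                       class = "land_supply_curve")
    L[live] <- land_supply(r[live], curve)
    # per-unit-output input requirements at (r, w_N = 1), unit cost = P
    sgl <- sg[live]
    cdl <- cd[live]
    l_unit <- n_unit <- numeric(sum(live))
    if (any(cdl)) {
      l_unit[cdl] <- (P[live] * thL[live] / r[live])[cdl]
      n_unit[cdl] <- (P[live] * thN[live])[cdl]
    }
    if (any(!cdl)) {
      fac <- ((1 / a[live]) * (aP[live])^sgl)[!cdl]
      l_unit[!cdl] <- fac * thL[live][!cdl] *
        (r[live][!cdl] / r0[live][!cdl])^(-sgl[!cdl]) / r0[live][!cdl]
      n_unit[!cdl] <- fac * thN[live][!cdl]
    }
    Q[live] <- L[live] / (c0[live] * l_unit)
    N[live] <- Q[live] * c0[live] * n_unit
  }
  r[corner] <- 0
  out <- data.frame(r = r, L = L, N = N, Q = Q, corner = corner)
  if (any(corner)) {
    attr(out, "corner_cells") <- cells$id[corner]
  }
  out
}
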