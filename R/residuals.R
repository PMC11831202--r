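#' Market-clearing residuals
#'
#' Evaluates excess supply (supply minus demand, corn-equivalent tons) in
#' every market at a candidate price vector:
#' \itemize{
#'   \item one residual per regional domestic crop market (domestic sales
#'     minus domestically sourced requirement),
#'   \item one per regional livestock and processed-food market (demand at
#'     the CES unit cost minus demand at the candidate price: these CRS
#'     sectors supply perfectly elastically at unit cost, so the market
#'     clears exactly where price equals unit cost),
#'   \item one world crop market residual (global exports minus global
#'     imports of the world pool).
#' }
#' Prices are actual levels; each behavioral form is anchored at the
#' world's base price levels (all 1 at initial calibration; moved by
#' re-basing), so corn-equivalent tons stay comparable across markets and
#' periods. By construction of the tons-conserving trade splits, the
#' regional net-export residuals `S_w - Qm` sum to minus the world import
#' residual.
#'
#' @param world a (possibly shocked) `agland_world`.
#' @param prices list with `P_dom` (vector, one per region), `P_ls`,
#'   `P_pr` (per region), and scalar `P_world`; all > 0, in levels.
#' @return list with `residuals` (named vector, tons), `scaled` (residuals
#'   divided by base market size), and `state` (the full implied quantity
#'   state: cells data.frame and regions data.frame).
#' @export
market_residuals <- function(world, prices) {
  rg <- world$regions
  cl <- world$cells
  R <- nrow(rg)
  P_d <- rep_len(prices$P_dom, R)
  P_l <- rep_len(prices$P_ls, R)
  P_p <- rep_len(prices$P_pr, R)
  P_w <- prices$P_world
  if (any(c(P_d, P_l, P_p, P_w) <= 0)) {
    stop("market_residuals: prices must be strictly positive")
  }

  # relative composite and producer crop price indices per region (1 at the
  # calibration anchor), and their levels
  I_comp <- I_cet <- numeric(R)
  for (i in seq_len(R)) {
    I_comp[i] <- armington_price_index(P_d[i], P_w,
                                       c(rg$src_d_v[i], rg$src_w_v[i]),
                                       rg$sigma_A[i],
                                       P0 = c(rg$P_d0[i], world$P_w0))
    I_cet[i] <- cet_price_index(P_d[i], P_w,
                                c(rg$sell_d_v[i], rg$sell_w_v[i]),
                                rg$sigma_T[i],
                                P0 = c(rg$P_d0[i], world$P_w0))
  }
  P_comp <- I_comp * rg$P_comp0
  P_prod <- I_cet * rg$P_prod0

  # final demands at relative prices
  D_c <- regional_demand(I_comp, rg$pc_income, rg$population,
                         rg$D0_crops / rg$population, rg$Y0, 1,
                         rg$eps_y_crops, rg$eps_p_crops)
  dem_at <- function(P_rel, D0, ey, ep) {
    ifelse(D0 > 0,
           regional_demand(P_rel, rg$pc_income, rg$population,
                           D0 / rg$population, rg$Y0, 1, ey, ep),
           0)
  }
  D_l <- dem_at(P_l / rg$P_l0, rg$D0_livestock,
                rg$eps_y_livestock, rg$eps_p_livestock)
  D_p <- dem_at(P_p / rg$P_p0, rg$D0_processed,
                rg$eps_y_processed, rg$eps_p_processed)

  # livestock / processed: CES unit cost over (crop composite, noncrop)
  sector <- function(pre, D_sec) {
    out0 <- rg[[paste0(pre, "_output0")]]
    alpha <- rg[[paste0(pre, "_crop_share")]]
    sgm <- rg[[paste0(pre, "_sigma")]]
    a <- rg[[paste0(pre, "_a")]]
    P0_sec <- rg[[paste0("P_", if (pre == "ls") "l" else "p", "0")]]
    D0_sec <- rg[[paste0("D0_", if (pre == "ls") "livestock" else "processed")]]
    ey <- rg[[paste0("eps_y_", if (pre == "ls") "livestock" else "processed")]]
    ep <- rg[[paste0("eps_p_", if (pre == "ls") "livestock" else "processed")]]
    ucost <- feed <- supply_q <- numeric(R)
    for (i in seq_len(R)) {
      if (out0[i] <= 0) next
      w_rel <- c(I_comp[i], 1)
      th <- c(alpha[i], 1 - alpha[i])
      c_rel <- ces_unit_cost(w_rel, th, sgm[i], a = a[i])
      ucost[i] <- c_rel * P0_sec[i]
      # crop-composite input in tons: relative Shephard scaled by the
      # base output/input price-level ratio
      feed[i] <- D_sec[i] *
        ces_input_demand(1, w_rel, th, sgm[i], a = a[i])[1] *
        P0_sec[i] / rg$P_comp0[i]
      supply_q[i] <- dem_at(c_rel, D0_sec, ey, ep)[i]
    }
    list(ucost = ucost, feed = feed, supply_q = supply_q)
  }
  ls <- sector("ls", D_l)
  pr <- sector("pr", D_p)

  # composite crop requirement and Armington sourcing
  QC <- D_c + ls$feed + pr$feed + rg$biofuel
  Qd <- Qm <- numeric(R)
  for (i in seq_len(R)) {
    sp <- armington_split(QC[i], P_d[i], P_w,
                          c(rg$src_d[i], rg$src_w[i]), rg$sigma_A[i],
                          P0 = c(rg$P_d0[i], world$P_w0))
    Qd[i] <- sp$from_domestic
    Qm[i] <- sp$from_world
  }

  # cell supply at the regional producer price, CET sales split
  ridx <- match(cl$region_id, rg$id)
  cs <- cell_supply(I_cet[ridx], cl, c0 = rg$P_prod0[ridx])
  Qsup <- as.numeric(tapply(cs$Q, factor(cl$region_id, levels = rg$id), sum))
  S_d <- S_w <- numeric(R)
  for (i in seq_len(R)) {
    sp <- cet_split(Qsup[i], P_d[i], P_w,
                    c(rg$sell_d[i], rg$sell_w[i]), rg$sigma_T[i],
                    P0 = c(rg$P_d0[i], world$P_w0))
    S_d[i] <- sp$to_domestic
    S_w[i] <- sp$to_world
  }

  res <- c(
    stats::setNames(S_d - Qd, paste0("crops_", rg$id)),
    stats::setNames(ls$supply_q - D_l, paste0("livestock_", rg$id)),
    stats::setNames(pr$supply_q - D_p, paste0("processed_", rg$id)),
    world = sum(S_w) - sum(Qm)
  )
  scale <- c(pmax(rg$QC0, 1e-9), pmax(rg$D0_livestock, 1e-9),
             pmax(rg$D0_processed, 1e-9),
             max(sum(rg$Qm0), 1e-9))
  state <- list(
    cells = data.frame(id = cl$id, region_id = cl$region_id,
                       r = cs$r, L = cs$L, N = cs$N, Q = cs$Q,
                       corner = cs$corner, stringsAsFactors = FALSE),
    regions = data.frame(
      id = rg$id, P_dom = P_d, P_ls = P_l, P_pr = P_p,
      P_comp = P_comp, P_prod = P_prod,
      D_crops = D_c, D_livestock = D_l, D_processed = D_p,
      feed_ls = ls$feed, feed_pr = pr$feed, biofuel = rg$biofuel,
      QC = QC, Qd = Qd, Qm = Qm, Qsup = Qsup, S_d = S_d, S_w = S_w,
      ucost_ls = ls$ucost, ucost_pr = pr$ucost,
      stringsAsFactors = FALSE),
    P_world = P_w
  )
  list(residuals = res, scaled = res / scale, state = state)
}
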