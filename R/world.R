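#' Calibrate a world from base-year tables
#'
#' Builds the model's full economic state from base-year share and level
#' data. All prices are normalized to 1 at the base (output is measured in
#' corn-equivalent tons; the regional nonland-input price is the numeraire),
#' so calibration amounts to backing out quantities and curve constants such
#' that the base year is an exact equilibrium:
#' \itemize{
#'   \item per cell: nonland input `N0`, base rent `r0` from the land cost
#'     share, and the land supply curve constants (`gamma`, `kappa`);
#'   \item per region: the composite crop requirement (final + livestock and
#'     processed feed + biofuel feedstock) and its domestic/world sourcing,
#'     reconciled exactly against domestic sales and the world pool;
#'   \item demand elasticities looked up from the income-elasticity table at
#'     base income.
#' }
#'
#' @param raw list with data.frames `regions`, `cells`, `shares`, `trade`
#'   and a list `config` carrying `elasticity_table` (see
#'   [read_world_bundle()] for the on-disk schema).
#' @param tol relative tolerance for the base market-clearing identities
#'   that the raw tables must satisfy (default 1e-6).
#' @return an object of class `agland_world`.
#' @seealso [make_world()] to generate synthetic raw tables,
#'   [market_residuals()] for the equilibrium conditions.
#' @export
calibrate <- function(raw, tol = 1e-6) {
  rg <- raw$regions
  cl <- raw$cells
  sh <- raw$shares
  tr <- raw$trade
  etab <- raw$config$elasticity_table
  stopifnot(is.data.frame(rg), is.data.frame(cl), is.data.frame(sh),
            is.data.frame(tr))
  validate_elasticity_table(etab)

  if (!all(cl$region_id %in% rg$id)) {
    stop("calibration: cells reference unknown regions: ",
         paste(unique(setdiff(cl$region_id, rg$id)), collapse = ", "))
  }
  # --- cell-level validation and calibration ---------------------------
  if (any(cl$cropland <= 0)) stop("calibration: base cropland must be positive")
  bad <- cl$cropland >= cl$asymptote
  if (any(bad)) {
    stop("calibration: cell(s) ", paste(utils::head(cl$id[bad], 5), collapse = ", "),
         " have base cropland >= cultivable asymptote")
  }
  th <- cl$land_cost_share
  if (any(th <= 0 | th >= 1)) {
    stop("calibration: land cost shares must lie strictly in (0,1)")
  }
  if (any(cl$substitution_elasticity <= 0)) {
    stop("calibration: cell substitution elasticities must be positive")
  }
  if (any(cl$output <= 0)) stop("calibration: base cell output must be positive")

  cells <- data.frame(
    id = as.character(cl$id), region_id = as.character(cl$region_id),
    lon = cl$lon, lat = cl$lat,
    L0 = cl$cropland, Lambda = cl$asymptote, Q0 = cl$output,
    theta_L = th, sigma = cl$substitution_elasticity,
    eta0 = cl$land_supply_elasticity,
    a = 1, stringsAsFactors = FALSE
  )
  # zero profit at base prices (P_prod = 1, w_N = 1): value = Q0
  cells$r0 <- th * cells$Q0 / cells$L0
  cells$N0 <- (1 - th) * cells$Q0
  curve <- land_supply_curve(cells$L0, cells$Lambda, cells$r0, cells$eta0)
  cells$gamma <- curve$gamma
  cells$kappa <- curve$kappa

  # --- sector shares ----------------------------------------------------
  need_sec <- c("livestock", "processed")
  for (r in rg$id) for (s in need_sec) {
    row <- sh[sh$region_id == r & sh$sector == s, ]
    if (nrow(row) != 1L) {
      stop("calibration: region ", r, " must have exactly one '", s,
           "' share row")
    }
    if (abs(row$crop_share + row$noncrop_share - 1) > tol) {
      stop("calibration: input cost shares for region ", r, ", sector ", s,
           " sum to ", row$crop_share + row$noncrop_share, ", not 1")
    }
    if (row$crop_share <= 0 || row$crop_share >= 1) {
      stop("calibration: crop cost share for region ", r, ", sector ", s,
           " must lie in (0,1)")
    }
  }

  # --- regional table ---------------------------------------------------
  ord <- order(rg$id)
  rg <- rg[ord, ]
  regions <- data.frame(
    id = as.character(rg$id), population = rg$population,
    pc_income = rg$pc_income, biofuel = rg$biofuel_demand,
    stringsAsFactors = FALSE
  )
  if (any(regions$population <= 0) || any(regions$pc_income <= 0)) {
    stop("calibration: population and income must be positive")
  }
  for (s in need_sec) {
    pre <- if (s == "livestock") "ls" else "pr"
    rows <- sh[sh$sector == s, ]
    rows <- rows[match(regions$id, rows$region_id), ]
    regions[[paste0(pre, "_output0")]] <- rows$output
    regions[[paste0(pre, "_crop_share")]] <- rows$crop_share
    regions[[paste0(pre, "_sigma")]] <- rows$substitution_elasticity
    regions[[paste0(pre, "_a")]] <- 1
  }
  tr <- tr[match(regions$id, tr$region_id), ]
  for (nm in c("sell_domestic", "sell_world")) {
    if (any(tr[[nm]] < 0 | tr[[nm]] > 1)) stop("calibration: bad selling share")
  }
  if (any(abs(tr$sell_domestic + tr$sell_world - 1) > tol) ||
      any(abs(tr$source_domestic + tr$source_world - 1) > tol)) {
    stop("calibration: trade shares must sum to 1 per region")
  }
  if (any(tr$armington_elasticity <= 0)) {
    stop("calibration: Armington elasticity must be positive")
  }
  regions$sigma_A <- tr$armington_elasticity
  regions$sigma_T <- tr$cet_elasticity

  # base final demand and per-capita calibration point
  regions$D0_crops <- rg$dem_crops
  regions$D0_livestock <- rg$dem_livestock
  regions$D0_processed <- rg$dem_processed
  if (any(rg$biofuel_demand < 0)) stop("calibration: biofuel demand must be >= 0")
  regions$Y0 <- regions$pc_income
  for (cm in c("crops", "livestock", "processed")) {
    e <- demand_elasticities(regions$pc_income, etab, cm)
    regions[[paste0("eps_y_", cm)]] <- e$eps_y
    regions[[paste0("eps_p_", cm)]] <- e$eps_p
  }

  # --- base quantity reconciliation ------------------------------------
  Qsup0 <- tapply(cells$Q0, cells$region_id, sum)[regions$id]
  regions$Qsup0 <- as.numeric(Qsup0)
  # composite crop requirement at base prices = 1: feed quantities equal
  # cost-share * sector output value
  feed_ls <- regions$ls_crop_share * regions$ls_output0
  feed_pr <- regions$pr_crop_share * regions$pr_output0
  regions$QC0 <- regions$D0_crops + feed_ls + feed_pr + regions$biofuel
  S_d0 <- tr$sell_domestic * regions$Qsup0
  S_w0 <- tr$sell_world * regions$Qsup0
  Qd0 <- tr$source_domestic * regions$QC0
  Qm0 <- tr$source_world * regions$QC0
  dom_gap <- abs(S_d0 - Qd0) / pmax(regions$QC0, 1e-12)
  if (any(dom_gap > tol)) {
    stop("calibration: domestic crop market does not clear at base for ",
         "region(s) ", paste(regions$id[dom_gap > tol], collapse = ", "),
         " (relative gap up to ", signif(max(dom_gap), 3), ")")
  }
  wgap <- abs(sum(S_w0) - sum(Qm0)) / max(sum(regions$QC0), 1e-12)
  if (wgap > tol) {
    stop("calibration: world crop market does not clear at base ",
         "(global exports != global imports, relative gap ", signif(wgap, 3), ")")
  }
  # store exact quantities; recompute shares so base residuals are 0
  regions$Qd0 <- S_d0
  regions$Qm0 <- regions$QC0 - S_d0
  regions$sell_d <- S_d0 / regions$Qsup0
  regions$sell_w <- 1 - regions$sell_d
  regions$src_d <- regions$Qd0 / regions$QC0
  regions$src_w <- 1 - regions$src_d
  # quantity shares drive the sourcing/sales allocation; value shares weight
  # the price indices. They coincide at base prices = 1 and are re-based
  # separately between periods so both rules stay invariant to re-basing.
  regions$src_d_v <- regions$src_d
  regions$src_w_v <- regions$src_w
  regions$sell_d_v <- regions$sell_d
  regions$sell_w_v <- regions$sell_w
  # base price levels (all 1 at initial calibration; re-basing between
  # periods moves these anchors instead of renormalizing, so corn-equivalent
  # tons remain comparable across markets and periods)
  regions$P_d0 <- 1
  regions$P_l0 <- 1
  regions$P_p0 <- 1
  regions$P_comp0 <- 1
  regions$P_prod0 <- 1

  world <- structure(list(regions = regions, cells = cells,
                          elasticity_table = etab,
                          P_w0 = 1),
                     class = "agland_world")
  world
}

#' @export
print.agland_world <- function(x, ...) {
  cat("<agland_world> ", nrow(x$regions), " regions, ", nrow(x$cells),
      " grid cells\n", sep = "")
  cat("  base crop output: ", format(sum(x$cells$Q0), big.mark = ","),
      " corn-eq t; cropland: ", format(round(sum(x$cells$L0)), big.mark = ","),
      " ha\n", sep = "")
  invisible(x)
}

#' Downscale regional totals to grid cells
#'
#' Allocates a regional total across the region's cells in proportion to
#' nonnegative spatial weights (e.g. cropland extent x crop production
#' maps). Conservation is exact: within each region the allocated values
#' sum to the regional total.
#'
#' @param regional_totals named numeric vector, names = region ids.
#' @param cell_weights data.frame with columns `cell_id`, `region_id`,
#'   `weight` (>= 0; at least one positive weight per region with a
#'   nonzero total).
#' @return numeric vector of per-cell values, aligned with `cell_weights`
#'   rows and named by `cell_id`.
#' @export
downscale_regional_output <- function(regional_totals, cell_weights) {
  stopifnot(all(c("cell_id", "region_id", "weight") %in% names(cell_weights)))
  if (any(cell_weights$weight < 0)) {
    stop("downscale: weights must be nonnegative")
  }
  out <- numeric(nrow(cell_weights))
  for (r in names(regional_totals)) {
    i <- cell_weights$region_id == r
    tot <- regional_totals[[r]]
    wsum <- sum(cell_weights$weight[i])
    if (wsum == 0) {
      if (tot != 0) {
        stop("downscale: region ", r, " has a nonzero total but all-zero weights")
      }
      out[i] <- 0
    } else {
      out[i] <- tot * cell_weights$weight[i] / wsum
    }
  }
  names(out) <- cell_weights$cell_id
  out
}

#' Downscale improved-variety TFP gains to grid cells
#'
#' The per-cell TFP gain from adoption of improved crop varieties is the
#' production-share-weighted average of regional per-crop gains:
#' \deqn{\tau_g = \sum_c s_{g,c} \, g_{r(g),c}} with cell crop-mix shares
#' `s` (value shares, summing to at most 1 per cell) and regional gains
#' `g >= 0`. Cells growing none of the covered crops get 0; the result is
#' always bounded by the largest crop-level gain.
#'
#' @param regional_gains data.frame with columns `region_id`, `crop`,
#'   `gain` (fractional TFP gain, >= 0).
#' @param cell_crop_mix data.frame with columns `cell_id`, `region_id`,
#'   `crop`, `share` (per-cell shares >= 0 summing to <= 1).
#' @return named numeric vector of per-cell gains `tau_g` (one entry per
#'   distinct `cell_id`, in order of first appearance).
#' @export
downscale_tfp_gain <- function(regional_gains, cell_crop_mix) {
  if (any(regional_gains$gain < 0)) {
    stop("downscale_tfp_gain: gains must be nonnegative")
  }
  if (any(cell_crop_mix$share < 0)) {
    stop("downscale_tfp_gain: crop-mix shares must be nonnegative")
  }
  ssum <- tapply(cell_crop_mix$share, cell_crop_mix$cell_id, sum)
  if (any(ssum > 1 + 1e-8)) {
    stop("downscale_tfp_gain: crop-mix shares must sum to <= 1 per cell")
  }
  key <- paste(cell_crop_mix$region_id, cell_crop_mix$crop, sep = "\r")
  gkey <- paste(regional_gains$region_id, regional_gains$crop, sep = "\r")
  g <- regional_gains$gain[match(key, gkey)]
  g[is.na(g)] <- 0  # crops without a gain estimate contribute nothing
  contrib <- cell_crop_mix$share * g
  ids <- unique(cell_crop_mix$cell_id)
  tau <- tapply(contrib, factor(cell_crop_mix$cell_id, levels = ids), sum)
  out <- as.numeric(tau)
  names(out) <- ids
  out[is.na(out)] <- 0
  out
}
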