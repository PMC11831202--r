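#' Construct a period shock set
#'
#' Bundles one period's exogenous drivers: regional growth rates of
#' population, per-capita income, biofuel feedstock demand, and sectoral
#' TFP (crops, livestock, processed), plus per-cell drivers: the
#' improved-variety TFP gain `tau_g` (the fraction of crop TFP growth
#' attributable to adoption of improved varieties, removed in the
#' counterfactual), the CGIAR-attributed fraction of that gain, and a
#' fractional shift of the cropland-supply asymptote (land-cover change,
#' applied in baseline and counterfactual alike).
#'
#' @param period period label (e.g. "P1").
#' @param regional data.frame with columns `region_id`, `pop_growth`,
#'   `income_growth`, `biofuel_growth`, `tfp_crops`, `tfp_livestock`,
#'   `tfp_processed` (all fractional rates over the period).
#' @param cells data.frame with columns `cell_id`, `tau_g` (>= 0),
#'   `cgiar_fraction` (in [0,1]), `landcover_shift` (fraction, > -1).
#' @return object of class `shock_set`.
#' @export
shock_set <- function(period, regional, cells) {
  need_r <- c("region_id", "pop_growth", "income_growth", "biofuel_growth",
              "tfp_crops", "tfp_livestock", "tfp_processed")
  need_c <- c("cell_id", "tau_g", "cgiar_fraction", "landcover_shift")
  stopifnot(all(need_r %in% names(regional)), all(need_c %in% names(cells)))
  if (!all(is.finite(as.matrix(regional[need_r[-1]])))) {
    stop("shock_set: regional growth rates must be finite")
  }
  if (any(cells$tau_g < 0)) stop("shock_set: tau_g must be >= 0")
  if (any(cells$cgiar_fraction < 0 | cells$cgiar_fraction > 1)) {
    stop("shock_set: cgiar_fraction must lie in [0,1]")
  }
  if (any(cells$landcover_shift <= -1)) {
    stop("shock_set: landcover_shift must exceed -1")
  }
  structure(list(period = period, regional = regional, cells = cells),
            class = "shock_set")
}

#' Zero shocks for a world
#'
#' Convenience constructor: a shock set with all growth rates and per-cell
#' drivers equal to zero, used for fixed-point checks.
#'
#' @param world an `agland_world`.
#' @param period period label.
#' @return a [shock_set()].
#' @export
zero_shocks <- function(world, period = "P0") {
  shock_set(
    period,
    regional = data.frame(region_id = world$regions$id, pop_growth = 0,
                          income_growth = 0, biofuel_growth = 0,
                          tfp_crops = 0, tfp_livestock = 0,
                          tfp_processed = 0),
    cells = data.frame(cell_id = world$cells$id, tau_g = 0,
                       cgiar_fraction = 0, landcover_shift = 0)
  )
}

#' Apply a shock set to a calibrated world
#'
#' Updates the exogenous state ahead of solving one period: population,
#' income, biofuel feedstock, sector TFP, per-cell crop TFP, and the
#' cropland asymptote. Demand elasticities are re-looked-up at the new
#' income level (dietary change with affluence) and held fixed within the
#' period. Under the `no_iv` variant the per-cell crop TFP growth is the
#' regional baseline rate minus the cell's improved-variety gain `tau_g`;
#' under `no_cgiar_iv` only the CGIAR-attributed portion is removed.
#'
#' @param world an `agland_world`.
#' @param shocks a [shock_set()].
#' @param variant one of "baseline", "no_iv", "no_cgiar_iv".
#' @param fraction apply this fraction of the period shock (gross rates
#'   raised to the power `fraction`); used by the multistep solver.
#' @param elasticity_income optional per-region income vector at which to
#'   look up the demand elasticities instead of the post-shock income; the
#'   multistep solver passes the end-of-period income so the elasticities
#'   are fixed over the whole period regardless of stepping.
#' @return a shocked `agland_world` (same class; base/calibration fields
#'   untouched, current state fields updated).
#' @export
apply_shocks <- function(world, shocks, variant = "baseline", fraction = 1,
                         elasticity_income = NULL) {
  variant <- match.arg(variant, c("baseline", "no_iv", "no_cgiar_iv"))
  stopifnot(inherits(shocks, "shock_set"))
  rg <- world$regions
  sr <- shocks$regional[match(rg$id, shocks$regional$region_id), ]
  if (any(is.na(sr$region_id))) {
    stop("apply_shocks: shock set missing regions: ",
         paste(setdiff(rg$id, shocks$regional$region_id), collapse = ", "))
  }
  sc <- shocks$cells[match(world$cells$id, shocks$cells$cell_id), ]
  if (any(is.na(sc$cell_id))) {
    stop("apply_shocks: shock set missing cells")
  }
  gr <- function(g) (1 + g)^fraction  # gross rate for a fractional sub-shock
  rg$population <- rg$population * gr(sr$pop_growth)
  rg$pc_income <- rg$pc_income * gr(sr$income_growth)
  rg$biofuel <- rg$biofuel * gr(sr$biofuel_growth)
  rg$ls_a <- rg$ls_a * gr(sr$tfp_livestock)
  rg$pr_a <- rg$pr_a * gr(sr$tfp_processed)
  e_inc <- if (is.null(elasticity_income)) rg$pc_income else elasticity_income
  for (cm in c("crops", "livestock", "processed")) {
    e <- demand_elasticities(e_inc, world$elasticity_table, cm)
    rg[[paste0("eps_y_", cm)]] <- e$eps_y
    rg[[paste0("eps_p_", cm)]] <- e$eps_p
  }

  cl <- world$cells
  g_crop <- sr$tfp_crops[match(cl$region_id, rg$id)]
  tau_eff <- switch(variant,
                    baseline = 0,
                    no_iv = sc$tau_g,
                    no_cgiar_iv = sc$cgiar_fraction * sc$tau_g)
  mult <- 1 + g_crop - tau_eff
  if (any(mult <= 0)) {
    stop("apply_shocks: counterfactual TFP multiplier nonpositive in ",
         sum(mult <= 0), " cell(s)")
  }
  cl$a <- cl$a * mult^fraction
  # land-cover change scales the whole supply curve proportionally (Lambda
  # scaled, kappa and gamma kept): cropland supplied at any rent shifts by
  # the same factor, and the shift composes path-independently across
  # sub-steps
  cl$Lambda <- cl$Lambda * gr(sc$landcover_shift)

  world$regions <- rg
  world$cells <- cl
  world
}
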