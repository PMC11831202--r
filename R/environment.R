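#' Environmental data layers
#'
#' Per-cell vegetation and soil carbon stocks, ecoregion and country
#' membership, biodiversity-hotspot membership, and the per-ecoregion,
#' per-taxon land-occupation characterization factors (potential species
#' committed to extinction per hectare of cropland, from a countryside
#' species-area relationship; taxa: plants, amphibians, birds, mammals,
#' reptiles).
#'
#' @param cells data.frame with columns `cell_id`, `c_veg` (tC/ha),
#'   `c_soil` (tC/ha), `ecoregion`, `country`, `hotspot` (hotspot id or NA
#'   outside hotspots).
#' @param cf data.frame with columns `ecoregion`, `taxon`, `cf`
#'   (species/ha, >= 0).
#' @return object of class `env_layers`.
#' @export
env_layers <- function(cells, cf) {
  need <- c("cell_id", "c_veg", "c_soil", "ecoregion", "country", "hotspot")
  stopifnot(all(need %in% names(cells)),
            all(c("ecoregion", "taxon", "cf") %in% names(cf)))
  if (any(cells$c_veg < 0) || any(cells$c_soil < 0)) {
    stop("env_layers: carbon stocks must be nonnegative")
  }
  if (any(cf$cf < 0)) stop("env_layers: characterization factors must be >= 0")
  structure(list(cells = cells, cf = cf), class = "env_layers")
}

#' Taxa covered by the biodiversity accounting
#' @export
env_taxa <- function() c("plants", "amphibians", "birds", "mammals", "reptiles")

#' One-time land-use-change carbon emissions
#'
#' Converting natural land to cropland releases the vegetation carbon stock
#' plus a fraction `soil_fraction` of the soil carbon stock, once:
#' \deqn{E_g = \Delta L_g (C_{veg,g} + f_s C_{soil,g}) \times 44/12}
#' in tCO2e. The accounting is signed (cropland contraction gives negative
#' emissions) and linear in the cropland change; foregone future
#' sequestration is not counted.
#'
#' @param dL per-cell cropland change (ha), named by cell id or aligned
#'   with `layers$cells`.
#' @param layers an [env_layers()].
#' @param soil_fraction fraction of the soil carbon stock emitted on
#'   conversion, in [0,1] (default 0.25).
#' @return numeric vector of per-cell emissions (tCO2e), same order as
#'   `layers$cells`.
#' @export
luc_emissions <- function(dL, layers, soil_fraction = 0.25) {
  stopifnot(inherits(layers, "env_layers"))
  if (soil_fraction < 0 || soil_fraction > 1) {
    stop("luc_emissions: soil_fraction must lie in [0,1]")
  }
  dL <- .align_cells(dL, layers)
  lc <- layers$cells
  dL * (lc$c_veg + soil_fraction * lc$c_soil) * (44 / 12)
}

#' Potential species loss from cropland change
#'
#' Applies the per-ecoregion, per-taxon occupation characterization factors
#' to the per-cell cropland change: \eqn{S_t = \sum_g CF_{t,e(g)} \Delta
#' L_g}. Linear and signed, like the carbon accounting; plants are reported
#' alongside (not merged with) the four animal taxa.
#'
#' @inheritParams luc_emissions
#' @return list with `total` (named vector, species per taxon), `by_country`
#'   (data.frame country x taxon), and `per_cell` (matrix cells x taxa).
#' @export
species_loss <- function(dL, layers) {
  stopifnot(inherits(layers, "env_layers"))
  dL <- .align_cells(dL, layers)
  lc <- layers$cells
  missing_eco <- setdiff(unique(lc$ecoregion), unique(layers$cf$ecoregion))
  if (length(missing_eco) > 0) {
    stop("species_loss: no characterization factors for ecoregion(s): ",
         paste(missing_eco, collapse = ", "))
  }
  taxa <- env_taxa()
  per_cell <- matrix(0, nrow(lc), length(taxa),
                     dimnames = list(lc$cell_id, taxa))
  for (t in taxa) {
    cft <- layers$cf[layers$cf$taxon == t, ]
    fac <- cft$cf[match(lc$ecoregion, cft$ecoregion)]
    if (any(is.na(fac))) {
      stop("species_loss: missing ", t, " factors for ecoregion(s): ",
           paste(unique(lc$ecoregion[is.na(fac)]), collapse = ", "))
    }
    per_cell[, t] <- dL * fac
  }
  by_country <- stats::aggregate(per_cell,
                                 by = list(country = lc$country), FUN = sum)
  list(total = colSums(per_cell), by_country = by_country,
       per_cell = per_cell)
}

#' Share of species impact inside biodiversity hotspots
#'
#' @param species_by_cell numeric vector of per-cell species impact (one
#'   taxon, or a sum), aligned with `layers$cells`.
#' @param layers an [env_layers()] whose `hotspot` column gives the hotspot
#'   id for member cells and NA elsewhere.
#' @return list with `share` (impact inside hotspots / global impact; NA
#'   with a warning if the global impact is zero) and `hotspots_touched`
#'   (count of distinct hotspot ids with nonzero impact).
#' @export
hotspot_share <- function(species_by_cell, layers) {
  stopifnot(inherits(layers, "env_layers"))
  hs <- layers$cells$hotspot
  species_by_cell <- .align_cells(species_by_cell, layers)
  total <- sum(species_by_cell)
  inside <- sum(species_by_cell[!is.na(hs)])
  if (total == 0) {
    warning("hotspot_share: zero global impact; share undefined")
    share <- NA_real_
  } else {
    share <- inside / total
  }
  touched <- unique(hs[!is.na(hs) & species_by_cell != 0])
  list(share = share, hotspots_touched = length(touched))
}

#' Aggregate per-taxon species impacts
#'
#' Total species figure across all five taxa (plants plus the four animal
#' groups). Used both on model output and on externally reported per-taxon
#' figures.
#'
#' @param per_taxon named numeric vector of per-taxon species counts.
#' @return their sum.
#' @export
species_total <- function(per_taxon) {
  sum(per_taxon)
}

#' Aggregate per-period impacts to a cumulative total
#'
#' One-time accounting is additive over periods: the cumulative impact is
#' the sum of the per-period increments.
#'
#' @param per_period numeric vector of per-period impact values.
#' @return their sum.
#' @export
cumulative_impact <- function(per_period) {
  sum(per_period)
}

#' Environmental impact report for a scenario comparison
#'
#' Runs the carbon and biodiversity accounting on the per-period
#' incremental cropland differences of a comparison. The sign convention
#' follows the comparison (counterfactual minus baseline): positive values
#' are impacts avoided by the technology under study.
#'
#' @param comparison an `agland_comparison`.
#' @param layers an [env_layers()] covering the comparison's cells.
#' @param soil_fraction see [luc_emissions()].
#' @return object of class `impact_report`: per-period and cumulative
#'   avoided emissions (tCO2e), per-taxon avoided species losses (per
#'   period, cumulative, by country), hotspot share of the cumulative plant
#'   impact, and regional emission aggregates.
#' @export
impact_report <- function(comparison, layers, soil_fraction = 0.25) {
  stopifnot(inherits(comparison, "agland_comparison"),
            inherits(layers, "env_layers"))
  periods <- comparison$periods
  taxa <- env_taxa()
  em_period <- stats::setNames(numeric(length(periods)), periods)
  sp_period <- matrix(0, length(periods), length(taxa),
                      dimnames = list(periods, taxa))
  em_cell_total <- NULL
  for (k in seq_along(periods)) {
    dL <- cropland_difference(comparison, periods[k], incremental = TRUE)
    e <- luc_emissions(dL, layers, soil_fraction)
    em_period[k] <- sum(e)
    em_cell_total <- if (is.null(em_cell_total)) e else em_cell_total + e
    sp_period[k, ] <- species_loss(dL, layers)$total
  }
  dL_total <- cropland_difference(comparison, "total")
  sp_total <- species_loss(dL_total, layers)
  hs <- hotspot_share(sp_total$per_cell[, "plants"], layers)
  reg <- tapply(em_cell_total,
                factor(comparison$per_cell$region_id,
                       levels = unique(comparison$per_cell$region_id)), sum)
  structure(list(
    emissions = list(per_period = em_period,
                     cumulative = cumulative_impact(em_period),
                     per_cell = em_cell_total,
                     by_region = reg),
    species = list(per_period = sp_period,
                   total = sp_total$total,
                   grand_total = species_total(sp_total$total),
                   by_country = sp_total$by_country),
    hotspot = hs,
    soil_fraction = soil_fraction,
    periods = periods
  ), class = "impact_report")
}

#' @export
print.impact_report <- function(x, ...) {
  cat("<impact_report> over ", length(x$periods), " period(s)\n",
      "  avoided LUC emissions: ", signif(x$emissions$cumulative, 4),
      " tCO2e (", paste(signif(x$emissions$per_period, 3), collapse = " + "),
      ")\n  avoided species loss: ", signif(x$species$grand_total, 4),
      " (plants ", signif(x$species$total[["plants"]], 3), ")\n",
      "  hotspot share of plant impact: ", signif(x$hotspot$share, 3),
      "\n", sep = "")
  invisible(x)
}

.align_cells <- function(dL, layers) {
  ids <- layers$cells$cell_id
  if (!is.null(names(dL))) {
    if (!all(ids %in% names(dL))) {
      stop("cropland-change vector does not cover all layer cells")
    }
    dL <- dL[ids]
  } else if (length(dL) != length(ids)) {
    stop("cropland-change vector length does not match the layers")
  }
  unname(dL)
}
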