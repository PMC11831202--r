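#' Specification of a synthetic world
#'
#' Parameters of the seeded toy-world generator. Defaults describe a small
#' three-region economy with the structural features the analysis relies
#' on: saturating land headroom with one land-constrained and one
#' land-abundant region, spatially clustered adoption of improved
#' varieties with first-period gains around 30-40 percent of crop TFP and
#' smaller follow-on gains, lognormal carbon stocks, per-taxon lognormal
#' characterization factors with plants far above the animal taxa, and
#' price-inelastic crop demand (|eps_p| < 1).
#'
#' @param n_regions number of regions (default 3).
#' @param cells_per_region grid cells per region (default 100).
#' @param seed RNG seed; the same seed yields a bit-identical world.
#' @param headroom_meanlog,headroom_sdlog lognormal parameters of the
#'   cell-level excess of the asymptote ratio over 1
#'   (Lambda/L0 = 1 + lognormal).
#' @param adoption_fraction fraction of each region's cells adopting
#'   improved varieties (contiguous blocks).
#' @param adoption_blocks number of contiguous adopting blocks per region.
#' @param tau_range list of length-2 ranges of the per-period
#'   improved-variety TFP gain among covered crops, by period.
#' @param carbon_veg_meanlog,carbon_veg_sdlog,carbon_soil_meanlog,carbon_soil_sdlog
#'   lognormal parameters of vegetation and soil carbon stocks (tC/ha).
#' @param cf_meanlog named per-taxon lognormal meanlog of the
#'   characterization factors (species/ha); plants dominate the animals.
#' @param cf_sdlog common lognormal sdlog of the characterization factors.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(n_regions = 3, cells_per_region = 100, seed = 42,
                       headroom_meanlog = log(1.5), headroom_sdlog = 0.5,
                       adoption_fraction = 0.5, adoption_blocks = 2,
                       tau_range = list(P1 = c(0.20, 0.40),
                                        P2 = c(0.08, 0.20),
                                        P3 = c(0.05, 0.15)),
                       carbon_veg_meanlog = log(80), carbon_veg_sdlog = 0.7,
                       carbon_soil_meanlog = log(60), carbon_soil_sdlog = 0.5,
                       cf_meanlog = c(plants = log(5e-5),
                                      amphibians = log(6e-6),
                                      birds = log(3e-6),
                                      mammals = log(2.5e-6),
                                      reptiles = log(1.5e-6)),
                       cf_sdlog = 0.8) {
  if (adoption_fraction < 0 || adoption_fraction > 1) {
    stop("synth_spec: adoption_fraction must lie in [0,1]")
  }
  for (rg in tau_range) {
    if (length(rg) != 2 || any(rg < 0) || rg[1] > rg[2]) {
      stop("synth_spec: each tau_range entry must be a valid nonnegative range")
    }
  }
  if (!all(env_taxa() %in% names(cf_meanlog))) {
    stop("synth_spec: cf_meanlog must cover all taxa")
  }
  structure(as.list(environment()), class = "synth_spec")
}

#' Synthetic demand-elasticity table
#'
#' Monotone income-to-elasticity mapping with price-inelastic crops
#' (|eps_p| < 1 throughout): absolute elasticities shrink with affluence.
#'
#' @return data.frame usable as an elasticity table.
#' @export
synth_elasticity_table <- function() {
  data.frame(
    income = rep(c(1000, 10000, 50000), times = 3),
    commodity = rep(c("crops", "livestock", "processed"), each = 3),
    eps_y = c(0.50, 0.25, 0.10,
              0.90, 0.60, 0.35,
              0.80, 0.55, 0.30),
    eps_p = c(-0.55, -0.40, -0.25,
              -0.80, -0.55, -0.40,
              -0.75, -0.50, -0.35)
  )
}

#' Generate a synthetic world, shocks and environmental layers
#'
#' Draws the raw base-year tables (regions, cells, sector shares, trade)
#' with base markets clearing exactly, calibrates them through
#' [calibrate()], and builds three periods of shocks (regional growth plus
#' clustered improved-variety TFP gains downscaled through the cell crop
#' mixes) and matching environmental layers. The first region is
#' land-constrained (little headroom over base cropland) and the last is
#' land-abundant.
#'
#' @param spec a [synth_spec()].
#' @return list with `world` (calibrated `agland_world`), `shocks` (list of
#'   three [shock_set()]s), `layers` ([env_layers()]), and `raw` (the raw
#'   input tables, as serialized by [write_world_bundle()]).
#' @export
make_world <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, .make_world_impl(spec))
}

.make_world_impl <- function(spec) {
  R <- spec$n_regions
  C <- spec$cells_per_region
  reg_ids <- sprintf("R%02d", seq_len(R))

  # --- cells -----------------------------------------------------------
  ncell <- R * C
  region_id <- rep(reg_ids, each = C)
  ncolg <- max(1L, floor(sqrt(C)))
  col <- (seq_len(C) - 1) %% ncolg
  row <- (seq_len(C) - 1) %/% ncolg
  lon <- rep(0.25 * col, R) + rep((seq_len(R) - 1) * 10, each = C)
  lat <- rep(0.25 * row, R)
  L0 <- stats::rlnorm(ncell, log(5000), 0.6)
  # headroom: first region constrained, last abundant
  # developing (adopting) regions are relatively land-constrained; the rich
  # non-adopting region is land-abundant
  head_mult <- stats::setNames(rep(0.6, R), reg_ids)
  head_mult[1] <- 0.25
  head_mult[R] <- 3
  headroom <- 1 + stats::rlnorm(ncell, spec$headroom_meanlog,
                                spec$headroom_sdlog) *
    head_mult[region_id]
  Lambda <- L0 * headroom
  # adoption of improved varieties is decided up front (contiguous blocks in
  # the developing regions) because it shapes the base yield map: diffusion
  # favored the better, irrigated cropland, so adopting cells sit on
  # higher-yield land
  adopt <- rep(FALSE, ncell)
  for (r in seq_len(R - 1)) {
    idx <- which(region_id == reg_ids[r])
    n_adopt <- round(spec$adoption_fraction * length(idx))
    if (n_adopt == 0) next
    nb <- max(1L, min(spec$adoption_blocks, n_adopt))
    sizes <- diff(round(seq(0, n_adopt, length.out = nb + 1)))
    slot <- floor(length(idx) / nb)
    for (b in seq_len(nb)) {
      if (sizes[b] == 0) next
      maxoff <- slot - sizes[b]
      off <- if (maxoff > 0) sample.int(maxoff, 1) else 0L
      s0 <- min((b - 1L) * slot + off + 1L, length(idx) - sizes[b] + 1L)
      adopt[idx[seq(s0, length.out = sizes[b])]] <- TRUE
    }
  }
  yield <- stats::rlnorm(ncell, log(3), 0.3) * ifelse(adopt, 1.4, 1)
  Q0 <- L0 * yield
  theta_L <- stats::runif(ncell, 0.2, 0.4)
  # land and nonland inputs are poor substitutes in crop production
  sigma <- stats::runif(ncell, 0.2, 0.5)
  # point elasticity consistent with the saturating curve: moderate curvature
  # (econometric land supply elasticities are well below 1), shrinking with
  # cell fullness so land-constrained cells respond little in either direction
  eta0 <- stats::runif(ncell, 0.25, 0.7) * (1 - L0 / Lambda)
  cells <- data.frame(
    id = sprintf("C%04d", seq_len(ncell)), region_id = region_id,
    lon = lon, lat = lat, cropland = L0, asymptote = Lambda, output = Q0,
    land_cost_share = theta_L, substitution_elasticity = sigma,
    land_supply_elasticity = eta0, stringsAsFactors = FALSE
  )

  # --- regions and base demand system ----------------------------------
  pc_income <- exp(stats::runif(R, log(1500), log(30000)))
  pc_income[1] <- 1800    # constrained, poor region
  pc_income[R] <- 28000   # abundant, rich region
  Qsup0 <- as.numeric(tapply(Q0, factor(region_id, levels = reg_ids), sum))
  sell_w <- stats::runif(R, 0.12, 0.30)
  S_w0 <- sell_w * Qsup0
  Qd0 <- (1 - sell_w) * Qsup0
  # allocate the world pool across importers
  imp_w <- stats::runif(R, 0.5, 1.5)
  Qm0 <- sum(S_w0) * imp_w / sum(imp_w)
  QC0 <- Qd0 + Qm0
  bio_share <- stats::runif(R, 0.01, 0.05)
  feed_ls_share <- stats::runif(R, 0.15, 0.25)
  feed_pr_share <- stats::runif(R, 0.15, 0.25)
  biofuel <- bio_share * QC0
  feed_ls <- feed_ls_share * QC0
  feed_pr <- feed_pr_share * QC0
  dem_crops <- QC0 - biofuel - feed_ls - feed_pr
  ls_crop_share <- stats::runif(R, 0.35, 0.55)
  pr_crop_share <- stats::runif(R, 0.55, 0.75)
  ls_output <- feed_ls / ls_crop_share
  pr_output <- feed_pr / pr_crop_share
  population <- round(stats::runif(R, 2e6, 5e7))

  regions <- data.frame(
    id = reg_ids, population = population, pc_income = pc_income,
    biofuel_demand = biofuel, dem_crops = dem_crops,
    dem_livestock = ls_output, dem_processed = pr_output,
    stringsAsFactors = FALSE
  )
  shares <- rbind(
    data.frame(region_id = reg_ids, sector = "livestock",
               crop_share = ls_crop_share, noncrop_share = 1 - ls_crop_share,
               output = ls_output,
               substitution_elasticity = stats::runif(R, 0.4, 0.7)),
    data.frame(region_id = reg_ids, sector = "processed",
               crop_share = pr_crop_share, noncrop_share = 1 - pr_crop_share,
               output = pr_output,
               substitution_elasticity = stats::runif(R, 0.4, 0.7))
  )
  trade <- data.frame(
    region_id = reg_ids,
    sell_domestic = 1 - sell_w, sell_world = sell_w,
    source_domestic = Qd0 / QC0, source_world = Qm0 / QC0,
    armington_elasticity = stats::runif(R, 1.5, 3.5),
    cet_elasticity = stats::runif(R, 1.5, 3.5)
  )
  raw <- list(regions = regions, cells = cells, shares = shares,
              trade = trade,
              config = list(elasticity_table = synth_elasticity_table()))
  world <- calibrate(raw)

  # --- improved-variety adoption: clustered crop mixes ------------------
  crops <- c("cereal", "root", "legume")
  mix <- NULL
  for (g in seq_len(ncell)) {
    if (!adopt[g]) next
    sh <- stats::runif(length(crops))
    sh <- sh / sum(sh) * stats::runif(1, 0.6, 0.95)  # covered share < 1
    mix <- rbind(mix, data.frame(cell_id = cells$id[g],
                                 region_id = region_id[g],
                                 crop = crops, share = sh))
  }
  cgiar_frac <- ifelse(adopt, stats::runif(ncell, 0.3, 0.7), 0)

  # --- shocks over three periods ---------------------------------------
  # growth paths keep demand expansion slightly ahead of TFP-driven supply
  # growth, so baseline cropland expands and real crop prices drift gently
  # down, as in the historical record
  base_growth <- list(
    P1 = list(pop = 0.70, inc = 0.90, bio = 0.50, tfp = 0.30,
              tfp_ls = 0.25, tfp_pr = 0.20),
    P2 = list(pop = 0.28, inc = 0.50, bio = 0.60, tfp = 0.14,
              tfp_ls = 0.12, tfp_pr = 0.10),
    P3 = list(pop = 0.22, inc = 0.45, bio = 0.80, tfp = 0.12,
              tfp_ls = 0.10, tfp_pr = 0.08)
  )
  shocks <- vector("list", 3)
  names(shocks) <- names(base_growth)
  for (p in names(base_growth)) {
    bg <- base_growth[[p]]
    rgrow <- data.frame(
      region_id = reg_ids,
      pop_growth = bg$pop * stats::runif(R, 0.7, 1.3),
      income_growth = bg$inc * stats::runif(R, 0.7, 1.3),
      biofuel_growth = bg$bio * stats::runif(R, 0.5, 1.5),
      tfp_crops = bg$tfp * stats::runif(R, 0.8, 1.2),
      tfp_livestock = bg$tfp_ls * stats::runif(R, 0.8, 1.2),
      tfp_processed = bg$tfp_pr * stats::runif(R, 0.8, 1.2)
    )
    rng <- spec$tau_range[[p]]
    gains <- data.frame(
      region_id = rep(reg_ids, each = length(crops)),
      crop = rep(crops, R),
      gain = stats::runif(R * length(crops), rng[1], rng[2])
    )
    tau <- stats::setNames(rep(0, ncell), cells$id)
    if (!is.null(mix)) {
      tg <- downscale_tfp_gain(gains, mix)
      tau[names(tg)] <- tg
    }
    cshock <- data.frame(
      cell_id = cells$id, tau_g = as.numeric(tau),
      cgiar_fraction = cgiar_frac,
      landcover_shift = stats::runif(ncell, -0.01, 0.08)
    )
    shocks[[p]] <- shock_set(p, rgrow, cshock)
  }

  # --- environmental layers --------------------------------------------
  n_eco <- 6
  eco <- sprintf("ECO%02d", 1 + (floor(lat / 0.5) %% n_eco))
  country <- paste0(region_id, "_", ifelse(col < ncolg / 2, "A", "B"))
  cf <- data.frame(
    ecoregion = rep(sprintf("ECO%02d", seq_len(n_eco)), times = 5),
    taxon = rep(env_taxa(), each = n_eco),
    stringsAsFactors = FALSE
  )
  cf$cf <- stats::rlnorm(nrow(cf), spec$cf_meanlog[cf$taxon], spec$cf_sdlog)
  # hotspots: the most plant-rich ecoregions actually present on the grid
  # (biodiversity-dense areas)
  pl <- cf[cf$taxon == "plants" & cf$ecoregion %in% unique(eco), ]
  hot_eco <- pl$ecoregion[order(-pl$cf)][seq_len(min(2, nrow(pl)))]
  hotspot <- ifelse(eco %in% hot_eco, paste0("HS_", eco), NA_character_)
  lcell <- data.frame(
    cell_id = cells$id, lon = lon, lat = lat,
    c_veg = stats::rlnorm(ncell, spec$carbon_veg_meanlog,
                          spec$carbon_veg_sdlog),
    c_soil = stats::rlnorm(ncell, spec$carbon_soil_meanlog,
                           spec$carbon_soil_sdlog),
    ecoregion = eco, country = country, hotspot = hotspot,
    stringsAsFactors = FALSE
  )
  layers <- env_layers(lcell, cf)

  list(world = world, shocks = shocks, layers = layers, raw = raw)
}

#' Minimal two-cell world for brute-force oracle checks
#'
#' One autarkic region with two grid cells, no livestock or processed
#' sector, no biofuel: the equilibrium system reduces to a single domestic
#' crop market residual, small enough for exhaustive price bisection.
#'
#' @return list with `world` (calibrated) and `raw` (its input tables).
#' @export
make_two_cell_oracle_world <- function() {
  regions <- data.frame(
    id = "R01", population = 1e6, pc_income = 5000, biofuel_demand = 0,
    dem_crops = 800, dem_livestock = 0, dem_processed = 0,
    stringsAsFactors = FALSE
  )
  cells <- data.frame(
    id = c("C0001", "C0002"), region_id = "R01",
    lon = c(0, 0.25), lat = c(0, 0),
    cropland = c(100, 150), asymptote = c(220, 450),
    output = c(300, 500),
    land_cost_share = c(0.30, 0.35),
    substitution_elasticity = c(0.6, 0.7),
    land_supply_elasticity = c(0.5, 0.8),
    stringsAsFactors = FALSE
  )
  shares <- data.frame(
    region_id = "R01", sector = c("livestock", "processed"),
    crop_share = c(0.45, 0.65), noncrop_share = c(0.55, 0.35),
    output = c(0, 0), substitution_elasticity = c(0.5, 0.5)
  )
  trade <- data.frame(
    region_id = "R01", sell_domestic = 1, sell_world = 0,
    source_domestic = 1, source_world = 0,
    armington_elasticity = 2, cet_elasticity = 2
  )
  raw <- list(regions = regions, cells = cells, shares = shares,
              trade = trade,
              config = list(elasticity_table = synth_elasticity_table()))
  list(world = calibrate(raw), raw = raw)
}
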