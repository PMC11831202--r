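#' Write a world input bundle
#'
#' Serializes the raw base-year tables to a directory: `regions.csv`,
#' `cells.csv`, `shares.csv`, `trade.csv` and `config.yaml` (scalars and
#' the income-elasticity table). Numeric columns are written with 17
#' significant digits so a write/read cycle is lossless and repeated
#' write-read cycles are byte-identical.
#'
#' @param raw raw table list as consumed by [calibrate()] (e.g. the `raw`
#'   element of [make_world()]).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world_bundle <- function(raw, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_csv17(raw$regions, file.path(dir, "regions.csv"))
  .write_csv17(raw$cells, file.path(dir, "cells.csv"))
  .write_csv17(raw$shares, file.path(dir, "shares.csv"))
  .write_csv17(raw$trade, file.path(dir, "trade.csv"))
  cfg <- raw$config
  cfg$elasticity_table <- lapply(
    seq_len(nrow(cfg$elasticity_table)),
    function(i) as.list(cfg$elasticity_table[i, , drop = FALSE])
  )
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"), precision = 15)
  invisible(dir)
}

#' Read a world input bundle
#'
#' Inverse of [write_world_bundle()].
#'
#' @param dir directory holding the bundle.
#' @return raw table list suitable for [calibrate()].
#' @export
read_world_bundle <- function(dir) {
  need <- c("regions.csv", "cells.csv", "shares.csv", "trade.csv",
            "config.yaml")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0) {
    stop("read_world_bundle: missing file(s) in ", dir, ": ",
         paste(missing, collapse = ", "))
  }
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  et <- do.call(rbind, lapply(cfg$elasticity_table, as.data.frame))
  cfg$elasticity_table <- et
  list(
    regions = utils::read.csv(file.path(dir, "regions.csv"),
                              stringsAsFactors = FALSE),
    cells = utils::read.csv(file.path(dir, "cells.csv"),
                            stringsAsFactors = FALSE),
    shares = utils::read.csv(file.path(dir, "shares.csv"),
                             stringsAsFactors = FALSE),
    trade = utils::read.csv(file.path(dir, "trade.csv"),
                            stringsAsFactors = FALSE),
    config = cfg
  )
}

#' Write period shock files
#'
#' One `shocks_<period>_regional.csv` and `shocks_<period>_cells.csv` pair
#' per period.
#'
#' @param shocks list of [shock_set()]s.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_shock_files <- function(shocks, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in shocks) {
    .write_csv17(s$regional,
                 file.path(dir, paste0("shocks_", s$period, "_regional.csv")))
    .write_csv17(s$cells,
                 file.path(dir, paste0("shocks_", s$period, "_cells.csv")))
  }
  invisible(dir)
}

#' Read period shock files
#'
#' @param dir directory written by [write_shock_files()].
#' @param periods period labels to read, in order.
#' @return list of [shock_set()]s.
#' @export
read_shock_files <- function(dir, periods) {
  out <- vector("list", length(periods))
  names(out) <- periods
  for (p in periods) {
    fr <- file.path(dir, paste0("shocks_", p, "_regional.csv"))
    fc <- file.path(dir, paste0("shocks_", p, "_cells.csv"))
    if (!file.exists(fr) || !file.exists(fc)) {
      stop("read_shock_files: missing shock files for period ", p)
    }
    out[[p]] <- shock_set(p,
                          utils::read.csv(fr, stringsAsFactors = FALSE),
                          utils::read.csv(fc, stringsAsFactors = FALSE))
  }
  out
}

#' Write environmental layers
#'
#' `layers_cells.csv` (cell id, lon, lat, carbon stocks, ecoregion,
#' country, hotspot) and `layers_cf.csv` (ecoregion x taxon factors).
#'
#' @param layers an [env_layers()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_layer_files <- function(layers, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_csv17(layers$cells, file.path(dir, "layers_cells.csv"))
  .write_csv17(layers$cf, file.path(dir, "layers_cf.csv"))
  invisible(dir)
}

#' Read environmental layers
#'
#' @param dir directory written by [write_layer_files()].
#' @return an [env_layers()].
#' @export
read_layer_files <- function(dir) {
  lc <- utils::read.csv(file.path(dir, "layers_cells.csv"),
                        stringsAsFactors = FALSE, na.strings = c("NA", ""))
  lc$hotspot <- as.character(lc$hotspot)  # stays character when all-NA
  env_layers(lc, utils::read.csv(file.path(dir, "layers_cf.csv"),
                                 stringsAsFactors = FALSE))
}

#' Run the full simulation pipeline from a configuration
#'
#' Reads a world bundle, shock files and environmental layers, runs the
#' baseline and the requested counterfactual variant over the configured
#' periods, and writes: per-period equilibrium tables
#' (`equilibrium_<variant>_<period>.csv`, with units in the headers), the
#' gridded cropland-difference layer (`difference_grid.csv`), the impact
#' report (`impact_summary.csv`, `species_by_country.csv`), and a run
#' manifest (`manifest.json` with the configuration hash and package
#' version). All inputs are read and validated before any output is
#' written.
#'
#' @param config list (or path to a YAML file) with entries `world_dir`,
#'   `shock_dir`, `layer_dir`, `periods` (character vector), `variant`
#'   ("no_iv" or "no_cgiar_iv"), `out_dir`, optional `solver` (options
#'   list), `soil_fraction`, `n_steps`.
#' @return the `agland_comparison`, invisibly; outputs on disk.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  need <- c("world_dir", "shock_dir", "layer_dir", "periods", "variant",
            "out_dir")
  missing <- setdiff(need, names(config))
  if (length(missing) > 0) {
    stop("run_pipeline: config missing entries: ",
         paste(missing, collapse = ", "))
  }
  variant <- match.arg(config$variant, c("no_iv", "no_cgiar_iv"))
  periods <- as.character(config$periods)
  solver <- if (is.null(config$solver)) list() else config$solver
  soil_fraction <- if (is.null(config$soil_fraction)) 0.25 else config$soil_fraction
  n_steps <- if (is.null(config$n_steps)) 1L else as.integer(config$n_steps)

  raw <- read_world_bundle(config$world_dir)
  world <- calibrate(raw)
  shocks <- read_shock_files(config$shock_dir, periods)
  layers <- read_layer_files(config$layer_dir)

  base <- run_scenario(world, shocks, "baseline", solver, n_steps)
  cf <- run_scenario(world, shocks, variant, solver, n_steps)
  cmp <- compare_scenarios(base, cf)
  rep <- impact_report(cmp, layers, soil_fraction)

  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (run in list(base, cf)) {
    for (p in periods) {
      st <- run$states[[p]]
      eq <- merge(st$cells,
                  st$regions[c("id", "P_dom", "P_comp", "P_prod")],
                  by.x = "region_id", by.y = "id", sort = FALSE)
      names(eq) <- c("region_id", "cell_id", "rent_per_ha", "cropland_ha",
                     "nonland_input", "output_corn_eq_t", "corner",
                     "price_domestic_crop", "price_crop_composite",
                     "price_producer_crop")
      .write_csv17(eq, file.path(out, paste0("equilibrium_", run$variant,
                                             "_", p, ".csv")))
    }
  }
  grid <- cmp$per_cell
  names(grid) <- sub("^dL_", "d_cropland_ha_", names(grid))
  names(grid)[names(grid) == "dL_total"] <- "d_cropland_ha_total"
  .write_csv17(grid, file.path(out, "difference_grid.csv"))
  summ <- data.frame(
    period = c(cmp$periods, "cumulative"),
    d_cropland_ha = c(cmp$per_period$d_cropland_ha,
                      cmp$cumulative$d_cropland_ha),
    d_output_corn_eq_t = c(cmp$per_period$d_output_t,
                           cmp$cumulative$d_output_t),
    d_price_pct = c(cmp$per_period$d_price_pct, cmp$cumulative$d_price_pct),
    emissions_avoided_tco2e = c(rep$emissions$per_period,
                                rep$emissions$cumulative)
  )
  sp <- rbind(rep$species$per_period, total = rep$species$total)
  summ <- cbind(summ, as.data.frame(sp))
  names(summ)[seq(ncol(summ) - 4, ncol(summ))] <-
    paste0("species_saved_", env_taxa())
  .write_csv17(summ, file.path(out, "impact_summary.csv"))
  .write_csv17(rep$species$by_country, file.path(out, "species_by_country.csv"))

  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, cfg_file)
  manifest <- list(
    config = config,
    config_md5 = unname(tools::md5sum(cfg_file)),
    package_version = as.character(utils::packageVersion("agland")),
    r_version = R.version.string,
    variant = variant, periods = periods
  )
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(cmp)
}

# CSV writer with lossless numeric formatting (17 significant digits):
# read.csv followed by .write_csv17 is idempotent at the byte level.
.write_csv17 <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- sprintf("%.17g", out[[j]])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
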