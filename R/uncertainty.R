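#' Define a parameter space for uncertainty propagation
#'
#' Each entry names a model parameter (by path), a sampling distribution
#' for its multiplicative scale factor, and an optional grouping tag:
#' entries sharing a group are driven by the same Latin-hypercube column
#' (jointly scaled). Supported paths:
#' \describe{
#'   \item{cells:sigma}{cell land/nonland substitution elasticities}
#'   \item{cells:eta0}{cell land supply elasticities (curve re-calibrated)}
#'   \item{regions:sigma_A}{Armington elasticities}
#'   \item{regions:sigma_T}{export transformation elasticities}
#'   \item{demand:eps_p}{all own-price demand elasticities (table-wide)}
#'   \item{demand:eps_y}{all income demand elasticities (table-wide)}
#'   \item{layers:carbon}{vegetation and soil carbon stocks}
#'   \item{layers:cf_plants}{plant characterization factors}
#'   \item{layers:cf_animals}{animal characterization factors}
#' }
#'
#' @param entries data.frame with columns `path`, `dist` ("uniform" or
#'   "triangular"), `lower`, `upper`, optional `mode` (triangular peak,
#'   defaults to the midpoint) and `group` (defaults to the path).
#' @return object of class `parameter_space`.
#' @export
parameter_space <- function(entries) {
  stopifnot(is.data.frame(entries),
            all(c("path", "dist", "lower", "upper") %in% names(entries)))
  known <- c("cells:sigma", "cells:eta0", "regions:sigma_A",
             "regions:sigma_T", "demand:eps_p", "demand:eps_y",
             "layers:carbon", "layers:cf_plants", "layers:cf_animals")
  bad <- setdiff(entries$path, known)
  if (length(bad) > 0) {
    stop("parameter_space: unknown parameter path(s): ",
         paste(bad, collapse = ", "))
  }
  if (!all(entries$dist %in% c("uniform", "triangular"))) {
    stop("parameter_space: dist must be 'uniform' or 'triangular'")
  }
  if (!all(is.finite(entries$lower)) || !all(is.finite(entries$upper)) ||
      any(entries$lower > entries$upper)) {
    stop("parameter_space: need finite bounds with lower <= upper")
  }
  if (is.null(entries$mode)) entries$mode <- (entries$lower + entries$upper) / 2
  entries$mode <- ifelse(is.na(entries$mode),
                         (entries$lower + entries$upper) / 2, entries$mode)
  if (any(entries$mode < entries$lower | entries$mode > entries$upper)) {
    stop("parameter_space: triangular mode must lie within the bounds")
  }
  if (is.null(entries$group)) entries$group <- entries$path
  entries$group <- ifelse(is.na(entries$group), entries$path, entries$group)
  structure(list(entries = entries), class = "parameter_space")
}

#' Default parameter space
#'
#' Synthetic placeholder ranges (+/- 50 percent uniform scale factors) over
#' the economic response parameters and the environmental factors; the
#' real study would take its ranges from measured parameter uncertainty.
#'
#' @return a [parameter_space()].
#' @export
default_parameter_space <- function() {
  parameter_space(data.frame(
    path = c("cells:sigma", "cells:eta0", "regions:sigma_A", "demand:eps_p",
             "layers:carbon", "layers:cf_plants", "layers:cf_animals"),
    dist = "uniform", lower = 0.5, upper = 1.5
  ))
}

#' Latin-hypercube sample of a parameter space
#'
#' Stratified sampling: for each sampled column, the `n` draws occupy each
#' of the `n` equal-probability strata exactly once. Entries sharing a
#' `group` receive the same underlying draw. Deterministic given `seed`.
#'
#' @param space a [parameter_space()].
#' @param n number of samples, >= 1.
#' @param seed integer RNG seed.
#' @return numeric matrix `n` x `nrow(entries)`, columns named by path.
#' @export
lhs_sample <- function(space, n, seed) {
  stopifnot(inherits(space, "parameter_space"), n >= 1)
  en <- space$entries
  groups <- unique(en$group)
  u <- with_seed(seed, lhs::randomLHS(n, length(groups)))
  colnames(u) <- groups
  out <- matrix(NA_real_, n, nrow(en), dimnames = list(NULL, en$path))
  for (i in seq_len(nrow(en))) {
    ui <- u[, en$group[i]]
    out[, i] <- switch(en$dist[i],
      uniform = en$lower[i] + (en$upper[i] - en$lower[i]) * ui,
      triangular = qtriangular(ui, en$lower[i], en$upper[i], en$mode[i])
    )
  }
  out
}

#' Triangular distribution quantile function
#'
#' @param p probabilities in [0,1].
#' @param lower,upper,mode distribution support and peak.
#' @return quantiles.
#' @export
qtriangular <- function(p, lower, upper, mode) {
  stopifnot(all(p >= 0 & p <= 1), lower <= upper,
            mode >= lower, mode <= upper)
  if (upper == lower) return(rep(lower, length(p)))
  Fc <- (mode - lower) / (upper - lower)
  ifelse(p < Fc,
         lower + sqrt(p * (upper - lower) * (mode - lower)),
         upper - sqrt((1 - p) * (upper - lower) * (upper - mode)))
}

#' Apply one sampled parameter vector
#'
#' Scales the targeted parameters of a world and environmental layers by
#' the sampled multipliers. Land supply curves are re-calibrated when the
#' base land supply elasticity is scaled.
#'
#' @param world an `agland_world`.
#' @param layers an [env_layers()] (or NULL if only economic paths are
#'   sampled).
#' @param sample named numeric vector (one row of [lhs_sample()]).
#' @return list with scaled `world` and `layers`.
#' @export
apply_parameter_sample <- function(world, layers, sample) {
  for (path in names(sample)) {
    v <- sample[[path]]
    if (path == "cells:sigma") {
      world$cells$sigma <- world$cells$sigma * v
    } else if (path == "cells:eta0") {
      world$cells$eta0 <- world$cells$eta0 * v
      cv <- land_supply_curve(world$cells$L0, world$cells$Lambda,
                              world$cells$r0, world$cells$eta0)
      world$cells$gamma <- cv$gamma
      world$cells$kappa <- cv$kappa
    } else if (path == "regions:sigma_A") {
      world$regions$sigma_A <- world$regions$sigma_A * v
    } else if (path == "regions:sigma_T") {
      world$regions$sigma_T <- world$regions$sigma_T * v
    } else if (path == "demand:eps_p") {
      world$elasticity_table$eps_p <- world$elasticity_table$eps_p * v
      for (cm in c("crops", "livestock", "processed")) {
        world$regions[[paste0("eps_p_", cm)]] <-
          world$regions[[paste0("eps_p_", cm)]] * v
      }
    } else if (path == "demand:eps_y") {
      world$elasticity_table$eps_y <- world$elasticity_table$eps_y * v
      for (cm in c("crops", "livestock", "processed")) {
        world$regions[[paste0("eps_y_", cm)]] <-
          world$regions[[paste0("eps_y_", cm)]] * v
      }
    } else if (path == "layers:carbon") {
      layers$cells$c_veg <- layers$cells$c_veg * v
      layers$cells$c_soil <- layers$cells$c_soil * v
    } else if (path == "layers:cf_plants") {
      i <- layers$cf$taxon == "plants"
      layers$cf$cf[i] <- layers$cf$cf[i] * v
    } else if (path == "layers:cf_animals") {
      i <- layers$cf$taxon != "plants"
      layers$cf$cf[i] <- layers$cf$cf[i] * v
    } else {
      stop("apply_parameter_sample: unknown path ", path)
    }
  }
  list(world = world, layers = layers)
}

#' Propagate parameter uncertainty through the scenario pair
#'
#' For each Latin-hypercube sample, re-scales the parameters, runs the
#' baseline/counterfactual scenario pair, and records the headline
#' outputs: global cropland saving (ha), global output difference (t),
#' global price difference (percent), avoided LUC emissions (tCO2e), and
#' avoided species losses (total and per taxon). Reports the mean and the
#' 2.5th / 97.5th percentiles (linear interpolation between order
#' statistics). Samples whose solver fails are recorded and excluded with
#' a warning; more than 10 percent failures aborts.
#'
#' @param world calibrated `agland_world`.
#' @param shock_sequence list of [shock_set()]s.
#' @param layers an [env_layers()].
#' @param space a [parameter_space()].
#' @param n number of Latin-hypercube samples.
#' @param seed RNG seed for the sampling plan.
#' @param variant counterfactual variant (default "no_iv").
#' @param options solver options.
#' @param soil_fraction see [luc_emissions()].
#' @return object of class `uncertainty_report`: `summary` (data.frame
#'   metric / mean / p2.5 / p97.5), `samples` (per-sample metric values),
#'   `n_failed`.
#' @export
run_uncertainty <- function(world, shock_sequence, layers, space, n, seed,
                            variant = "no_iv", options = list(),
                            soil_fraction = 0.25) {
  plan <- lhs_sample(space, n, seed)
  rows <- vector("list", n)
  failed <- 0L
  for (s in seq_len(n)) {
    scaled <- apply_parameter_sample(world, layers, plan[s, ])
    rows[[s]] <- tryCatch({
      base <- run_scenario(scaled$world, shock_sequence, "baseline", options)
      cf <- run_scenario(scaled$world, shock_sequence, variant, options)
      cmp <- compare_scenarios(base, cf)
      rep <- impact_report(cmp, scaled$layers, soil_fraction)
      c(cropland_saving_ha = cmp$cumulative$d_cropland_ha,
        output_difference_t = cmp$cumulative$d_output_t,
        price_difference_pct = cmp$cumulative$d_price_pct,
        emissions_avoided_tco2e = rep$emissions$cumulative,
        species_saved_total = rep$species$grand_total,
        stats::setNames(rep$species$total,
                        paste0("species_saved_", names(rep$species$total))))
    }, error = function(e) {
      failed <<- failed + 1L
      NULL
    })
  }
  if (failed > 0.1 * n) {
    stop("run_uncertainty: ", failed, " of ", n, " samples failed to solve")
  }
  if (failed > 0) {
    warning("run_uncertainty: excluded ", failed, " failed sample(s)")
  }
  mat <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  qs <- apply(mat, 2, stats::quantile, probs = c(0.025, 0.975), type = 7)
  summary <- data.frame(metric = colnames(mat),
                        mean = colMeans(mat),
                        p2.5 = qs[1, ], p97.5 = qs[2, ],
                        row.names = NULL)
  structure(list(summary = summary, samples = as.data.frame(mat),
                 n = n, n_failed = failed, seed = seed),
            class = "uncertainty_report")
}

#' @export
print.uncertainty_report <- function(x, ...) {
  cat("<uncertainty_report> ", x$n - x$n_failed, " of ", x$n,
      " Latin-hypercube samples\n", sep = "")
  print(transform(x$summary, mean = signif(mean, 4), p2.5 = signif(p2.5, 4),
                  p97.5 = signif(p97.5, 4)), row.names = FALSE)
  invisible(x)
}

#' Evaluate a function with a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the previous RNG state so
#' sampling plans are reproducible without disturbing the caller's stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
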