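#' Re-base a world at a solved equilibrium
#'
#' Sequential comparative statics: the solved state becomes the next
#' period's calibration point. All prices are renormalized to 1 (relative
#' price information is preserved in the re-based share parameters), cell
#' TFP multipliers are absorbed into the new base, and:
#' \itemize{
#'   \item cell cost shares become the realized value shares (the standard
#'     calibrated-share re-basing, under which the CES cost function is
#'     unchanged as a function);
#'   \item the land supply curve keeps its shape: the new anchor (r, L)
#'     lies on the old curve, so `kappa` is unchanged;
#'   \item trade allocation shares become realized quantity shares and the
#'     price-index weights the correspondingly updated value weights, so
#'     both trade rules are also invariant to re-basing.
#' }
#'
#' @param state an `agland_equilibrium` from [solve_equilibrium()].
#' @return a calibrated `agland_world` anchored at the solved state.
#' @export
rebase_world <- function(state) {
  stopifnot(inherits(state, "agland_equilibrium"))
  w <- state$world
  cs <- state$cells
  rs <- state$regions
  if (any(cs$corner)) {
    stop("rebase_world: cannot re-base a state with corner cells (",
         sum(cs$corner), " cell(s) at zero land)")
  }
  cl <- w$cells
  stopifnot(identical(cl$id, cs$id))
  P_prod <- rs$P_prod[match(cl$region_id, rs$id)]
  cl$L0 <- cs$L
  cl$N0 <- cs$N
  cl$Q0 <- cs$Q
  cl$r0 <- cs$r
  cl$theta_L <- cs$r * cs$L / (P_prod * cs$Q)
  cl$a <- 1
  cl$kappa <- cl$r0^cl$gamma * (cl$Lambda - cl$L0) / cl$L0
  cl$eta0 <- cl$gamma * (1 - cl$L0 / cl$Lambda)

  rg <- w$regions
  stopifnot(identical(rg$id, rs$id))
  P_w <- state$prices$P_world
  # move the base price anchors to the solved levels
  rg$P_d0 <- rs$P_dom
  rg$P_l0 <- ifelse(rg$ls_output0 > 0, rs$P_ls, rg$P_l0)
  rg$P_p0 <- ifelse(rg$pr_output0 > 0, rs$P_pr, rg$P_p0)
  rg$P_comp0 <- rs$P_comp
  rg$P_prod0 <- rs$P_prod
  w$P_w0 <- P_w
  rg$Y0 <- rg$pc_income
  rg$D0_crops <- rs$D_crops
  rg$D0_livestock <- rs$D_livestock
  rg$D0_processed <- rs$D_processed
  for (pre in c("ls", "pr")) {
    out0 <- if (pre == "ls") rs$D_livestock else rs$D_processed
    feed <- if (pre == "ls") rs$feed_ls else rs$feed_pr
    uc <- if (pre == "ls") rs$ucost_ls else rs$ucost_pr
    has <- rg[[paste0(pre, "_output0")]] > 0
    rg[[paste0(pre, "_output0")]] <- ifelse(has, out0, 0)
    newshare <- ifelse(has, rs$P_comp * feed / (uc * pmax(out0, 1e-300)), NA)
    rg[[paste0(pre, "_crop_share")]][has] <- newshare[has]
    rg[[paste0(pre, "_a")]] <- 1
  }
  rg$QC0 <- rs$QC
  rg$Qd0 <- rs$Qd
  rg$Qm0 <- rs$Qm
  rg$Qsup0 <- rs$Qsup
  rg$src_d <- rs$Qd / rs$QC
  rg$src_w <- 1 - rg$src_d
  rg$sell_d <- rs$S_d / rs$Qsup
  rg$sell_w <- 1 - rg$sell_d
  # value shares at the solved prices weight the re-based price indices
  vsrc <- rs$P_dom * rs$Qd
  vsrc_w <- P_w * rs$Qm
  rg$src_d_v <- vsrc / (vsrc + vsrc_w)
  rg$src_w_v <- 1 - rg$src_d_v
  vsell <- rs$P_dom * rs$S_d
  vsell_w <- P_w * rs$S_w
  rg$sell_d_v <- vsell / (vsell + vsell_w)
  rg$sell_w_v <- 1 - rg$sell_d_v

  w$cells <- cl
  w$regions <- rg
  w
}

#' Run a multi-period scenario
#'
#' Solves the periods of a shock sequence in order, re-basing the world at
#' each solved state before applying the next period's shocks: the
#' historical windows are chained as sequential comparative statics.
#'
#' @param world a calibrated `agland_world`.
#' @param shock_sequence list of [shock_set()]s, in period order.
#' @param variant "baseline", "no_iv" (all improved-variety TFP gains
#'   removed) or "no_cgiar_iv" (only the CGIAR-attributed portion removed).
#' @param options solver options, see [solve_equilibrium()].
#' @param n_steps sub-shock steps per period (see [solve_multistep()]).
#' @return object of class `agland_scenario`: list with `states` (one
#'   `agland_equilibrium` per period), `periods`, `variant`.
#' @export
run_scenario <- function(world, shock_sequence, variant = "baseline",
                         options = list(), n_steps = 1L) {
  if (length(shock_sequence) == 0L) {
    stop("run_scenario: shock_sequence must contain at least one period")
  }
  ok <- vapply(shock_sequence, inherits, logical(1), "shock_set")
  if (!all(ok)) stop("run_scenario: shock_sequence must be a list of shock_set")
  states <- vector("list", length(shock_sequence))
  w <- world
  for (k in seq_along(shock_sequence)) {
    states[[k]] <- solve_multistep(w, shock_sequence[[k]], n_steps = n_steps,
                                   variant = variant, options = options)
    if (k < length(shock_sequence)) w <- rebase_world(states[[k]])
  }
  periods <- vapply(shock_sequence, function(s) as.character(s$period),
                    character(1))
  structure(list(states = stats::setNames(states, periods),
                 periods = periods, variant = variant),
            class = "agland_scenario")
}

#' Compare baseline and counterfactual scenario runs
#'
#' Differences are counterfactual minus baseline, so positive cropland
#' differences are "land savings" attributable to the technology removed in
#' the counterfactual. Cropland is a stock: the per-period value is the
#' change in the difference over the period (increments sum exactly to the
#' end-of-horizon difference); crop output is a flow (per-period flow
#' differences; the cumulative entry is the end-of-horizon flow
#' difference); the global crop price difference is the percentage gap of
#' the chained world price relatives.
#'
#' @param baseline,counterfactual `agland_scenario` objects over the same
#'   world and period list.
#' @return object of class `agland_comparison`: `per_cell` (per-period
#'   incremental and total cropland differences, ha), `regional`,
#'   `per_period` (global increments), and `cumulative`.
#' @export
compare_scenarios <- function(baseline, counterfactual) {
  stopifnot(inherits(baseline, "agland_scenario"),
            inherits(counterfactual, "agland_scenario"))
  if (!identical(baseline$periods, counterfactual$periods)) {
    stop("compare_scenarios: period lists differ")
  }
  ids <- baseline$states[[1]]$cells$id
  if (!identical(ids, counterfactual$states[[1]]$cells$id)) {
    stop("compare_scenarios: scenarios were run on different worlds")
  }
  P <- length(baseline$periods)
  cl0 <- baseline$states[[1]]$world$cells
  per_cell <- data.frame(cell_id = ids,
                         region_id = cl0$region_id,
                         lon = cl0$lon, lat = cl0$lat,
                         stringsAsFactors = FALSE)
  dL_end_prev <- rep(0, length(ids))
  per_period <- data.frame(period = baseline$periods,
                           d_cropland_ha = NA_real_,
                           d_cropland_end_ha = NA_real_,
                           d_output_t = NA_real_,
                           d_price_pct = NA_real_)
  regional <- NULL
  for (k in seq_len(P)) {
    sb <- baseline$states[[k]]
    sc <- counterfactual$states[[k]]
    dL_end <- sc$cells$L - sb$cells$L
    inc <- dL_end - dL_end_prev
    per_cell[[paste0("dL_", baseline$periods[k])]] <- inc
    per_period$d_cropland_ha[k] <- sum(inc)
    per_period$d_cropland_end_ha[k] <- sum(dL_end)
    per_period$d_output_t[k] <- sum(sc$cells$Q) - sum(sb$cells$Q)
    # world price levels are comparable across periods (anchored re-basing)
    per_period$d_price_pct[k] <- 100 *
      (sc$prices$P_world / sb$prices$P_world - 1)
    reg_inc <- tapply(inc, factor(per_cell$region_id,
                                  levels = unique(per_cell$region_id)), sum)
    regional <- rbind(regional,
                      data.frame(period = rep(baseline$periods[k],
                                              length(reg_inc)),
                                 region_id = names(reg_inc),
                                 d_cropland_ha = as.numeric(reg_inc),
                                 row.names = NULL,
                                 stringsAsFactors = FALSE))
    dL_end_prev <- dL_end
  }
  per_cell$dL_total <- dL_end_prev
  structure(list(
    per_cell = per_cell,
    regional = regional,
    per_period = per_period,
    cumulative = list(
      d_cropland_ha = sum(dL_end_prev),
      d_output_t = per_period$d_output_t[P],
      d_price_pct = per_period$d_price_pct[P]
    ),
    periods = baseline$periods,
    variants = c(baseline = baseline$variant,
                 counterfactual = counterfactual$variant)
  ), class = "agland_comparison")
}

#' @export
print.agland_comparison <- function(x, ...) {
  cat("<agland_comparison> ", x$variants[["counterfactual"]], " - ",
      x$variants[["baseline"]], " over ", length(x$periods), " period(s)\n",
      "  cumulative cropland difference: ",
      format(round(x$cumulative$d_cropland_ha), big.mark = ","), " ha\n",
      "  cumulative output difference:   ",
      format(round(x$cumulative$d_output_t), big.mark = ","), " t\n",
      "  cumulative price difference:    ",
      signif(x$cumulative$d_price_pct, 4), " %\n", sep = "")
  invisible(x)
}

#' Per-cell cropland differences from a comparison
#'
#' @param comparison an `agland_comparison`.
#' @param period a period label, or "total" for the end-of-horizon
#'   difference.
#' @param incremental if TRUE (default) return the change in the difference
#'   over the period; if FALSE the stock difference at the period's end.
#' @return named numeric vector of per-cell cropland differences (ha),
#'   counterfactual minus baseline.
#' @export
cropland_difference <- function(comparison, period = "total",
                                incremental = TRUE) {
  stopifnot(inherits(comparison, "agland_comparison"))
  pc <- comparison$per_cell
  if (period == "total") {
    out <- pc$dL_total
  } else {
    if (!period %in% comparison$periods) {
      stop("cropland_difference: unknown period '", period, "'")
    }
    k <- match(period, comparison$periods)
    if (incremental) {
      out <- pc[[paste0("dL_", period)]]
    } else {
      out <- rowSums(as.matrix(pc[paste0("dL_", comparison$periods[seq_len(k)])]))
    }
  }
  stats::setNames(out, pc$cell_id)
}
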