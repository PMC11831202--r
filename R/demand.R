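#' Regional commodity demand
#'
#' Constant-elasticity final demand per region and commodity:
#' \deqn{D = N \, d_0 \, (Y/Y_0)^{\varepsilon_y} (P/P_0)^{\varepsilon_p}}
#' with population `N`, per-capita income `Y`, commodity price `P`, and the
#' calibration point (`d0`, `Y0`, `P0`). Elasticities evolve with income
#' (richer regions respond less to both prices and income); they are looked
#' up once per period from the income-elasticity table, not inside the
#' solver.
#'
#' @param P commodity price (composite price for crops).
#' @param Y per-capita income (currency/person/yr).
#' @param N_pop population (persons).
#' @param d0 base per-capita demand (corn-equivalent tons/person/yr).
#' @param Y0,P0 calibration income and price.
#' @param eps_y income elasticity, >= 0.
#' @param eps_p own-price elasticity, <= 0.
#' @return demand (corn-equivalent tons/yr).
#' @export
regional_demand <- function(P, Y, N_pop, d0, Y0, P0, eps_y, eps_p) {
  if (any(P <= 0) || any(Y <= 0) || any(N_pop <= 0)) {
    stop("regional_demand: P, Y and N_pop must be positive")
  }
  if (any(eps_y < 0)) stop("regional_demand: income elasticity must be >= 0")
  if (any(eps_p > 0)) stop("regional_demand: price elasticity must be <= 0")
  N_pop * d0 * (Y / Y0)^eps_y * (P / P0)^eps_p
}

#' Income-dependent demand elasticities
#'
#' Interpolates income and own-price demand elasticities from a lookup table
#' mapping per-capita income to elasticities per commodity. The table must
#' be monotone: as income rises, `eps_y` does not increase and `eps_p` does
#' not decrease (absolute responsiveness shrinks with affluence, the
#' standard Engel/Bennett pattern). Interpolation is linear in log income,
#' with flat extrapolation beyond the table range.
#'
#' @param income per-capita income(s) at which to look up.
#' @param table data.frame with columns `income`, `commodity`, `eps_y`,
#'   `eps_p`.
#' @param commodity commodity name(s), recycled against `income`.
#' @return data.frame with columns `eps_y`, `eps_p`.
#' @export
demand_elasticities <- function(income, table, commodity) {
  validate_elasticity_table(table)
  n <- max(length(income), length(commodity))
  income <- rep_len(income, n)
  commodity <- rep_len(commodity, n)
  out <- data.frame(eps_y = numeric(n), eps_p = numeric(n))
  for (cm in unique(commodity)) {
    tab <- table[table$commodity == cm, ]
    if (nrow(tab) == 0L) {
      stop("demand_elasticities: no table entries for commodity '", cm, "'")
    }
    tab <- tab[order(tab$income), ]
    i <- commodity == cm
    lx <- log(pmin(pmax(income[i], min(tab$income)), max(tab$income)))
    if (nrow(tab) == 1L) {
      out$eps_y[i] <- tab$eps_y
      out$eps_p[i] <- tab$eps_p
    } else {
      out$eps_y[i] <- stats::approx(log(tab$income), tab$eps_y, lx)$y
      out$eps_p[i] <- stats::approx(log(tab$income), tab$eps_p, lx)$y
    }
  }
  out
}

#' Validate an income-elasticity table
#'
#' Checks the monotonicity contract: per commodity, `eps_y` non-increasing
#' and `eps_p` non-decreasing in income, with `eps_y >= 0 >= eps_p`.
#'
#' @param table data.frame with columns `income`, `commodity`, `eps_y`,
#'   `eps_p`.
#' @return the table, invisibly, if valid; otherwise an error.
#' @export
validate_elasticity_table <- function(table) {
  need <- c("income", "commodity", "eps_y", "eps_p")
  if (!all(need %in% names(table))) {
    stop("elasticity table must have columns ", paste(need, collapse = ", "))
  }
  if (any(table$eps_y < 0) || any(table$eps_p > 0)) {
    stop("elasticity table: require eps_y >= 0 and eps_p <= 0")
  }
  for (cm in unique(table$commodity)) {
    tab <- table[table$commodity == cm, ]
    tab <- tab[order(tab$income), ]
    if (is.unsorted(-tab$eps_y) || is.unsorted(tab$eps_p)) {
      stop("elasticity table not monotone in income for commodity '", cm,
           "': |elasticities| must shrink as income grows")
    }
  }
  invisible(table)
}
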