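# Reform scenarios. Because the CBS base is the highest national price per
# brand, a producer gains nothing by pricing below that maximum, so prices
# per category are uniform across states in every scenario:
#   I   minimum price adjustment -- the lowest uniform price keeping the
#       tax burden strictly below 100% in every state;
#   II  keep the consumer-share-weighted average pre-reform markup;
#   III keep the maximum pre-reform markup across states.
# Smokers respond through the total price elasticity; the illicit segment
# is held fixed at its calibrated size.

#' Post-reform uniform national price per price category
#'
#' Computes the uniform price of each legal category under one of the
#' three industry strategies. Prices are maximised over states because the
#' binding state is the one with the highest combined rate (the uniform
#' price must be feasible everywhere). Scenario II prices are floored at
#' the scenario I price as a safeguard (any non-negative markup already
#' implies a price at or above the feasibility floor).
#'
#' @param scenario `"I"`, `"II"` or `"III"`.
#' @param markups A `"markup_table"` from [baseline_markups()]; not needed
#'   for scenario I.
#' @param costs A [cost_table()].
#' @param regime_reform The post-reform [tax_regime()].
#' @return Named vector of prices (BRL/pack) for `PC2`, `PC3`, `PC4`.
#' @examples
#' scenario_price("I", costs = default_cost_table(),
#'                regime_reform = default_reform_regime())
#' @export
scenario_price <- function(scenario = c("I", "II", "III"), markups = NULL,
                           costs, regime_reform) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(costs, "cost_table"))
  states <- brazil_states()$state
  price <- stats::setNames(numeric(3), legal_pcs())
  if (scenario != "I" && is.null(markups)) {
    stop("scenarios II and III need the baseline markup table")
  }
  for (k in legal_pcs()) {
    ck <- as.numeric(costs)[match(k, names(costs))]
    floor_k <- max(vapply(states, floor_price, numeric(1),
                          unit_cost = ck, regime = regime_reform))
    if (scenario == "I") {
      price[k] <- floor_k
    } else {
      m <- switch(scenario, II = markups$weighted_average[[k]],
                  III = markups$maximum[[k]])
      p <- max(vapply(states, price_from_markup, numeric(1),
                      markup = m, unit_cost = ck, regime = regime_reform))
      price[k] <- max(p, floor_k)
    }
  }
  price
}

#' Apply the demand response to new uniform prices
#'
#' For every legal (state, category) cell, the relative price change
#' `D = (p_new - p_old) / p_old` is measured against the state's baseline
#' price. Cell consumption (packs) scales linearly by the total elasticity,
#' `1 + e_total(region, PC) * D`, the smoker count by the prevalence
#' component, `1 + e_prev(region) * D`, and the intensity is the implied
#' consumption per remaining smoker. Both factors are floored at zero: a
#' price increase beyond the linear extrapolation limit (`|e * D| >= 1`)
#' clamps the cell to zero with a warning. Illicit (PC1) cells never
#' change: their size is held constant after calibration and smokers do
#' not switch categories.
#'
#' @param market A [market_state()] (baseline, typically calibrated).
#' @param elasticities An [elasticity_table()].
#' @param new_prices Named vector of uniform prices for `PC2`, `PC3`,
#'   `PC4`.
#' @return A [market_state()] with updated smoker counts, intensities and
#'   prices.
#' @export
demand_response <- function(market, elasticities, new_prices) {
  stopifnot(inherits(market, "market_state"),
            inherits(elasticities, "elasticity_table"))
  if (!all(legal_pcs() %in% names(new_prices))) {
    stop("new_prices must be named PC2, PC3, PC4")
  }
  out <- market
  clamped <- 0L
  for (i in which(out$pc != "PC1")) {
    k <- out$pc[i]
    r <- as.character(out$region[i])
    p_old <- out$mean_price[i]
    p_new <- new_prices[[k]]
    delta <- (p_new - p_old) / p_old
    q_fac <- 1 + elasticities$total[r, k] * delta
    s_fac <- 1 + elasticities$prevalence[r] * delta
    if (q_fac < 0 || s_fac < 0) {
      clamped <- clamped + 1L
      q_fac <- max(q_fac, 0)
      s_fac <- max(s_fac, 0)
    }
    packs <- out$smokers[i] * out$mean_cpd[i]
    new_packs <- packs * q_fac
    new_smokers <- out$smokers[i] * s_fac
    out$smokers[i] <- new_smokers
    out$mean_cpd[i] <- if (new_smokers > 0) new_packs / new_smokers else 0
    out$mean_price[i] <- p_new
  }
  if (clamped > 0) {
    warning(sprintf(paste("price change beyond the linear elasticity",
                          "extrapolation limit in %d cell(s); consumption",
                          "clamped at zero"), clamped))
  }
  tot <- tapply(out$smokers, out$state, sum)
  out$share <- ifelse(tot[out$state] > 0, out$smokers / tot[out$state], 0)
  out
}

#' Run one reform scenario end to end
#'
#' Composes pricing, demand response and revenue aggregation: baseline
#' markups are measured under current rules, the scenario's uniform prices
#' are computed under the reform regime, smokers adjust via the total
#' elasticity, and yearly revenue is re-assessed cell by cell at the new
#' prices.
#'
#' @param scenario `"I"`, `"II"` or `"III"`.
#' @param market Calibrated baseline [market_state()].
#' @param elasticities An [elasticity_table()].
#' @param regime_now Current-rules [tax_regime()].
#' @param regime_reform Post-reform [tax_regime()].
#' @param costs A [cost_table()].
#' @return An object of class `"scenario_result"`: list with `scenario`,
#'   `prices` (uniform BRL/pack per category), `burden` (consumption-
#'   weighted tax burden per category), `consumption_change_pc` (% per
#'   category), `consumption_change_cells` (per state and category),
#'   `revenue_total`, `revenue_by_state`, `revenue_by_pc`,
#'   `revenue_share_pc` (%), `baseline_revenue`, `revenue_change_pct`, and
#'   the post-response `market`.
#' @examples
#' \donttest{
#' svy <- generate_survey(generator_config(seed = 11, n_respondents = 20000))
#' cal <- calibrate_illicit_market(aggregate_market(svy),
#'                                 default_current_regime(), 17.75e9)
#' run_scenario("I", cal$market, default_elasticity_table(),
#'              default_current_regime(), default_reform_regime(),
#'              default_cost_table())
#' }
#' @export
run_scenario <- function(scenario, market, elasticities, regime_now,
                         regime_reform, costs) {
  scenario <- match.arg(scenario, c("I", "II", "III"))
  markups <- baseline_markups(market, regime_now, costs)
  prices <- scenario_price(scenario, markups, costs, regime_reform)
  post <- demand_response(market, elasticities, prices)

  legal_pre <- market$pc != "PC1"
  packs_pre <- packs_per_year(market)
  packs_post <- packs_per_year(post)

  # revenue at uniform prices under the reform regime
  rev_cell <- numeric(nrow(post))
  burden_cell <- numeric(nrow(post))
  for (i in which(post$pc != "PC1")) {
    a <- assess(post$mean_price[i], post$mean_price[i], post$state[i],
                regime_reform)
    rev_cell[i] <- packs_post[i] * a$total_tax
    burden_cell[i] <- a$burden
  }
  revenue_by_state <- tapply(rev_cell, post$state, sum)
  revenue_by_pc <- tapply(rev_cell, post$pc, sum)[legal_pcs()]
  revenue_total <- sum(rev_cell)

  burden <- cons_change <- stats::setNames(numeric(3), legal_pcs())
  for (k in legal_pcs()) {
    sel <- post$pc == k
    burden[k] <- weighted_mean(burden_cell[sel], packs_post[sel])
    cons_change[k] <- 100 * (sum(packs_post[sel]) / sum(packs_pre[sel]) - 1)
  }
  cells <- data.frame(state = post$state, pc = post$pc,
                      consumption_change_pct =
                        ifelse(packs_pre > 0,
                               100 * (packs_post / packs_pre - 1), 0),
                      stringsAsFactors = FALSE)

  base_rev <- baseline_revenue(market, regime_now)
  structure(list(scenario = scenario,
                 prices = prices,
                 burden = burden,
                 consumption_change_pc = cons_change,
                 consumption_change_cells = cells[legal_pre, , drop = FALSE],
                 revenue_total = revenue_total,
                 revenue_by_state = revenue_by_state,
                 revenue_by_pc = revenue_by_pc,
                 revenue_share_pc = 100 * revenue_by_pc / revenue_total,
                 baseline_revenue = base_rev,
                 revenue_change_pct = percent_change(revenue_total, base_rev),
                 markups = markups,
                 market = post),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> Scenario %s\n", x$scenario))
  tab <- rbind(`price (BRL/pack)` = round(x$prices, 2),
               `tax burden (%)` = round(100 * x$burden, 1),
               `consumption change (%)` = round(x$consumption_change_pc, 1),
               `share in collection (%)` = round(x$revenue_share_pc, 2))
  print(tab)
  cat(sprintf("  revenue %.2f BRL Bi/year (baseline %.2f, change %+.1f%%)\n",
              x$revenue_total / 1e9, x$baseline_revenue / 1e9,
              x$revenue_change_pct))
  invisible(x)
}

#' Summary table across scenarios
#'
#' Stacks baseline features and per-scenario results into the standard
#' comparison layout: yearly collection and its change, then price, tax
#' burden, share in collection and consumption change per legal category.
#'
#' @param baseline_market Calibrated baseline [market_state()].
#' @param regime_now Current-rules [tax_regime()].
#' @param results List of `"scenario_result"` objects.
#' @return A `data.frame` with a `feature` column and one column per
#'   scenario (plus `baseline`).
#' @export
scenario_table <- function(baseline_market, regime_now, results) {
  stopifnot(length(results) >= 1)
  base_rev <- baseline_revenue(baseline_market, regime_now)
  legal <- baseline_market[baseline_market$pc != "PC1", , drop = FALSE]
  packs <- packs_per_year(baseline_market)[baseline_market$pc != "PC1"]
  pmax_pc <- tapply(legal$mean_price, legal$pc, max)
  base_price <- base_burden <- base_share <- stats::setNames(numeric(3),
                                                             legal_pcs())
  rev_cell <- vapply(seq_len(nrow(legal)), function(i) {
    assess(legal$mean_price[i], pmax_pc[[legal$pc[i]]], legal$state[i],
           regime_now)$total_tax
  }, numeric(1)) * packs
  for (k in legal_pcs()) {
    sel <- legal$pc == k
    base_price[k] <- weighted_mean(legal$mean_price[sel], packs[sel])
    base_burden[k] <- weighted_mean(rev_cell[sel] / packs[sel] /
                                      legal$mean_price[sel], packs[sel])
    base_share[k] <- 100 * sum(rev_cell[sel]) / sum(rev_cell)
  }

  feature <- c("Tax collection (BRL Bi per year)", "Change (Baseline ref, %)")
  for (k in legal_pcs()) {
    feature <- c(feature, paste0(k, ": price (BRL)"),
                 paste0(k, ": tax burden (%)"),
                 paste0(k, ": share in tax collection (%)"),
                 paste0(k, ": consumption (% change)"))
  }
  out <- data.frame(feature = feature, stringsAsFactors = FALSE)
  col_base <- c(round(base_rev / 1e9, 2), NA)
  for (k in legal_pcs()) {
    col_base <- c(col_base, round(base_price[k], 2),
                  round(100 * base_burden[k], 1),
                  round(base_share[k], 2), NA)
  }
  out$baseline <- col_base
  for (res in results) {
    col <- c(round(res$revenue_total / 1e9, 2), res$revenue_change_pct)
    for (k in legal_pcs()) {
      col <- c(col, round(res$prices[[k]], 2),
               round(100 * res$burden[[k]], 1),
               round(res$revenue_share_pc[[k]], 2),
               round(res$consumption_change_pc[[k]], 1))
    }
    out[[paste0("scenario_", res$scenario)]] <- col
  }
  out
}
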