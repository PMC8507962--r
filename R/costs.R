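# Unit production costs per price category (constant across states: under
# current rules markups differ across states because taxes and logistics
# differ, while production costs are basically the same).

#' Unit cost table
#'
#' Production cost from factory to point of sale, BRL per pack, one value
#' per legal price category (the illicit segment is outside the taxed
#' market and carries no cost entry).
#'
#' @param costs Named numeric vector with entries `PC2`, `PC3`, `PC4`,
#'   all positive.
#' @return An object of class `"cost_table"`.
#' @examples
#' cost_table(c(PC2 = 0.65, PC3 = 0.66, PC4 = 2.90))
#' @export
cost_table <- function(costs) {
  if (!all(legal_pcs() %in% names(costs))) {
    stop("costs must be named PC2, PC3, PC4")
  }
  costs <- costs[legal_pcs()]
  if (any(costs <= 0)) stop("unit costs must be positive")
  if (is.unsorted(costs, strictly = FALSE)) {
    warning("unit costs are not non-decreasing across price categories")
  }
  structure(as.numeric(costs), names = legal_pcs(), class = "cost_table")
}

#' Default unit costs
#'
#' The default fixture back-solves unit costs from the default baseline
#' price grid so that every state's implied markup is positive: low- and
#' medium-price brands share an almost identical manufacturing cost
#' (0.650 / 0.653 BRL per pack -- their price difference is markup, not
#' cost), while premium brands cost 2.90 BRL per pack. Near-identical
#' low/medium costs are what makes their minimum feasible prices collapse
#' to (essentially) one price after the reform.
#'
#' @return A [cost_table()].
#' @export
default_cost_table <- function() {
  cost_table(c(PC2 = 0.650, PC3 = 0.653, PC4 = 2.90))
}

#' @export
print.cost_table <- function(x, ...) {
  cat("<cost_table> BRL/pack:",
      paste(sprintf("%s %.3f", names(x), as.numeric(x)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Baseline markups per state and price category
#'
#' The producer markup over unit cost implied by observed prices under the
#' current regime: `m(s, k) = (p(s, k) - tax(s, k) - cost(k)) / cost(k)`
#' for every legal cell. Errors if any implied markup is negative (the
#' cost table is then inconsistent with observed prices). Also returns the
#' consumer-share-weighted average and the maximum markup per category,
#' the two statistics the reform scenarios use.
#'
#' @param market A [market_state()].
#' @param regime A [tax_regime()] (current rules).
#' @param costs A [cost_table()].
#' @return An object of class `"markup_table"`: list with `cells`
#'   (data.frame state/pc/markup), `weighted_average` and `maximum` (named
#'   by category), and `weights` description.
#' @export
baseline_markups <- function(market, regime, costs) {
  stopifnot(inherits(market, "market_state"), inherits(costs, "cost_table"))
  legal <- market[market$pc != "PC1", , drop = FALSE]
  pmax_pc <- tapply(legal$mean_price, legal$pc, max)
  ck <- as.numeric(costs)[match(legal$pc, names(costs))]
  tax <- vapply(seq_len(nrow(legal)), function(i) {
    assess(legal$mean_price[i], pmax_pc[[legal$pc[i]]], legal$state[i],
           regime)$total_tax
  }, numeric(1))
  m <- (legal$mean_price - tax - ck) / ck
  if (any(m < 0)) {
    bad <- which(m < 0)
    stopf("negative implied markup in %s: unit costs inconsistent with %s",
          paste(sprintf("%s/%s (%.3f)", legal$state[bad], legal$pc[bad],
                        m[bad])[seq_len(min(5, length(bad)))],
                collapse = ", "),
          "observed prices")
  }
  wavg <- mx <- stats::setNames(numeric(3), legal_pcs())
  for (k in legal_pcs()) {
    sel <- legal$pc == k
    wavg[k] <- weighted_mean(m[sel], legal$smokers[sel])
    mx[k] <- max(m[sel])
  }
  structure(list(cells = data.frame(state = legal$state, pc = legal$pc,
                                    markup = m, stringsAsFactors = FALSE),
                 weighted_average = wavg, maximum = mx,
                 weights = "share of consumers (smokers) per state"),
            class = "markup_table")
}

#' @export
print.markup_table <- function(x, ...) {
  cat("<markup_table> producer markup over unit cost\n")
  print(round(rbind(`weighted average` = x$weighted_average,
                    maximum = x$maximum), 3))
  invisible(x)
}
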