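# Shared fixtures, built in code.

# CBS special regime in isolation: 22% on the highest national brand price
# plus 1.10 BRL/pack.
cbs_only_regime <- function() {
  tax_regime(list(
    tax_component("cbs_ad_valorem", "ad_valorem", rate = 0.22,
                  base = "highest_national_brand_price"),
    tax_component("cbs_specific", "specific", amount = 1.10)
  ), name = "CBS only")
}

# Flat single-state-invariant regime from an (alpha, beta) pair.
flat_regime <- function(alpha = 0, beta = 0) {
  comps <- list()
  if (alpha > 0) {
    comps <- c(comps, list(tax_component("av", "ad_valorem", rate = alpha)))
  }
  if (beta > 0) {
    comps <- c(comps, list(tax_component("sp", "specific", amount = beta)))
  }
  tax_regime(comps, name = sprintf("flat a=%.2f b=%.2f", alpha, beta))
}

# Independent grid-search oracle for the minimum feasible price: scan the
# 0.01-BRL grid upward for the first price whose net-of-tax revenue covers
# the unit cost with a strictly positive margin over taxes.
floor_price_grid <- function(unit_cost, alpha, beta) {
  p_hi <- (beta + unit_cost) / (1 - alpha) + 0.05
  grid <- seq(0.01, max(p_hi, 0.02), by = 0.01)
  profit <- grid * (1 - alpha) - beta
  ok <- profit - unit_cost >= -1e-9 & profit > 1e-9
  if (!any(ok)) stop("grid oracle found no feasible price")
  grid[which(ok)[1]]
}

# Hand-built market over a subset of states; remaining cells get zero
# smokers so constructor invariants still hold.
hand_market <- function(cells, price_floor = 5) {
  pops <- stats::setNames(rep(1e6, length(unique(cells$state))),
                          unique(cells$state))
  market_state(cells, populations = pops, price_floor = price_floor)
}

# Survey and market fixtures shared by several test files (generated once).
tiny_cfg <- function(seed = 42, n = 20000, ...) {
  generator_config(seed = seed, n_respondents = n, ...)
}

shared_survey <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_survey(tiny_cfg())
    cache
  }
})

shared_market <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- aggregate_market(shared_survey())
    cache
  }
})

# Default-fixture baseline: market calibrated to the 17.75 BRL Bi yearly
# collection under current rules.
shared_calibrated <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- calibrate_illicit_market(shared_market(),
                                         default_current_regime(), 17.75e9)
    }
    cache
  }
})
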