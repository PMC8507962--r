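# Industry price-setting scenarios and the demand response.

test_that("baseline markups match hand arithmetic", {
  cells <- data.frame(state = c("SP", "SP", "SP", "SP"),
                      pc = c("PC1", "PC2", "PC3", "PC4"),
                      smokers = c(0, 100, 100, 100),
                      mean_price = c(0.4, 5.00, 6.00, 12.00),
                      mean_cpd = c(0, 10, 10, 10))
  mk <- hand_market(cells, price_floor = 0.5)
  # no taxes, price = 2 x cost: markup 1 everywhere
  costs <- cost_table(c(PC2 = 2.50, PC3 = 3.00, PC4 = 6.00))
  m <- baseline_markups(mk, tax_regime(), costs)
  expect_equal(unname(m$weighted_average), rep(1, 3))
  expect_equal(unname(m$maximum), rep(1, 3))
  # with a specific tax of 1 BRL: (5 - 1 - 2.5) / 2.5 = 0.6
  m2 <- baseline_markups(mk, flat_regime(beta = 1), costs)
  expect_equal(m2$weighted_average[["PC2"]], 0.6, tolerance = 1e-12)
  # costs inconsistent with prices are an error
  expect_error(baseline_markups(mk, flat_regime(beta = 3),
                                cost_table(c(PC2 = 2.5, PC3 = 3.2,
                                             PC4 = 11.5))),
               "inconsistent")
})

test_that("markups differ across states exactly when tax rates differ", {
  cells <- data.frame(state = rep(c("SP", "RJ"), each = 4),
                      pc = rep(c("PC1", "PC2", "PC3", "PC4"), 2),
                      smokers = rep(c(0, 100, 100, 100), 2),
                      mean_price = rep(c(4.0, 6.00, 8.00, 13.00), 2),
                      mean_cpd = rep(c(0, 10, 10, 10), 2))
  mk <- hand_market(cells)
  costs <- default_cost_table()
  same <- baseline_markups(mk, flat_regime(alpha = 0.3, beta = 1), costs)
  expect_equal(stats::sd(same$cells$markup[same$cells$pc == "PC2"]), 0)
  vary <- baseline_markups(mk, default_current_regime(), costs)
  expect_gt(stats::sd(vary$cells$markup[vary$cells$pc == "PC2"]), 0)
})

test_that("scenario I price is the binding state's feasibility floor", {
  # CBS-only regime has no state variation: floor is the worked 1.42
  p <- scenario_price("I", costs = cost_table(c(PC2 = 1e-9, PC3 = 2e-9,
                                                PC4 = 3e-9)),
                      regime_reform = cbs_only_regime())
  expect_equal(p[["PC2"]], 1.42)
  # raising one state's ICMS can only raise the national price
  base <- default_reform_regime()
  ov <- base$state_overrides
  ov[["RJ"]] <- c(icms = 0.35)
  higher <- tax_regime(base$components, state_overrides = ov)
  p0 <- scenario_price("I", costs = default_cost_table(),
                       regime_reform = base)
  p1 <- scenario_price("I", costs = default_cost_table(),
                       regime_reform = higher)
  expect_true(all(p1 >= p0))
})

test_that("default-fixture scenario prices are ordered and collapse PC2/PC3", {
  cal <- shared_calibrated()
  markups <- baseline_markups(cal$market, default_current_regime(),
                              default_cost_table())
  reform <- default_reform_regime()
  pI <- scenario_price("I", markups, default_cost_table(), reform)
  pII <- scenario_price("II", markups, default_cost_table(), reform)
  pIII <- scenario_price("III", markups, default_cost_table(), reform)
  expect_true(all(pI <= pII & pII <= pIII))
  # low- and medium-price categories collapse to (essentially) one price
  expect_lt(abs(pI[["PC2"]] - pI[["PC3"]]), 0.05)
  # implicit floor far above the official 5.00 BRL minimum
  expect_gt(pI[["PC2"]], 5.00)
})

test_that("demand response is the identity at unchanged prices", {
  cal <- shared_calibrated()
  old_prices <- vapply(c("PC2", "PC3", "PC4"), function(k) {
    max(cal$market$mean_price[cal$market$pc == k])
  }, numeric(1))
  # uniform price equal to each cell's own price: zero change everywhere
  one_state <- cal$market[cal$market$state == "SP", ]
  mk <- market_state(one_state[c("state", "pc", "smokers", "mean_price",
                                 "mean_cpd")],
                     populations = attr(cal$market, "populations")["SP"])
  same <- demand_response(mk, default_elasticity_table(),
                          stats::setNames(mk$mean_price[match(
                            c("PC2", "PC3", "PC4"), mk$pc)],
                            c("PC2", "PC3", "PC4")))
  expect_equal(same$smokers, mk$smokers, tolerance = 1e-12)
  expect_equal(same$mean_cpd, mk$mean_cpd, tolerance = 1e-12)
})

test_that("demand response applies the total elasticity linearly", {
  cells <- data.frame(state = "RS", pc = c("PC1", "PC2", "PC3", "PC4"),
                      smokers = c(0, 0, 0, 1000),
                      mean_price = c(4.00, 6.00, 8.00, 10.00),
                      mean_cpd = c(0, 0, 0, 20))
  mk <- hand_market(cells)
  tab <- default_elasticity_table()  # South PC4 total = -0.39
  post <- demand_response(mk, tab, c(PC2 = 6, PC3 = 8, PC4 = 11))
  packs0 <- packs_per_year(mk)[4]
  packs1 <- packs_per_year(post)[4]
  expect_equal(100 * (packs1 / packs0 - 1), -3.9, tolerance = 1e-9)
  # smokers shrink by the prevalence share of the response
  expect_equal(post$smokers[4], 1000 * (1 - 0.21 * 0.10), tolerance = 1e-9)
})

test_that("extreme price jumps clamp consumption at zero with a warning", {
  cells <- data.frame(state = "BA", pc = c("PC1", "PC2", "PC3", "PC4"),
                      smokers = c(0, 1000, 0, 0),
                      mean_price = c(4.00, 5.50, 8.00, 13.00),
                      mean_cpd = c(0, 15, 0, 0))
  mk <- hand_market(cells)
  expect_warning(
    post <- demand_response(mk, default_elasticity_table(),
                            c(PC2 = 30, PC3 = 8, PC4 = 13)),
    "clamped")
  expect_equal(packs_per_year(post)[2], 0)
  expect_gte(post$smokers[2], 0)
})

test_that("scenarios preserve uniformity, conservation and decomposition", {
  cal <- shared_calibrated()
  et <- default_elasticity_table()
  rn <- default_current_regime()
  rr <- default_reform_regime()
  costs <- default_cost_table()
  results <- lapply(c("I", "II", "III"), run_scenario, market = cal$market,
                    elasticities = et, regime_now = rn, regime_reform = rr,
                    costs = costs)
  prev <- NULL
  for (res in results) {
    post <- res$market
    for (k in c("PC2", "PC3", "PC4")) {
      # post-reform price dispersion across states is exactly zero
      expect_equal(stats::sd(post$mean_price[post$pc == k]), 0)
      expect_equal(unique(post$mean_price[post$pc == k]), res$prices[[k]])
    }
    expect_true(all(res$burden < 1))
    expect_true(all(post$smokers >= 0))
    # the illicit segment is held fixed
    expect_equal(post$smokers[post$pc == "PC1"],
                 cal$market$smokers[cal$market$pc == "PC1"])
    expect_equal(packs_per_year(post)[post$pc == "PC1"],
                 packs_per_year(cal$market)[cal$market$pc == "PC1"])
    # revenue decomposition: states and categories tell the same total
    expect_equal(sum(res$revenue_by_state), res$revenue_total,
                 tolerance = 1e-9)
    expect_equal(sum(res$revenue_by_pc), res$revenue_total,
                 tolerance = 1e-9)
    expect_equal(sum(res$revenue_share_pc), 100, tolerance = 1e-9)
    if (!is.null(prev)) {
      # consumption decline deepens from I to II to III
      expect_true(all(res$consumption_change_pc <=
                        prev$consumption_change_pc + 1e-9))
    }
    prev <- res
  }
})
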