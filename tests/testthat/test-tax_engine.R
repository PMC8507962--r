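# Per-pack assessment and the pricing inversions.

test_that("CBS is charged on the highest national brand price", {
  cbs <- cbs_only_regime()
  prices <- c(10.00, 12.50, 14.00)
  taxes <- vapply(prices, function(p) {
    assess(p, 14.00, "SP", cbs)$total_tax
  }, numeric(1))
  # same CBS amount in every state, regardless of the local price
  expect_equal(taxes, rep(14.00 * 0.22 + 1.10, 3))
  expect_equal(taxes[1], 4.18, tolerance = 1e-12)
  # pricing below the national maximum only raises the burden
  low <- assess(10.00, 14.00, "SP", cbs)
  high <- assess(14.00, 14.00, "SP", cbs)
  expect_equal(low$total_tax, high$total_tax)
  expect_equal(low$burden, 0.418, tolerance = 1e-12)
  expect_equal(high$burden, 4.18 / 14, tolerance = 1e-12)
  expect_gt(low$burden, high$burden)
})

test_that("assessment is additive over components and over regimes", {
  r <- default_current_regime()
  a <- assess(7.50, 8.00, "BA", r)
  expect_equal(sum(a$components), a$total_tax)
  # splitting a regime into parts preserves the total
  parts <- lapply(r$components, function(cm) {
    ov <- r$state_overrides["BA"]
    ov[["BA"]] <- ov[["BA"]][intersect(names(ov[["BA"]]), cm$name)]
    if (!length(ov[["BA"]])) ov <- list()
    tax_regime(list(cm), state_overrides = ov)
  })
  expect_equal(sum(vapply(parts, function(p) {
    assess(7.50, 8.00, "BA", p)$total_tax
  }, numeric(1))), a$total_tax)
  # empty regime: zero tax, zero burden
  none <- assess(7.50, 8.00, "BA", tax_regime())
  expect_identical(none$total_tax, 0)
  expect_identical(none$burden, 0)
})

test_that("burden strictly decreases in the local price under a fixed maximum", {
  cbs <- cbs_only_regime()
  burdens <- vapply(seq(6, 14, by = 0.5), function(p) {
    assess(p, 14, "MG", cbs)$burden
  }, numeric(1))
  expect_true(all(diff(burdens) < 0))
})

test_that("the national-maximum definition is enforced", {
  expect_error(assess(10, 9.99, "SP", cbs_only_regime()),
               "national maximum")
  expect_error(assess(0, 1, "SP", cbs_only_regime()), "price_local")
})

test_that("floor price matches its closed form and the worked example", {
  cbs <- cbs_only_regime()
  # 1.10 / (1 - 0.22) = 1.4103 -> 1.42 after rounding up to the cent
  expect_equal(floor_price(0, "SP", cbs), 1.42)
  # empty regime and zero cost: the floor is the cost
  expect_equal(floor_price(0, "SP", tax_regime()), 0)
  # an exact-cent closed form with zero cost has 100% burden: next cent
  r <- flat_regime(alpha = 0.22, beta = 0.78)  # p* = 0.78 / 0.78 = 1.00
  expect_equal(floor_price(0, "SP", r), 1.01)
})

test_that("floor price equals the 0.01-BRL grid-search oracle", {
  set.seed(401)
  for (i in 1:200) {
    alpha <- runif(1, 0, 0.9)
    beta <- runif(1, 0.01, 5)
    cost <- runif(1, 0, 3)
    got <- floor_price(cost, "SP", flat_regime(alpha, beta))
    want <- floor_price_grid(cost, alpha, beta)
    expect_equal(got, want, tolerance = 1e-9,
                 label = sprintf("floor(a=%.3f, b=%.3f, c=%.3f)",
                                 alpha, beta, cost))
  }
})

test_that("floor price is feasible and one cent lower is not", {
  set.seed(402)
  for (i in 1:100) {
    alpha <- runif(1, 0, 0.9)
    beta <- runif(1, 0.01, 5)
    cost <- runif(1, 0, 3)
    r <- flat_regime(alpha, beta)
    p <- floor_price(cost, "SP", r)
    a <- assess(p, p, "SP", r)
    expect_lt(a$burden, 1)
    expect_gte(p - a$total_tax - cost, -1e-9)
    # one cent below: negative margin or a burden at or above 100%
    p2 <- p - 0.01
    a2 <- assess(p2, p2, "SP", r)
    expect_true(p2 - a2$total_tax - cost < -1e-9 || a2$burden >= 1 - 1e-12)
  }
})

test_that("markup inversion is consistent with the floor and round-trips", {
  r <- flat_regime(alpha = 0.5)
  # markup 1.0, cost 1.00: p = (2 + 0) / 0.5 = 4.00; net of tax 2.00
  p <- price_from_markup(1, 1, "SP", r)
  expect_equal(p, 4.00)
  expect_equal(p - assess(p, p, "SP", r)$total_tax, 2.00)
  # markup 0 reproduces the unrounded floor
  set.seed(403)
  for (i in 1:50) {
    alpha <- runif(1, 0, 0.9)
    beta <- runif(1, 0.01, 4)
    cost <- runif(1, 0.1, 3)
    rr <- flat_regime(alpha, beta)
    expect_equal(price_from_markup(0, cost, "SP", rr, round = FALSE),
                 (beta + cost) / (1 - alpha), tolerance = 1e-12)
    # round trip markup -> price -> markup
    m <- runif(1, 0, 3)
    expect_equal(markup_of(price_from_markup(m, cost, "SP", rr,
                                             round = FALSE),
                           cost, "SP", rr),
                 m, tolerance = 1e-9)
    # positive markup keeps the burden strictly below 1
    pm <- price_from_markup(m, cost, "SP", rr)
    expect_lt(assess(pm, pm, "SP", rr)$burden, 1)
  }
  expect_error(markup_of(4, 0, "SP", r), "undefined")
})

test_that("state overrides change effective rates and infeasible regimes fail", {
  r <- default_current_regime()
  expect_equal(effective_rates(r, "RJ")$alpha_local,
               0.1115 + 0.1425 + 0.280, tolerance = 1e-12)
  expect_equal(effective_rates(r, "SP")$alpha_local,
               0.1115 + 0.1425 + 0.245, tolerance = 1e-12)
  expect_equal(effective_rates(r, "SP")$beta, 1.50)
  expect_error(
    tax_regime(list(tax_component("a", "ad_valorem", rate = 0.6),
                    tax_component("b", "ad_valorem", rate = 0.5))),
    "infeasible")
  expect_error(tax_component("x", "ad_valorem", rate = 1.2), "rate")
})

test_that("regimes survive a YAML round trip", {
  for (r in list(default_current_regime(), default_reform_regime())) {
    path <- withr::local_tempfile(fileext = ".yaml")
    write_tax_regime(r, path)
    r2 <- read_tax_regime(path)
    for (s in c("SP", "RJ", "MS", "AM")) {
      expect_equal(effective_rates(r2, s), effective_rates(r, s))
    }
  }
  # shipped fixtures load to the default regimes
  fx <- system.file("extdata", "regime-reform.yaml", package = "cigsim")
  expect_equal(effective_rates(read_tax_regime(fx), "RJ"),
               effective_rates(default_reform_regime(), "RJ"))
})
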