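# Synthetic smoker-survey generator.

test_that("identical seed and configuration give identical output", {
  cfg <- tiny_cfg(seed = 99, n = 5000)
  a <- generate_survey(cfg)
  b <- generate_survey(cfg)
  expect_identical(a, b)
  # a different seed changes the draw
  c <- generate_survey(cfg, seed = 100)
  expect_false(identical(a, c))
  # generation does not disturb the caller's RNG stream
  set.seed(1); x <- runif(1)
  set.seed(1); invisible(generate_survey(tiny_cfg(n = 500))); y <- runif(1)
  expect_identical(x, y)
})

test_that("zero smoker share yields an all-non-smoking survey", {
  svy <- generate_survey(generator_config(seed = 3, n_respondents = 2000,
                                          smoker_share = 0))
  expect_false(any(svy$smokes))
  expect_true(all(is.na(svy$price_paid)))
  expect_true(all(is.na(svy$cigarettes_per_day)))
})

test_that("price draws respect the official floor partition", {
  svy <- shared_survey()
  floor <- attr(svy, "price_floor")
  sm <- svy[svy$smokes, ]
  expect_true(all(sm$price_paid[sm$price_category == 1] < floor))
  expect_true(all(sm$price_paid[sm$price_category > 1] >= floor))
  # consumption and price exist exactly for smokers
  expect_false(anyNA(sm$cigarettes_per_day))
  expect_true(all(is.na(svy$price_paid[!svy$smokes])))
  expect_true(all(sm$cigarettes_per_day >= 1 & sm$cigarettes_per_day <= 60))
})

test_that("region is the fixed deterministic function of the state code", {
  svy <- shared_survey()
  expect_identical(svy$region, state_region(svy$state))
  expect_identical(as.character(state_region(c("SP", "BA", "MS", "AM"))),
                   c("Southeast", "Northeast", "Midwest", "North"))
  expect_error(state_region("XX"), "unknown state")
})

test_that("default configuration stays inside the documented bands", {
  cfg <- generator_config()
  expect_true(all(cfg$smoker_share >= 0.04 & cfg$smoker_share <= 0.13))
  expect_equal(unname(rowSums(cfg$pc_shares)), rep(1, 27), tolerance = 1e-12)
  expect_true(all(cfg$true_prevalence_elasticity <= 0))
  expect_true(all(cfg$true_conditional_elasticity <= 0))
  expect_true(all(cfg$pc_price_means[, "PC1"] < cfg$price_floor))
  expect_true(all(cfg$pc_price_means[, -1] >= cfg$price_floor))
  # realized prevalence tracks the configured share level
  svy <- shared_survey()
  expect_equal(mean(svy$smokes),
               weighted.mean(cfg$smoker_share, cfg$state_populations),
               tolerance = 0.15)
})

test_that("degenerate configurations are rejected", {
  flat_prices <- matrix(rep(c(3.80, 5.38, 7.90, 12.84), each = 27), 27, 4,
                        dimnames = list(brazil_states()$state, NULL))
  cfg <- generator_config(pc_price_means = flat_prices)
  expect_error(generate_survey(cfg), "unidentifiable")

  bad_shares <- matrix(0.3, 27, 4, dimnames = list(brazil_states()$state,
                                                   NULL))
  expect_error(generator_config(pc_shares = bad_shares), "sum to 1")
  expect_error(generator_config(true_prevalence_elasticity = 0.2), "<= 0")
  expect_error(generator_config(price_noise_sd = -1), "price_noise_sd")
})

test_that("zero generating elasticities leave no price signal", {
  cfg <- generator_config(seed = 17, n_respondents = 30000,
                          true_prevalence_elasticity = 0,
                          true_conditional_elasticity = 0)
  svy <- generate_survey(cfg)
  sm <- svy[svy$smokes, ]
  # pooled conditional slope: log consumption on log state-category price
  key <- paste(sm$state, sm$price_category)
  lp <- log(tapply(sm$price_paid, key, mean))[key]
  fit <- summary(stats::lm(log(sm$cigarettes_per_day) ~ lp))
  expect_lt(abs(fit$coefficients["lp", "t value"]), 3)
  # prevalence: state smoking rate uncorrelated with state price
  rate <- tapply(svy$smokes, svy$state, mean)
  price <- tapply(sm$price_paid, sm$state, mean)[names(rate)]
  ct <- stats::cor.test(rate, log(price))
  expect_gt(ct$p.value, 0.01)
})

test_that("surveys survive a CSV round trip", {
  svy <- generate_survey(tiny_cfg(seed = 5, n = 1000))
  path <- tempfile(fileext = ".csv")
  write_survey(svy, path)
  back <- read_survey(path)
  expect_equal(attr(back, "price_floor"), attr(svy, "price_floor"))
  expect_equal(back$price_paid, svy$price_paid)
  expect_identical(back$state, svy$state)
  expect_identical(back$smokes, svy$smokes)
  unlink(path)
})
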