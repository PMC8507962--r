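# Two-part elasticity estimation.

test_that("total is prevalence plus conditional, cell by cell", {
  prev <- c(North = -0.24, Northeast = -0.26, Southeast = -0.24,
            South = -0.21, Midwest = -0.23)
  cond <- matrix(-0.60, 5, 4,
                 dimnames = list(names(prev), c("PC1", "PC2", "PC3", "PC4")))
  tab <- combine_elasticities(prev, cond)
  expect_equal(tab$total["Northeast", "PC1"], -0.86, tolerance = 1e-12)
  expect_equal(tab$total, sweep(tab$conditional, 1, tab$prevalence, `+`),
               tolerance = 1e-12)
  # subtracting prevalence returns the conditional table
  expect_equal(sweep(tab$total, 1, tab$prevalence, `-`), tab$conditional,
               tolerance = 1e-12)
  # zeros map to zeros
  z <- combine_elasticities(prev * 0, cond * 0)
  expect_true(all(z$total == 0))
})

test_that("the identity holds for estimated tables by construction", {
  fit <- estimate_elasticities(shared_survey())
  tab <- fit$table
  expect_equal(tab$total, sweep(tab$conditional, 1, tab$prevalence, `+`),
               tolerance = 1e-9)
  expect_identical(dim(coef(fit)), c(5L, 4L))
  expect_false(anyNA(tab$conditional))
  expect_false(anyNA(tab$prevalence_se))
})

test_that("zero generating effects give estimates compatible with zero", {
  cfg <- generator_config(seed = 23, n_respondents = 30000,
                          true_prevalence_elasticity = 0,
                          true_conditional_elasticity = 0)
  svy <- generate_survey(cfg)
  pr <- estimate_prevalence(svy)
  cd <- estimate_conditional(svy)
  expect_true(all(abs(pr$prevalence / pr$se) < 4))
  expect_true(all(abs(cd$conditional / cd$se) < 4))
})

test_that("estimates are invariant to record order", {
  svy <- generate_survey(tiny_cfg(seed = 31, n = 10000))
  perm <- svy[rev(seq_len(nrow(svy))), ]
  a <- estimate_elasticities(svy)
  b <- estimate_elasticities(perm)
  expect_equal(a$table$prevalence, b$table$prevalence, tolerance = 1e-8)
  expect_equal(a$table$conditional, b$table$conditional, tolerance = 1e-8)
})

test_that("constant survey weights do not change the estimates", {
  svy <- generate_survey(tiny_cfg(seed = 32, n = 10000))
  reweighted <- svy
  reweighted$survey_weight <- 2
  a <- estimate_elasticities(svy)
  b <- estimate_elasticities(reweighted)
  # probit IRLS stops on a deviance-scaled criterion, so a constant weight
  # moves the estimates only within convergence noise
  expect_equal(a$table$prevalence, b$table$prevalence, tolerance = 1e-3)
  expect_equal(a$table$conditional, b$table$conditional, tolerance = 1e-8)
})

test_that("conditional bias shrinks as the sample grows", {
  # homogeneous generating value -0.6; mean absolute error across cells and
  # two seeds must fall from n = 5k to n = 50k
  err <- function(n, seeds) {
    mean(vapply(seeds, function(s) {
      cfg <- generator_config(seed = s, n_respondents = n,
                              smoker_share = 0.09,
                              true_conditional_elasticity = -0.60)
      # small n leaves near-singleton cells; their HC1 warning is expected
      cd <- suppressWarnings(estimate_conditional(generate_survey(cfg)))
      mean(abs(cd$conditional + 0.60))
    }, numeric(1)))
  }
  expect_lt(err(50000, 61:62), err(5000, 61:62))
})

test_that("degenerate inputs are rejected with informative errors", {
  svy <- shared_survey()
  # a region with no non-smokers
  drop_ns <- svy[!(svy$region == "North" & !svy$smokes), ]
  expect_error(estimate_prevalence(drop_ns), "North")
  # smokers from a single state: one price point per cell
  one_state <- svy[svy$state == "SP" | (!svy$smokes & svy$state == "RJ"), ]
  expect_error(estimate_conditional(one_state),
               "fewer than 2 distinct state-average prices")
})

test_that("elasticity tables survive a CSV round trip", {
  fit <- estimate_elasticities(shared_survey())
  path <- tempfile(fileext = ".csv")
  write_elasticities(fit$table, path)
  back <- read_elasticities(path)
  expect_equal(back$prevalence, fit$table$prevalence)
  expect_equal(back$conditional, fit$table$conditional)
  expect_equal(back$total, fit$table$total)
  unlink(path)
})
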