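# Seeded generation of smoker-level survey records with known price
# elasticities, emulating the structure of the Brazilian risk-factor phone
# survey: smoking status, daily consumption, last-purchase price, and
# socio-economic covariates, with price variation placed at the state level.

#' Generate a synthetic smoker survey
#'
#' Draws `config$n_respondents` records. Smoking status comes from a
#' latent-index probit whose log-price coefficient reproduces the
#' configured prevalence elasticity at the configuration's mean prevalence;
#' among smokers, log daily cigarette consumption is linear in the log
#' state-level price of the smoker's price category with the configured
#' conditional elasticity as slope, plus covariate effects and Gaussian
#' noise. Prices are drawn around state-by-category means and respect the
#' official floor partition: illicit (PC1) purchases are strictly below the
#' floor, legal purchases at or above it.
#'
#' Identical `seed` and configuration give byte-identical output. A
#' configuration without cross-state price variation is rejected because
#' the price elasticities would be unidentifiable from the generated data.
#'
#' @param config A [generator_config()].
#' @param seed Optional override of `config$seed`.
#' @return A `data.frame` of class `"smoker_survey"`, one row per
#'   respondent, with columns `state`, `region`, `year`, `smokes`,
#'   `cigarettes_per_day`, `price_paid`, `price_category` (1-4, `NA` for
#'   non-smokers), `age`, `female`, `income`, `education`,
#'   `years_smoking`, `survey_weight`. The official price floor is attached
#'   as attribute `"price_floor"`.
#' @examples
#' svy <- generate_survey(generator_config(seed = 7, n_respondents = 2000))
#' table(svy$smokes)
#' @export
generate_survey <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  validate_generator_config(config)
  st <- brazil_states()
  states <- st$state
  regions <- region_levels()

  p_state <- config_state_price(config)
  if (all(apply(config$pc_price_means, 2, stats::sd) < 1e-9)) {
    stop(paste("configuration has zero cross-state price variance:",
               "price elasticities are unidentifiable"))
  }

  pop <- config$state_populations
  lp_state <- log(p_state)
  lp_bar <- weighted_mean(lp_state, pop)
  p_bar_prev <- weighted_mean(config$smoker_share, pop)  # mean prevalence

  # probit log-price coefficient per region reproducing the generating
  # prevalence elasticity at the configuration's mean prevalence:
  # elasticity = gamma * dnorm(qnorm(P)) / P  =>  gamma = e * P / dnorm(...)
  gamma_r <- if (p_bar_prev > 0) {
    config$true_prevalence_elasticity * p_bar_prev /
      stats::dnorm(stats::qnorm(p_bar_prev))
  } else {
    stats::setNames(rep(0, 5), regions)
  }

  cv <- config$covariates
  n <- config$n_respondents

  with_seed(seed, {
    si <- sample.int(27L, n, replace = TRUE, prob = pop / sum(pop))
    state <- states[si]
    region <- st$region[si]

    age <- pmin(90, pmax(18, round(stats::rnorm(n, cv$age_mean, cv$age_sd))))
    female <- stats::runif(n) < cv$female_p
    income <- round(stats::rlnorm(n, cv$income_meanlog, cv$income_sdlog), 2)
    education <- sample.int(5L, n, replace = TRUE, prob = cv$educ_probs)
    year <- ifelse(stats::runif(n) < 0.5, 2018L, 2019L)

    age_std <- (age - cv$age_mean) / cv$age_sd
    inc_std <- (log(income) - cv$income_meanlog) / cv$income_sdlog
    educ_std <- (education - 3) / 1.2

    # latent smoking index: state level set by the configured share at the
    # national-average price, cross-state price term, mild covariate effects
    z <- stats::qnorm(config$smoker_share[si]) +
      gamma_r[as.character(region)] * (lp_state[si] - lp_bar) +
      0.05 * age_std - 0.08 * female - 0.06 * inc_std - 0.05 * educ_std
    smokes <- stats::runif(n) < stats::pnorm(z)

    price_category <- rep(NA_integer_, n)
    price_paid <- rep(NA_real_, n)
    cigarettes_per_day <- rep(NA_integer_, n)
    years_smoking <- integer(n)

    ns <- sum(smokes)
    if (ns > 0) {
      sm_state_i <- si[smokes]
      # price category: multinomial per state
      cum <- t(apply(config$pc_shares, 1, cumsum))
      u <- stats::runif(ns)
      pc <- 1L + (u > cum[sm_state_i, 1]) + (u > cum[sm_state_i, 2]) +
        (u > cum[sm_state_i, 3])
      mu_price <- config$pc_price_means[cbind(sm_state_i, pc)]
      pr <- stats::rnorm(ns, mu_price, config$price_noise_sd)
      floor <- config$price_floor
      pr <- ifelse(pc == 1L,
                   pmin(pmax(pr, 1.00), floor - 0.01),
                   pmax(pr, floor))
      pr <- round(pr, 2)

      # years smoked: increases with age, at least 1, at most age - 16
      ys <- round(0.5 * (age[smokes] - 16) + stats::rnorm(ns, 0, 4))
      ys <- pmax(1L, pmin(age[smokes] - 16L, as.integer(ys)))

      # realized state-by-category mean prices: the generating price level
      # for consumption intensity, matching the regressor the estimator
      # uses (the state-average price substitutes the individual price)
      cell <- interaction(states[sm_state_i], pc, drop = FALSE,
                          lex.order = TRUE)
      cell_mean <- tapply(pr, cell, mean)
      lp_cell <- log(cell_mean[as.character(cell)])
      # centre log price within each category across states
      pc_lp_bar <- tapply(lp_cell, pc, mean)
      lp_centered <- lp_cell - pc_lp_bar[as.character(pc)]

      eps_cond <- config$true_conditional_elasticity[
        cbind(as.character(st$region[sm_state_i]), pc_levels()[pc])]
      ys_std <- (ys - 15) / 10
      log_cpd <- cv$cpd_log_median + eps_cond * lp_centered +
        0.06 * age_std[smokes] - 0.05 * female[smokes] +
        0.05 * inc_std[smokes] + 0.03 * ys_std +
        stats::rnorm(ns, 0, cv$cpd_log_sd)
      cpd <- as.integer(pmin(60, pmax(1, round(exp(log_cpd)))))

      price_category[smokes] <- pc
      price_paid[smokes] <- pr
      cigarettes_per_day[smokes] <- cpd
      years_smoking[smokes] <- ys
    }
    # a quarter of non-smokers are former smokers with positive years
    if (ns < n) {
      former <- !smokes & stats::runif(n) < 0.25
      years_smoking[former] <- sample.int(15L, sum(former), replace = TRUE)
    }

    out <- data.frame(
      state = state,
      region = region,
      year = year,
      smokes = smokes,
      cigarettes_per_day = cigarettes_per_day,
      price_paid = price_paid,
      price_category = price_category,
      age = age,
      female = female,
      income = income,
      education = education,
      years_smoking = years_smoking,
      survey_weight = 1,
      stringsAsFactors = FALSE
    )
    attr(out, "price_floor") <- config$price_floor
    class(out) <- c("smoker_survey", "data.frame")
    out
  })
}

#' Read or write a synthetic survey as CSV
#'
#' One row per respondent with the documented [generate_survey()] columns.
#' The price floor is stored in a `# price_floor:` header comment.
#'
#' @param survey A `"smoker_survey"` data frame.
#' @param path File path.
#' @return `read_survey()` returns a `"smoker_survey"` data frame;
#'   `write_survey()` returns `path` invisibly.
#' @export
write_survey <- function(survey, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# price_floor: %.2f",
                     attr(survey, "price_floor") %||% 5.00), con)
  utils::write.csv(as.data.frame(survey), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survey
#' @export
read_survey <- function(path) {
  first <- readLines(path, n = 1L)
  floor <- 5.00
  skip <- 0L
  if (startsWith(first, "# price_floor:")) {
    floor <- as.numeric(sub("# price_floor:", "", first))
    skip <- 1L
  }
  out <- utils::read.csv(path, skip = skip, stringsAsFactors = FALSE)
  out$region <- factor(out$region, levels = region_levels())
  attr(out, "price_floor") <- floor
  class(out) <- c("smoker_survey", "data.frame")
  out
}
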