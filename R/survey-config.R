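# Configuration of the synthetic smoker-survey generator. Defaults encode
# the market structure the simulation assumes for Brazil: 27 states in five
# regions, smoker shares between 4 and 13 percent of the population, a
# four-way price-category split with an illicit segment (PC1) priced below
# the official 5.00 BRL floor, the legal market split in three equal
# segments, and cigarette prices that vary across states (the estimators
# identify price effects from exactly this cross-state variation).

#' Configuration for the synthetic survey generator
#'
#' Builds a validated generator configuration. All arguments have defaults;
#' override any subset. State-indexed arguments are vectors named by the 27
#' state codes; region-indexed arguments are named by the five macro-regions
#' (see [brazil_states()]); `(state, PC)` and `(region, PC)` arguments are
#' matrices with `PC1`..`PC4` columns.
#'
#' @param seed Integer seed; every draw in [generate_survey()] derives from
#'   it.
#' @param n_respondents Number of survey records to generate.
#' @param state_populations Named vector, inhabitants per state.
#' @param smoker_share Named vector, fraction of smokers per state *at the
#'   national-average price level*. Realized state prevalence additionally
#'   reflects the state's price level through the generating prevalence
#'   elasticity. Defaults are region-level values in `[0.04, 0.13]`.
#' @param pc_shares State-by-PC matrix of market shares among smokers; rows
#'   must sum to 1. Default: an illicit share decreasing in the state price
#'   level, legal market split in three equal parts.
#' @param pc_price_means State-by-PC matrix of mean prices (BRL per
#'   20-cigarette pack). PC1 means must lie below `price_floor`, legal means
#'   at or above it.
#' @param price_noise_sd Within-state price dispersion, BRL.
#' @param price_floor Official minimum legal price, BRL/pack.
#' @param true_prevalence_elasticity Named vector per region, `<= 0`.
#' @param true_conditional_elasticity Region-by-PC matrix, `<= 0`.
#' @param covariates List of covariate distribution parameters (see
#'   Details).
#'
#' @details Default generating elasticities follow the usual pattern for
#' Brazil: poorer regions and cheaper price categories are more price
#' sensitive, prevalence elasticities near -0.2 and conditional
#' elasticities between about -0.2 and -0.6. Covariate parameters:
#' `age_mean`, `age_sd`, `female_p`, `income_meanlog`, `income_sdlog`,
#' `educ_probs` (5 ordinal levels), `cpd_log_median` (median cigarettes/day
#' among smokers, default 12) and `cpd_log_sd`.
#'
#' @return An object of class `"generator_config"` (a validated list).
#' @examples
#' cfg <- generator_config(seed = 1, n_respondents = 1000)
#' cfg$smoker_share[c("SP", "BA")]
#' @export
generator_config <- function(seed = 1L,
                             n_respondents = 50000L,
                             state_populations = NULL,
                             smoker_share = NULL,
                             pc_shares = NULL,
                             pc_price_means = NULL,
                             price_noise_sd = 0.15,
                             price_floor = 5.00,
                             true_prevalence_elasticity = NULL,
                             true_conditional_elasticity = NULL,
                             covariates = list()) {
  st <- brazil_states()
  states <- st$state
  regions <- region_levels()
  f <- st$price_index

  if (is.null(state_populations)) {
    state_populations <- stats::setNames(st$population, states)
  }
  if (is.null(smoker_share)) {
    region_share <- c(North = 0.065, Northeast = 0.080, Southeast = 0.090,
                      South = 0.115, Midwest = 0.085)
    smoker_share <- stats::setNames(region_share[as.character(st$region)],
                                    states)
  }
  if (length(smoker_share) == 1L) {
    smoker_share <- stats::setNames(rep(smoker_share, 27), states)
  }
  if (is.null(pc_shares)) {
    s1 <- 0.03 + 0.32 * (1 - f)
    pc_shares <- cbind(PC1 = s1, PC2 = (1 - s1) / 3, PC3 = (1 - s1) / 3,
                       PC4 = (1 - s1) / 3)
    rownames(pc_shares) <- states
  }
  if (is.null(pc_price_means)) {
    pc_price_means <- cbind(PC1 = 2.60 + 2.00 * f,
                            PC2 = 5.00 + 0.80 * f,
                            PC3 = 6.20 + 3.00 * f,
                            PC4 = 9.50 + 6.50 * f)
    rownames(pc_price_means) <- states
  }
  if (is.null(true_prevalence_elasticity)) {
    true_prevalence_elasticity <- c(North = -0.24, Northeast = -0.26,
                                    Southeast = -0.24, South = -0.21,
                                    Midwest = -0.23)
  }
  if (length(true_prevalence_elasticity) == 1L) {
    true_prevalence_elasticity <-
      stats::setNames(rep(true_prevalence_elasticity, 5), regions)
  }
  if (is.null(true_conditional_elasticity)) {
    # conditional = total - prevalence, region by price category
    true_conditional_elasticity <- rbind(
      North     = c(-0.49, -0.44, -0.26, -0.24),
      Northeast = c(-0.60, -0.42, -0.36, -0.31),
      Southeast = c(-0.32, -0.44, -0.22, -0.18),
      South     = c(-0.30, -0.45, -0.19, -0.18),
      Midwest   = c(-0.46, -0.44, -0.19, -0.24)
    )
    colnames(true_conditional_elasticity) <- pc_levels()
  }
  if (length(true_conditional_elasticity) == 1L) {
    true_conditional_elasticity <-
      matrix(true_conditional_elasticity, 5, 4,
             dimnames = list(regions, pc_levels()))
  }
  # tolerate unnamed matrices: rows in state order, columns PC1..PC4
  fix_names <- function(m, rows) {
    if (is.null(rownames(m))) rownames(m) <- rows
    if (is.null(colnames(m))) colnames(m) <- pc_levels()
    m
  }
  pc_shares <- fix_names(pc_shares, states)
  pc_price_means <- fix_names(pc_price_means, states)
  true_conditional_elasticity <- fix_names(true_conditional_elasticity,
                                           regions)
  if (is.null(names(true_prevalence_elasticity))) {
    names(true_prevalence_elasticity) <- regions
  }
  if (is.null(names(smoker_share))) names(smoker_share) <- states
  if (is.null(names(state_populations))) names(state_populations) <- states

  cov_defaults <- list(age_mean = 42, age_sd = 13, female_p = 0.52,
                       income_meanlog = log(2000), income_sdlog = 0.7,
                       educ_probs = c(0.15, 0.30, 0.30, 0.15, 0.10),
                       cpd_log_median = log(12), cpd_log_sd = 0.40)
  covariates <- utils::modifyList(cov_defaults, covariates)

  cfg <- structure(list(
    seed = as.integer(seed),
    n_respondents = as.integer(n_respondents),
    state_populations = state_populations[states],
    smoker_share = smoker_share[states],
    pc_shares = pc_shares[states, pc_levels(), drop = FALSE],
    pc_price_means = pc_price_means[states, pc_levels(), drop = FALSE],
    price_noise_sd = price_noise_sd,
    price_floor = price_floor,
    true_prevalence_elasticity = true_prevalence_elasticity[regions],
    true_conditional_elasticity =
      true_conditional_elasticity[regions, pc_levels(), drop = FALSE],
    covariates = covariates
  ), class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  states <- brazil_states()$state
  if (anyNA(cfg$state_populations) || any(cfg$state_populations <= 0)) {
    stop("state_populations must be positive for all 27 states")
  }
  if (anyNA(cfg$smoker_share) ||
      any(cfg$smoker_share < 0 | cfg$smoker_share > 1)) {
    stop("smoker_share must be in [0, 1] for all 27 states")
  }
  rs <- rowSums(cfg$pc_shares)
  if (anyNA(rs) || any(abs(rs - 1) > 1e-9)) {
    stop("pc_shares rows must sum to 1 (within 1e-9)")
  }
  if (any(cfg$pc_shares < 0)) stop("pc_shares must be non-negative")
  if (any(cfg$pc_price_means <= 0)) stop("pc_price_means must be positive")
  if (any(cfg$pc_price_means[, "PC1"] >= cfg$price_floor)) {
    stop("PC1 mean prices must lie below the official price floor")
  }
  legal <- cfg$pc_price_means[, legal_pcs()]
  if (any(legal < cfg$price_floor)) {
    stop("legal-category mean prices must be at or above the price floor")
  }
  if (any(cfg$true_prevalence_elasticity > 0) ||
      any(cfg$true_conditional_elasticity > 0)) {
    stop("generating elasticities must be <= 0")
  }
  if (cfg$price_noise_sd < 0) stop("price_noise_sd must be >= 0")
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  seed %d, %d respondents, price floor %.2f BRL\n",
              x$seed, x$n_respondents, x$price_floor))
  cat(sprintf("  smoker share: %.1f-%.1f%% across states\n",
              100 * min(x$smoker_share), 100 * max(x$smoker_share)))
  cat(sprintf("  mean illicit (PC1) share: %.1f%%\n",
              100 * mean(x$pc_shares[, "PC1"])))
  cat(sprintf("  prevalence elasticities: %s\n",
              paste(sprintf("%s %.2f", names(x$true_prevalence_elasticity),
                            x$true_prevalence_elasticity), collapse = ", ")))
  invisible(x)
}

# Share-weighted average pack price per state implied by a configuration.
config_state_price <- function(cfg) {
  stats::setNames(rowSums(cfg$pc_shares * cfg$pc_price_means),
                  rownames(cfg$pc_shares))
}
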