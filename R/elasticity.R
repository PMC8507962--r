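# Two-part price-elasticity estimation from smoker microdata:
# an extensive margin (probit of smoking status, the prevalence
# elasticity) and an intensive margin (log consumption regression among
# smokers, the conditional elasticity), both using state-average prices in
# place of the individually reported price so that brand switching does not
# bias the estimates. Total elasticity = prevalence + conditional.

#' Elasticity table
#'
#' Container for prevalence elasticities per region and conditional
#' elasticities per region and price category. The total elasticity is
#' their elementwise sum and is recomputed on construction, so the
#' additive identity `total = prevalence + conditional` holds for every
#' cell by construction.
#'
#' @param prevalence Named vector, one elasticity per region.
#' @param conditional Region-by-PC matrix of conditional elasticities.
#' @param prevalence_se,conditional_se Optional standard errors, same
#'   shapes.
#' @return An object of class `"elasticity_table"` with elements
#'   `prevalence`, `conditional`, `total`, `prevalence_se`,
#'   `conditional_se`.
#' @examples
#' tab <- default_elasticity_table()
#' tab$total["Northeast", "PC1"]  # prevalence + conditional
#' @export
elasticity_table <- function(prevalence, conditional,
                             prevalence_se = NULL, conditional_se = NULL) {
  regions <- region_levels()
  if (!all(regions %in% names(prevalence))) {
    stop("prevalence needs one entry per region")
  }
  prevalence <- prevalence[regions]
  if (!all(regions %in% rownames(conditional)) ||
      !all(pc_levels() %in% colnames(conditional))) {
    stop("conditional needs region rows and PC1..PC4 columns")
  }
  conditional <- conditional[regions, pc_levels(), drop = FALSE]
  total <- sweep(conditional, 1, prevalence, `+`)
  structure(list(prevalence = prevalence, conditional = conditional,
                 total = total,
                 prevalence_se = prevalence_se,
                 conditional_se = conditional_se),
            class = "elasticity_table")
}

#' Combine prevalence and conditional elasticities
#'
#' The total price elasticity used in the simulations is the sum of the
#' extensive-margin (prevalence) and intensive-margin (conditional)
#' elasticities, elementwise per region and price category.
#'
#' @param prevalence Named vector per region, or the result of
#'   [estimate_prevalence()].
#' @param conditional Region-by-PC matrix, or the result of
#'   [estimate_conditional()].
#' @return An [elasticity_table()].
#' @export
combine_elasticities <- function(prevalence, conditional) {
  pse <- cse <- NULL
  if (is.list(prevalence) && !is.null(prevalence$prevalence)) {
    pse <- prevalence$se
    prevalence <- prevalence$prevalence
  }
  if (is.list(conditional) && !is.null(conditional$conditional)) {
    cse <- conditional$se
    conditional <- conditional$conditional
  }
  elasticity_table(prevalence, conditional,
                   prevalence_se = pse, conditional_se = cse)
}

#' Default elasticity table
#'
#' The generating elasticities of the default synthetic-survey
#' configuration, as an [elasticity_table()]: prevalence elasticities
#' around -0.2 per region and totals between about -0.9 (cheap categories,
#' poorer regions) and -0.4 (premium brands in the South). Used as the
#' fixed elasticity input of the default simulation fixture.
#'
#' @return An [elasticity_table()].
#' @export
default_elasticity_table <- function() {
  cfg <- generator_config()
  elasticity_table(cfg$true_prevalence_elasticity,
                   cfg$true_conditional_elasticity)
}

#' @export
print.elasticity_table <- function(x, digits = 3, ...) {
  cat("<elasticity_table> total price elasticity (prevalence + conditional)\n")
  tab <- cbind(Prevalence = x$prevalence, x$total)
  print(round(tab, digits))
  invisible(x)
}

#' @export
as.data.frame.elasticity_table <- function(x, ...) {
  regions <- region_levels()
  out <- expand.grid(region = regions, pc = pc_levels(),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$prevalence <- x$prevalence[out$region]
  out$conditional <- x$conditional[cbind(out$region, out$pc)]
  out$total <- x$total[cbind(out$region, out$pc)]
  if (!is.null(x$prevalence_se)) out$prevalence_se <- x$prevalence_se[out$region]
  if (!is.null(x$conditional_se)) {
    out$conditional_se <- x$conditional_se[cbind(out$region, out$pc)]
  }
  out[order(out$region, out$pc), , drop = FALSE]
}

# Attach the log state-average price among smokers to every record.
state_log_price <- function(records) {
  sm <- records[records$smokes & !is.na(records$price_paid), , drop = FALSE]
  if (!nrow(sm)) stop("no priced smoker records")
  wp <- tapply(sm$survey_weight * sm$price_paid, sm$state, sum)
  ww <- tapply(sm$survey_weight, sm$state, sum)
  log(wp / ww)
}

#' Estimate prevalence elasticities (extensive margin)
#'
#' Fits a probit of smoking status on the log state-average cigarette
#' price, interacted with region, controlling for age, gender, log income
#' and education (plus a survey-year indicator when several years are
#' present). The prevalence elasticity per region is the average marginal
#' effect of log price in that region divided by the region's mean smoking
#' prevalence.
#'
#' @param records A `"smoker_survey"` data frame with smokers and
#'   non-smokers.
#' @return List with `prevalence` (named vector per region), `se`
#'   (delta-method standard errors) and `model` (the fitted [stats::glm()]).
#' @export
estimate_prevalence <- function(records) {
  by_region <- table(records$region,
                     factor(records$smokes, levels = c(FALSE, TRUE)))
  if (any(by_region[, "FALSE"] == 0)) {
    bad <- rownames(by_region)[by_region[, "FALSE"] == 0]
    stopf("no non-smokers in region(s) %s: prevalence not estimable",
          paste(bad, collapse = ", "))
  }
  if (any(by_region[, "TRUE"] == 0)) {
    bad <- rownames(by_region)[by_region[, "TRUE"] == 0]
    stopf("no smokers in region(s) %s: prevalence not estimable",
          paste(bad, collapse = ", "))
  }
  lp_state <- state_log_price(records)
  d <- data.frame(
    smokes = records$smokes,
    region = records$region,
    log_price = as.numeric(lp_state[records$state]),
    age = records$age,
    female = records$female,
    log_income = log(records$income),
    education = records$education,
    w = records$survey_weight
  )
  fml <- smokes ~ region + region:log_price + age + female + log_income +
    education
  if (length(unique(records$year %||% 1)) > 1) {
    d$year <- factor(records$year)
    fml <- stats::update(fml, . ~ . + year)
  }
  fit <- suppressWarnings(
    stats::glm(fml, family = stats::binomial("probit"), data = d, weights = w)
  )
  if (!fit$converged) {
    stop("probit did not converge (possible separation); ",
         "check controls and price variation")
  }
  mu <- stats::fitted(fit)
  if (all(mu > 1 - 1e-8) || all(mu < 1e-8)) {
    stop("probit fitted probabilities degenerate: perfect separation ",
         "between smokers and non-smokers")
  }
  eta <- stats::predict(fit, type = "link")
  cf <- stats::coef(fit)
  se_cf <- sqrt(diag(stats::vcov(fit)))

  regions <- region_levels()
  prevalence <- se <- stats::setNames(numeric(5), regions)
  for (r in regions) {
    nm <- paste0("region", r, ":log_price")
    if (!nm %in% names(cf) || is.na(cf[nm])) {
      stopf("log-price effect for region %s not identified (no price %s)",
            r, "variation within the region")
    }
    idx <- d$region == r
    phi_bar <- weighted_mean(stats::dnorm(eta[idx]), d$w[idx])
    prev_r <- weighted_mean(d$smokes[idx], d$w[idx])
    prevalence[r] <- cf[nm] * phi_bar / prev_r
    se[r] <- se_cf[nm] * phi_bar / prev_r
  }
  list(prevalence = prevalence, se = se, model = fit)
}

#' Estimate conditional elasticities (intensive margin)
#'
#' Among smokers, regresses log daily cigarette consumption on the log
#' state-average price of the smoker's price category, interacted with
#' region and price category, controlling for age, gender, log income,
#' education and years of smoking (plus a survey-year indicator when
#' several years are present). Standard errors are
#' heteroskedasticity-robust (HC1).
#'
#' @param records A `"smoker_survey"` data frame; only smoker rows are
#'   used. Every (region, price category) cell needs at least two distinct
#'   state-average prices.
#' @return List with `conditional` (region-by-PC matrix), `se` (HC1
#'   standard errors) and `model` (the fitted [stats::lm()]).
#' @export
estimate_conditional <- function(records) {
  sm <- records[records$smokes, , drop = FALSE]
  if (!nrow(sm)) stop("no smoker records")
  pc <- factor(pc_levels()[sm$price_category], levels = pc_levels())

  # state-average price per price category (the category's price level in
  # the smoker's state substitutes the individually reported price)
  key <- interaction(sm$state, pc, drop = TRUE, lex.order = TRUE)
  wp <- tapply(sm$survey_weight * sm$price_paid, key, sum)
  ww <- tapply(sm$survey_weight, key, sum)
  lp_cell <- log(wp / ww)

  d <- data.frame(
    log_cpd = log(sm$cigarettes_per_day),
    region = droplevels(sm$region),
    pc = droplevels(pc),
    log_price = as.numeric(lp_cell[as.character(key)]),
    age = sm$age,
    female = sm$female,
    log_income = log(sm$income),
    education = sm$education,
    years_smoking = sm$years_smoking,
    w = sm$survey_weight
  )
  n_prices <- tapply(d$log_price, list(d$region, d$pc),
                     function(x) length(unique(x)))
  thin <- which(is.na(n_prices) | n_prices < 2, arr.ind = TRUE)
  if (nrow(thin)) {
    cells <- paste(rownames(n_prices)[thin[, 1]],
                   colnames(n_prices)[thin[, 2]], sep = "/")
    stopf("fewer than 2 distinct state-average prices in cell(s): %s",
          paste(cells, collapse = ", "))
  }
  fml <- log_cpd ~ region * pc + region:pc:log_price + age + female +
    log_income + education + years_smoking
  if (length(unique(sm$year %||% 1)) > 1) {
    d$year <- factor(sm$year)
    fml <- stats::update(fml, . ~ . + year)
  }
  fit <- stats::lm(fml, data = d, weights = w)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stopf("rank-deficient design; collinear term(s): %s",
          paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  vc <- sandwich::vcovHC(fit, type = "HC1")
  se_cf <- sqrt(diag(vc))

  regions <- levels(d$region)
  pcs <- levels(d$pc)
  conditional <- se <- matrix(NA_real_, length(regions), length(pcs),
                              dimnames = list(regions, pcs))
  for (r in regions) {
    for (k in pcs) {
      nm <- paste0("region", r, ":pc", k, ":log_price")
      if (!nm %in% names(cf)) {
        stopf("missing interaction coefficient %s", nm)
      }
      conditional[r, k] <- cf[nm]
      se[r, k] <- se_cf[nm]
    }
  }
  list(conditional = conditional, se = se, model = fit)
}

#' Fit the two-part elasticity model
#'
#' Convenience wrapper fitting both margins on the same records and
#' combining them into an [elasticity_table()].
#'
#' @param records A `"smoker_survey"` data frame.
#' @return An object of class `"elasticity_fit"` with elements `table`
#'   (the [elasticity_table()]), `prevalence_fit`, `conditional_fit`,
#'   and `n` (records used).
#' @examples
#' svy <- generate_survey(generator_config(seed = 5, n_respondents = 20000))
#' fit <- estimate_elasticities(svy)
#' coef(fit)["South", "PC4"]
#' @export
estimate_elasticities <- function(records) {
  prev <- estimate_prevalence(records)
  cond <- estimate_conditional(records)
  structure(list(table = combine_elasticities(prev, cond),
                 prevalence_fit = prev, conditional_fit = cond,
                 n = nrow(records), n_smokers = sum(records$smokes)),
            class = "elasticity_fit")
}

#' @export
print.elasticity_fit <- function(x, ...) {
  cat(sprintf("<elasticity_fit> %d records (%d smokers)\n", x$n, x$n_smokers))
  print(x$table)
  invisible(x)
}

#' @export
coef.elasticity_fit <- function(object, ...) object$table$total

#' @export
summary.elasticity_fit <- function(object, ...) {
  tab <- as.data.frame(object$table)
  cat(sprintf("Two-part elasticity model: %d records, %d smokers\n",
              object$n, object$n_smokers))
  cat("\nPrevalence (probit, average marginal effect / mean prevalence):\n")
  print(round(cbind(estimate = object$table$prevalence,
                    se = object$table$prevalence_se), 3))
  cat("\nConditional (log-log, HC1 standard errors):\n")
  print(round(object$table$conditional, 3))
  cat("\nTotal = prevalence + conditional:\n")
  print(round(object$table$total, 3))
  invisible(tab)
}

#' Read or write an elasticity table as CSV
#'
#' Long layout mirroring the standard region-by-category presentation:
#' one row per (region, PC) with `prevalence`, `conditional`, `total` and,
#' when available, standard errors.
#'
#' @param table An [elasticity_table()].
#' @param path File path.
#' @return `read_elasticities()` returns an [elasticity_table()];
#'   `write_elasticities()` returns `path` invisibly.
#' @export
write_elasticities <- function(table, path) {
  stopifnot(inherits(table, "elasticity_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_elasticities
#' @export
read_elasticities <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "pc", "prevalence", "conditional")
  if (!all(need %in% names(d))) {
    stop("elasticity CSV needs columns ", paste(need, collapse = ", "))
  }
  regions <- region_levels()
  prev <- stats::setNames(
    vapply(regions, function(r) d$prevalence[d$region == r][1], numeric(1)),
    regions)
  cond <- matrix(NA_real_, 5, 4, dimnames = list(regions, pc_levels()))
  cond[cbind(d$region, d$pc)] <- d$conditional
  cse <- NULL
  if ("conditional_se" %in% names(d)) {
    cse <- cond
    cse[cbind(d$region, d$pc)] <- d$conditional_se
  }
  pse <- NULL
  if ("prevalence_se" %in% names(d)) {
    pse <- stats::setNames(
      vapply(regions, function(r) d$prevalence_se[d$region == r][1],
             numeric(1)),
      regions)
  }
  elasticity_table(prev, cond, prevalence_se = pse, conditional_se = cse)
}
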