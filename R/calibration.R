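# Baseline revenue and calibration of the illicit market share: survey
# phone interviews understate the illicit segment, so PC1 is inflated --
# every legal category reduced by one proportional factor, the freed mass
# moved into PC1 -- until simulated yearly tax revenue matches the observed
# aggregate collection.

#' Yearly tax revenue implied by a market state
#'
#' Sums per-pack taxes over the legal cells: for each (state, legal PC)
#' cell, `packs/year x per-pack tax` at the cell's mean price, where
#' `packs/year = smokers x cigarettes/day x 365 / 20`. The illicit segment
#' (PC1) contributes nothing. Ad valorem components with the national-
#' maximum base use the highest cell price of the category across states.
#'
#' @param market A [market_state()].
#' @param regime A [tax_regime()].
#' @return Revenue in BRL per year.
#' @examples
#' mk <- aggregate_market(generate_survey(generator_config(seed = 2,
#'                                                         n_respondents = 20000)))
#' baseline_revenue(mk, default_current_regime()) / 1e9  # BRL billions
#' @export
baseline_revenue <- function(market, regime) {
  stopifnot(inherits(market, "market_state"), inherits(regime, "tax_regime"))
  legal <- market[market$pc != "PC1", , drop = FALSE]
  if (!nrow(legal)) return(0)
  pmax_pc <- tapply(legal$mean_price, legal$pc, max)
  packs <- legal$smokers * legal$mean_cpd * 365 / 20
  tax <- vapply(seq_len(nrow(legal)), function(i) {
    assess(legal$mean_price[i], pmax_pc[[legal$pc[i]]], legal$state[i],
           regime)$total_tax
  }, numeric(1))
  sum(packs * tax)
}

# Shift a proportion delta of every legal category's smokers into PC1.
shift_market <- function(market, delta) {
  out <- market
  legal <- out$pc != "PC1"
  moved <- tapply(out$smokers[legal] * delta, out$state[legal], sum)
  out$smokers[legal] <- out$smokers[legal] * (1 - delta)
  i1 <- which(out$pc == "PC1")
  out$smokers[i1] <- out$smokers[i1] + as.numeric(moved[out$state[i1]])
  tot <- tapply(out$smokers, out$state, sum)
  out$share <- ifelse(tot[out$state] > 0, out$smokers / tot[out$state], 0)
  out
}

#' Calibrate the illicit market share to a revenue target
#'
#' Finds, by bisection, the single proportional factor `delta` such that
#' moving a fraction `delta` of every legal category's smokers (in every
#' state) into the illicit segment makes [baseline_revenue()] match
#' `target_revenue`. Legal shares are scaled multiplicatively, so they can
#' approach but never cross zero. Revenue is linear and strictly
#' decreasing in `delta` while the legal market is non-empty, so the
#' bisection has a unique solution whenever
#' `0 <= target_revenue <= baseline_revenue(market, regime)`.
#'
#' @param market A [market_state()].
#' @param regime A [tax_regime()] (current rules).
#' @param target_revenue Observed yearly collection, BRL.
#' @param tol Relative revenue tolerance of the bisection.
#' @return An object of class `"calibration_result"`: list with `delta`,
#'   `shift_pp` (percentage points of each state's smokers moved into
#'   PC1), `average_shift_pp`, `market` (the adjusted [market_state()]),
#'   `achieved_revenue` and `target_revenue`.
#' @export
calibrate_illicit_market <- function(market, regime, target_revenue,
                                     tol = 1e-6) {
  stopifnot(inherits(market, "market_state"), target_revenue >= 0)
  r0 <- baseline_revenue(market, regime)
  if (target_revenue > r0 * (1 + 1e-12)) {
    stopf(paste("target revenue %.3e exceeds the uncalibrated revenue %.3e:",
                "calibration can only shrink the legal market"),
          target_revenue, r0)
  }
  if (target_revenue == 0) {
    warning("zero revenue target: shifting the entire legal market into PC1")
    delta <- 1
  } else if (abs(r0 - target_revenue) / target_revenue <= tol) {
    delta <- 0
  } else {
    lo <- 0
    hi <- 1
    repeat {
      mid <- (lo + hi) / 2
      r <- baseline_revenue(shift_market(market, mid), regime)
      if (abs(r - target_revenue) / target_revenue <= tol ||
          hi - lo < 1e-12) {
        delta <- mid
        break
      }
      if (r > target_revenue) lo <- mid else hi <- mid
    }
  }
  adjusted <- shift_market(market, delta)
  legal_share <- 1 - market$share[market$pc == "PC1"]
  names(legal_share) <- market$state[market$pc == "PC1"]
  shift_pp <- 100 * delta * legal_share
  structure(list(delta = delta,
                 shift_pp = shift_pp,
                 average_shift_pp = mean(shift_pp),
                 market = adjusted,
                 achieved_revenue = baseline_revenue(adjusted, regime),
                 target_revenue = target_revenue),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n")
  cat(sprintf("  delta = %.4f (proportional reduction of legal shares)\n",
              x$delta))
  cat(sprintf("  average shift into PC1: %.1f percentage points\n",
              x$average_shift_pp))
  s1 <- x$market$share[x$market$pc == "PC1"]
  cat(sprintf("  post-calibration illicit share: %.0f%% to %.0f%% across states\n",
              100 * min(s1), 100 * max(s1)))
  cat(sprintf("  revenue: %.3f BRL Bi/year (target %.3f)\n",
              x$achieved_revenue / 1e9, x$target_revenue / 1e9))
  invisible(x)
}
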