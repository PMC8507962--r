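# Per-pack tax assessment and the pricing inversions (minimum feasible
# price, price from a target markup, markup implied by a price).

#' Assess per-pack taxes on a cigarette pack
#'
#' Computes the BRL amount of every component of a regime for a pack sold at
#' `price_local` in `state`, when the highest retail price of the brand
#' across the country is `price_national_max`. Ad valorem components use
#' their declared base; the burden is always computed against the local
#' retail price. Under the CBS base convention a producer that prices a
#' brand below its national maximum pays the same CBS amount but faces a
#' strictly larger burden.
#'
#' @param price_local Local retail price, BRL/pack, `> 0`.
#' @param price_national_max Highest retail price of the brand in any state,
#'   BRL/pack; must be `>= price_local`.
#' @param state Two-letter state code.
#' @param regime A [tax_regime()].
#' @return An object of class `"tax_assessment"`: list with `components`
#'   (named BRL amounts), `total_tax` (BRL/pack) and `burden`
#'   (total tax / local retail price).
#' @examples
#' cbs <- tax_regime(list(
#'   tax_component("cbs_ad_valorem", "ad_valorem", rate = 0.22,
#'                 base = "highest_national_brand_price"),
#'   tax_component("cbs_specific", "specific", amount = 1.10)
#' ))
#' assess(10, 14, "SP", cbs)$total_tax  # 14 * 0.22 + 1.10 = 4.18
#' @export
assess <- function(price_local, price_national_max = price_local, state,
                   regime) {
  stopifnot(inherits(regime, "tax_regime"))
  if (!is.numeric(price_local) || price_local <= 0) {
    stop("price_local must be > 0")
  }
  if (price_national_max < price_local) {
    stopf(paste("price_national_max (%.2f) < price_local (%.2f):",
                "violates the definition of the national maximum"),
          price_national_max, price_local)
  }
  check_states(state)
  ov <- regime$state_overrides[[state]]
  amounts <- vapply(regime$components, function(comp) {
    rate <- comp$rate
    if (!is.null(ov) && comp$name %in% names(ov)) rate <- ov[[comp$name]]
    if (comp$kind == "specific") {
      comp$amount
    } else if (comp$base == "local_retail_price") {
      rate * price_local
    } else {
      rate * price_national_max
    }
  }, numeric(1))
  names(amounts) <- vapply(regime$components, `[[`, character(1), "name")
  total <- sum(amounts)
  structure(list(components = amounts, total_tax = total,
                 burden = total / price_local,
                 price_local = price_local,
                 price_national_max = price_national_max,
                 state = state),
            class = "tax_assessment")
}

#' @export
print.tax_assessment <- function(x, ...) {
  cat(sprintf("<tax_assessment> state %s, price %.2f BRL (national max %.2f)\n",
              x$state, x$price_local, x$price_national_max))
  for (nm in names(x$components)) {
    cat(sprintf("  %-16s %6.3f BRL\n", nm, x$components[[nm]]))
  }
  cat(sprintf("  total tax %.3f BRL/pack, burden %.1f%% of retail price\n",
              x$total_tax, 100 * x$burden))
  invisible(x)
}

# Total ad valorem rate and specific amount in a state under uniform
# national pricing (chosen price = national maximum, so both bases
# coincide). Errors if the combined rate leaves no feasible price.
uniform_rates <- function(regime, state) {
  er <- effective_rates(regime, state)
  alpha <- er$alpha_local + er$alpha_national
  if (alpha >= 1) {
    stopf("combined ad valorem rate %.3f >= 1 in state %s: no feasible price",
          alpha, state)
  }
  list(alpha = alpha, beta = er$beta)
}

#' Minimum feasible retail price under uniform national pricing
#'
#' The lowest price (rounded up to the cent) at which a pack sold uniformly
#' across states covers its taxes and unit cost in `state`, i.e. the
#' smallest `p` with `p - total_tax(p) >= unit_cost` and a tax burden
#' strictly below 100 percent. Before rounding the closed form is
#' `p* = (beta + unit_cost) / (1 - alpha)`, where `alpha` is the combined ad
#' valorem rate and `beta` the combined specific amount in the state. With a
#' zero cost and an empty regime the floor is 0.
#'
#' @param unit_cost Production cost, BRL/pack, `>= 0`.
#' @param state Two-letter state code.
#' @param regime A [tax_regime()].
#' @return Price in BRL/pack, a multiple of 0.01.
#' @examples
#' cbs <- tax_regime(list(
#'   tax_component("cbs_ad_valorem", "ad_valorem", rate = 0.22,
#'                 base = "highest_national_brand_price"),
#'   tax_component("cbs_specific", "specific", amount = 1.10)
#' ))
#' floor_price(0, "SP", cbs)  # 1.10 / 0.78 = 1.4103 -> 1.42
#' @export
floor_price <- function(unit_cost, state, regime) {
  stopifnot(unit_cost >= 0)
  ur <- uniform_rates(regime, state)
  p_star <- (ur$beta + unit_cost) / (1 - ur$alpha)
  if (p_star <= 0) return(round_up_cent(unit_cost))
  p <- round_up_cent(p_star)
  # keep the burden strictly below 100%: at zero unit cost the closed form
  # can land exactly on a cent with zero margin (burden exactly 100%), in
  # which case the next cent is the first feasible price
  if (p * (1 - ur$alpha) - ur$beta <= 1e-9) p <- round(p + 0.01, 2)
  p
}

#' Uniform price that attains a target markup
#'
#' The price `p` solving `p - total_tax(p) - unit_cost = markup * unit_cost`
#' under uniform national pricing:
#' `p = ((1 + markup) * unit_cost + beta) / (1 - alpha)`, rounded up to the
#' cent unless `round = FALSE`. With `markup = 0` this is the unrounded
#' minimum feasible price.
#'
#' @param markup Target markup over unit cost, fraction `>= 0`.
#' @param unit_cost Production cost, BRL/pack.
#' @param state Two-letter state code.
#' @param regime A [tax_regime()].
#' @param round Round the result up to the cent? Default `TRUE`.
#' @return Price in BRL/pack.
#' @examples
#' r <- tax_regime(list(tax_component("av", "ad_valorem", rate = 0.5)))
#' price_from_markup(1, 1, "SP", r)  # (2 + 0) / 0.5 = 4.00
#' @export
price_from_markup <- function(markup, unit_cost, state, regime,
                              round = TRUE) {
  stopifnot(markup >= 0, unit_cost >= 0)
  ur <- uniform_rates(regime, state)
  p <- ((1 + markup) * unit_cost + ur$beta) / (1 - ur$alpha)
  if (round) round_up_cent(p) else p
}

#' Markup implied by a uniform price
#'
#' Inverse of [price_from_markup()]:
#' `markup = (p * (1 - alpha) - beta - unit_cost) / unit_cost`. Exact
#' round-trip (`markup_of(price_from_markup(m, ..., round = FALSE))`)
#' recovers `m` to numerical precision; cent rounding perturbs it by up to
#' one cent of margin.
#'
#' @param price Uniform retail price, BRL/pack.
#' @param unit_cost Production cost, BRL/pack, `> 0` (the markup is
#'   undefined at zero cost).
#' @param state Two-letter state code.
#' @param regime A [tax_regime()].
#' @return Markup as a fraction of unit cost.
#' @export
markup_of <- function(price, unit_cost, state, regime) {
  if (unit_cost <= 0) {
    stop("markup is undefined for unit_cost <= 0")
  }
  ur <- uniform_rates(regime, state)
  (price * (1 - ur$alpha) - ur$beta - unit_cost) / unit_cost
}
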