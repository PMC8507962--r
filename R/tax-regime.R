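# Tax regimes: lists of ad valorem / specific components with per-state
# overrides. A pack is 20 cigarettes throughout; all amounts are BRL per pack.

#' Define a tax component
#'
#' A component is either ad valorem (a rate applied to a declared price base)
#' or specific (a fixed BRL amount per 20-cigarette pack). Ad valorem
#' components declare whether their base is the local retail price or the
#' highest retail price of the brand across the country (the base of the
#' proposed CBS).
#'
#' @param name Component label, e.g. `"icms"` or `"cbs_ad_valorem"`.
#' @param kind `"ad_valorem"` or `"specific"`.
#' @param rate Fraction in `[0, 1)`; required for ad valorem components.
#' @param amount BRL per pack, `>= 0`; required for specific components.
#' @param base Price base for ad valorem components:
#'   `"local_retail_price"` or `"highest_national_brand_price"`.
#' @param level `"federal"` or `"state"`. State-level components are the ones
#'   whose rate may be overridden per state in [tax_regime()].
#' @return An object of class `"tax_component"`.
#' @examples
#' tax_component("cbs_ad_valorem", "ad_valorem", rate = 0.22,
#'               base = "highest_national_brand_price")
#' tax_component("cbs_specific", "specific", amount = 1.10)
#' @export
tax_component <- function(name, kind = c("ad_valorem", "specific"),
                          rate = NULL, amount = NULL,
                          base = c("local_retail_price",
                                   "highest_national_brand_price"),
                          level = c("federal", "state")) {
  kind <- match.arg(kind)
  base <- match.arg(base)
  level <- match.arg(level)
  if (kind == "ad_valorem") {
    if (is.null(rate)) stopf("ad valorem component '%s' needs a rate", name)
    if (rate < 0 || rate >= 1) {
      stopf("rate of component '%s' must be in [0, 1)", name)
    }
    amount <- 0
  } else {
    if (is.null(amount)) stopf("specific component '%s' needs an amount", name)
    if (amount < 0) stopf("amount of component '%s' must be >= 0", name)
    rate <- 0
  }
  structure(list(name = name, kind = kind, rate = rate, amount = amount,
                 base = base, level = level),
            class = "tax_component")
}

#' Define a tax regime
#'
#' A regime is an ordered list of [tax_component()]s plus optional per-state
#' rate overrides for state-level components (in Brazil, the ICMS rate on
#' cigarettes differs by state). For every state the combined ad valorem rate
#' charged on the local retail price must stay below 1, otherwise no feasible
#' retail price exists.
#'
#' @param components List of [tax_component()] objects.
#' @param state_overrides Named list: state code -> named numeric vector of
#'   component rates overriding the component default in that state.
#' @param name Optional regime label.
#' @return An object of class `"tax_regime"`.
#' @examples
#' cbs <- tax_regime(list(
#'   tax_component("cbs_ad_valorem", "ad_valorem", rate = 0.22,
#'                 base = "highest_national_brand_price"),
#'   tax_component("cbs_specific", "specific", amount = 1.10)
#' ), name = "CBS special regime")
#' cbs
#' @export
tax_regime <- function(components = list(), state_overrides = list(),
                       name = "regime") {
  if (inherits(components, "tax_component")) components <- list(components)
  ok <- vapply(components, inherits, logical(1), what = "tax_component")
  if (!all(ok)) stop("components must all be tax_component objects")
  nms <- vapply(components, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("component names must be unique")
  if (length(state_overrides)) {
    check_states(names(state_overrides), "state_overrides")
    for (s in names(state_overrides)) {
      ov <- state_overrides[[s]]
      bad <- setdiff(names(ov), nms)
      if (length(bad)) {
        stopf("state override for %s names unknown component(s): %s",
              s, paste(bad, collapse = ", "))
      }
      if (any(ov < 0 | ov >= 1)) {
        stopf("state override rates for %s must be in [0, 1)", s)
      }
    }
  }
  regime <- structure(list(components = components,
                           state_overrides = state_overrides,
                           name = name),
                      class = "tax_regime")
  # feasibility: combined local-base ad valorem rate < 1 in every state
  for (s in brazil_states()$state) {
    er <- effective_rates(regime, s)
    if (er$alpha_local + er$alpha_national >= 1) {
      stopf("combined ad valorem rate in state %s is %.3f >= 1: infeasible",
            s, er$alpha_local + er$alpha_national)
    }
  }
  regime
}

#' Effective ad valorem and specific rates of a regime in a state
#'
#' Collapses a regime into the combined ad valorem rate on the local retail
#' price (`alpha_local`), the combined ad valorem rate on the highest
#' national brand price (`alpha_national`), and the combined specific amount
#' (`beta`, BRL/pack), applying any per-state overrides. Under uniform
#' national pricing the two bases coincide and the total ad valorem rate is
#' `alpha_local + alpha_national`.
#'
#' @param regime A [tax_regime()].
#' @param state Two-letter state code.
#' @return List with `alpha_local`, `alpha_national`, `beta`.
#' @export
effective_rates <- function(regime, state) {
  stopifnot(inherits(regime, "tax_regime"), length(state) == 1L)
  check_states(state)
  al <- an <- bt <- 0
  ov <- regime$state_overrides[[state]]
  for (comp in regime$components) {
    rate <- comp$rate
    if (!is.null(ov) && comp$name %in% names(ov)) rate <- ov[[comp$name]]
    if (comp$kind == "ad_valorem") {
      if (comp$base == "local_retail_price") al <- al + rate
      else an <- an + rate
    } else {
      bt <- bt + comp$amount
    }
  }
  list(alpha_local = al, alpha_national = an, beta = bt)
}

#' @export
print.tax_component <- function(x, ...) {
  if (x$kind == "ad_valorem") {
    cat(sprintf("  %-16s ad valorem %5.2f%% on %s (%s)\n", x$name,
                100 * x$rate, gsub("_", " ", x$base), x$level))
  } else {
    cat(sprintf("  %-16s specific   %5.2f BRL/pack (%s)\n", x$name,
                x$amount, x$level))
  }
  invisible(x)
}

#' @export
print.tax_regime <- function(x, ...) {
  cat(sprintf("<tax_regime> %s: %d component(s)\n", x$name,
              length(x$components)))
  for (comp in x$components) print(comp)
  if (length(x$state_overrides)) {
    cat(sprintf("  per-state overrides for %d state(s): %s\n",
                length(x$state_overrides),
                paste(names(x$state_overrides), collapse = ", ")))
  }
  invisible(x)
}

#' Default current-law and reform tax regimes
#'
#' `default_current_regime()` represents current Brazilian cigarette
#' taxation as effective rates on the retail price: PIS/COFINS (ad valorem),
#' IPI (an ad valorem plus a specific portion, standing in for the statutory
#' IPI special rule), and a state-level ICMS whose rate varies by state. The
#' statutory rate schedules are not reproduced; the components are effective
#' rates calibrated so that the simulated baseline tax burdens are about
#' 78/69/62 percent of the retail price for the low/medium/premium
#' categories, matching published aggregates for the Brazilian market.
#'
#' `default_reform_regime()` applies the reform: PIS/COFINS is replaced by
#' the CBS special regime for cigarettes (22 percent ad valorem on the
#' highest national retail price per brand plus a specific 1.10 BRL per
#' pack); IPI and ICMS are unchanged.
#'
#' @return A [tax_regime()].
#' @examples
#' default_current_regime()
#' default_reform_regime()
#' @export
default_current_regime <- function() {
  tax_regime(
    components = list(
      tax_component("pis_cofins", "ad_valorem", rate = 0.1115,
                    base = "local_retail_price", level = "federal"),
      tax_component("ipi_ad_valorem", "ad_valorem", rate = 0.1425,
                    base = "local_retail_price", level = "federal"),
      tax_component("ipi_specific", "specific", amount = 1.50,
                    level = "federal"),
      tax_component("icms", "ad_valorem", rate = 0.25,
                    base = "local_retail_price", level = "state")
    ),
    state_overrides = default_icms_overrides(),
    name = "current (PIS/COFINS + IPI + ICMS)"
  )
}

#' @rdname default_current_regime
#' @export
default_reform_regime <- function() {
  tax_regime(
    components = list(
      tax_component("cbs_ad_valorem", "ad_valorem", rate = 0.22,
                    base = "highest_national_brand_price", level = "federal"),
      tax_component("cbs_specific", "specific", amount = 1.10,
                    level = "federal"),
      tax_component("ipi_ad_valorem", "ad_valorem", rate = 0.1425,
                    base = "local_retail_price", level = "federal"),
      tax_component("ipi_specific", "specific", amount = 1.50,
                    level = "federal"),
      tax_component("icms", "ad_valorem", rate = 0.25,
                    base = "local_retail_price", level = "state")
    ),
    state_overrides = default_icms_overrides(),
    name = "reform (CBS + IPI + ICMS)"
  )
}

# ICMS effective rates by state: region-level defaults plus two states with
# distinctly higher rates. Population-weighted mean ~ 0.25.
default_icms_overrides <- function() {
  st <- brazil_states()
  region_rate <- c(North = 0.250, Northeast = 0.265, Southeast = 0.245,
                   South = 0.250, Midwest = 0.260)
  rate <- region_rate[as.character(st$region)]
  names(rate) <- st$state
  rate[["RJ"]] <- 0.280
  rate[["MS"]] <- 0.270
  lapply(rate, function(r) c(icms = r))
}

#' Read or write a tax regime as YAML
#'
#' The YAML layout has a `name`, a `components` list (each with `name`,
#' `kind`, and `rate`/`amount`, `base`, `level`), and an optional
#' `state_overrides` map of state code to component-rate maps.
#'
#' @param path File path.
#' @param regime A [tax_regime()].
#' @return `read_tax_regime()` returns a [tax_regime()];
#'   `write_tax_regime()` returns `path` invisibly.
#' @export
read_tax_regime <- function(path) {
  spec <- yaml::read_yaml(path)
  comps <- lapply(spec$components, function(cm) {
    tax_component(cm$name, cm$kind, rate = cm$rate, amount = cm$amount,
                  base = cm$base %||% "local_retail_price",
                  level = cm$level %||% "federal")
  })
  ov <- lapply(spec$state_overrides %||% list(), function(x) unlist(x))
  tax_regime(comps, state_overrides = ov, name = spec$name %||% "regime")
}

#' @rdname read_tax_regime
#' @export
write_tax_regime <- function(regime, path) {
  stopifnot(inherits(regime, "tax_regime"))
  comps <- lapply(regime$components, function(cm) {
    out <- list(name = cm$name, kind = cm$kind)
    if (cm$kind == "ad_valorem") {
      out$rate <- cm$rate
      out$base <- cm$base
    } else {
      out$amount <- cm$amount
    }
    out$level <- cm$level
    out
  })
  yaml::write_yaml(list(name = regime$name, components = comps,
                        state_overrides = lapply(regime$state_overrides,
                                                 as.list)),
                   path)
  invisible(path)
}
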