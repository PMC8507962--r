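# Fixed geography: the 27 Brazilian federative units and their macro-regions.
# Populations are approximate 2019 resident-population figures (inhabitants).
# price_index is a unitless 0-1 state price level used by the default
# generator configuration; it varies widely *within* each region because the
# estimators identify price effects from cross-state variation within region.

.cigsim_states <- local({
  tab <- rbind(
    # code  name                    region       pop_millions price_index
    c("AC", "Acre",                 "North",     "0.88", "0.05"),
    c("AP", "Amapa",                "North",     "0.85", "0.20"),
    c("AM", "Amazonas",             "North",     "4.14", "0.35"),
    c("PA", "Para",                 "North",     "8.60", "0.50"),
    c("RO", "Rondonia",             "North",     "1.78", "0.65"),
    c("RR", "Roraima",              "North",     "0.61", "0.80"),
    c("TO", "Tocantins",            "North",     "1.57", "0.95"),
    c("AL", "Alagoas",              "Northeast", "3.34", "0.05"),
    c("MA", "Maranhao",             "Northeast", "7.08", "0.1625"),
    c("PI", "Piaui",                "Northeast", "3.27", "0.275"),
    c("PB", "Paraiba",              "Northeast", "4.02", "0.3875"),
    c("SE", "Sergipe",              "Northeast", "2.30", "0.50"),
    c("CE", "Ceara",                "Northeast", "9.13", "0.6125"),
    c("RN", "Rio Grande do Norte",  "Northeast", "3.51", "0.725"),
    c("PE", "Pernambuco",           "Northeast", "9.56", "0.8375"),
    c("BA", "Bahia",                "Northeast", "14.87", "0.95"),
    c("ES", "Espirito Santo",       "Southeast", "4.02", "0.15"),
    c("MG", "Minas Gerais",         "Southeast", "21.17", "0.40"),
    c("SP", "Sao Paulo",            "Southeast", "45.92", "0.65"),
    c("RJ", "Rio de Janeiro",       "Southeast", "17.26", "0.90"),
    c("PR", "Parana",               "South",     "11.43", "0.15"),
    c("SC", "Santa Catarina",       "South",     "7.16", "0.50"),
    c("RS", "Rio Grande do Sul",    "South",     "11.38", "0.85"),
    c("MS", "Mato Grosso do Sul",   "Midwest",   "2.78", "0.05"),
    c("GO", "Goias",                "Midwest",   "7.02", "0.35"),
    c("MT", "Mato Grosso",          "Midwest",   "3.48", "0.65"),
    c("DF", "Distrito Federal",     "Midwest",   "3.02", "0.95")
  )
  data.frame(
    state = tab[, 1],
    name = tab[, 2],
    region = factor(tab[, 3], levels = c("North", "Northeast", "Southeast",
                                         "South", "Midwest")),
    population = as.numeric(tab[, 4]) * 1e6,
    price_index = as.numeric(tab[, 5]),
    stringsAsFactors = FALSE
  )
})

#' Brazilian federative units used throughout the package
#'
#' Returns the fixed table of the 27 Brazilian federative units (26 states
#' plus the Federal District) with their macro-region, approximate 2019
#' resident population, and the unitless state price level (`price_index`,
#' in `[0, 1]`) that drives cross-state price variation in the default
#' synthetic-survey configuration.
#'
#' @return A `data.frame` with columns `state` (two-letter code), `name`,
#'   `region` (factor with levels North, Northeast, Southeast, South,
#'   Midwest), `population` (inhabitants) and `price_index`.
#' @examples
#' head(brazil_states())
#' @export
brazil_states <- function() .cigsim_states

#' @rdname brazil_states
#' @return `region_levels()` returns the five macro-region names in their
#'   canonical order.
#' @export
region_levels <- function() levels(.cigsim_states$region)

#' Map state codes to macro-regions
#'
#' The region of each federative unit is a fixed, deterministic function of
#' the state code.
#'
#' @param state Character vector of two-letter state codes.
#' @return Factor of macro-regions, same length as `state`.
#' @examples
#' state_region(c("SP", "BA", "MS"))
#' @export
state_region <- function(state) {
  idx <- match(state, .cigsim_states$state)
  if (anyNA(idx)) {
    stop("unknown state code(s): ",
         paste(unique(state[is.na(idx)]), collapse = ", "))
  }
  .cigsim_states$region[idx]
}

pc_levels <- function() c("PC1", "PC2", "PC3", "PC4")

legal_pcs <- function() c("PC2", "PC3", "PC4")

check_states <- function(state, what = "state") {
  bad <- setdiff(unique(state), .cigsim_states$state)
  if (length(bad)) {
    stop("unknown ", what, " code(s): ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}
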