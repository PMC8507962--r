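# State x price-category market aggregates: smoker counts scaled to state
# populations through survey weights, mean pack prices and mean daily
# consumption per cell.

#' Construct a market state
#'
#' A market state is the state-by-price-category grid the simulation
#' engine operates on: population-scaled smoker counts, mean pack prices
#' and mean daily cigarette consumption per cell, plus state populations
#' and the official price floor. Normally built from survey records with
#' [aggregate_market()]; the constructor validates the grid invariants
#' (shares per state sum to 1, PC1 priced below the floor, legal
#' categories at or above it).
#'
#' @param cells `data.frame` with columns `state`, `pc` (`"PC1"`..`"PC4"`),
#'   `smokers`, `mean_price`, `mean_cpd`.
#' @param populations Named vector of state populations.
#' @param price_floor Official minimum legal price, BRL/pack.
#' @return An object of class `"market_state"`: the cell `data.frame` with
#'   a `region` and a within-state `share` column, ordered by state and
#'   category, with `populations` and `price_floor` attributes.
#' @export
market_state <- function(cells, populations, price_floor = 5.00) {
  need <- c("state", "pc", "smokers", "mean_price", "mean_cpd")
  if (!all(need %in% names(cells))) {
    stop("cells must have columns ", paste(need, collapse = ", "))
  }
  check_states(cells$state)
  if (!all(cells$pc %in% pc_levels())) stop("pc must be PC1..PC4")
  if (anyDuplicated(cells[c("state", "pc")])) {
    stop("duplicate (state, pc) cells")
  }
  if (any(cells$smokers < 0)) stop("smoker counts must be >= 0")
  cells <- cells[order(cells$state, cells$pc), , drop = FALSE]
  cells$region <- state_region(cells$state)
  tot <- tapply(cells$smokers, cells$state, sum)
  cells$share <- ifelse(tot[cells$state] > 0,
                        cells$smokers / tot[cells$state], 0)
  occupied <- cells$smokers > 0
  if (any(occupied & cells$pc == "PC1" & cells$mean_price >= price_floor)) {
    stop("PC1 cells must be priced below the official floor")
  }
  if (any(occupied & cells$pc != "PC1" & cells$mean_price < price_floor)) {
    stop("legal-category cells must be priced at or above the official floor")
  }
  rownames(cells) <- NULL
  structure(cells,
            populations = populations,
            price_floor = price_floor,
            class = c("market_state", "data.frame"))
}

#' Aggregate survey records into a market state
#'
#' Scales weighted smoker counts per (state, price category) cell to the
#' state population — each state's weighted smoker fraction among its
#' respondents is multiplied by its population — and computes weighted mean
#' prices and daily consumption per cell. Cells with no sampled smokers get
#' zero smokers and the national category means as price/intensity
#' placeholders so that downstream price arithmetic stays defined.
#'
#' @param records A `"smoker_survey"` data frame (see [generate_survey()]).
#' @param populations Named vector of inhabitants per state; defaults to
#'   the built-in state populations.
#' @param price_floor Official minimum legal price; defaults to the
#'   survey's `"price_floor"` attribute.
#' @return A [market_state()].
#' @examples
#' svy <- generate_survey(generator_config(seed = 3, n_respondents = 20000))
#' mk <- aggregate_market(svy)
#' head(mk)
#' @export
aggregate_market <- function(records,
                             populations = NULL,
                             price_floor = attr(records, "price_floor")) {
  st <- brazil_states()
  if (is.null(populations)) {
    populations <- stats::setNames(st$population, st$state)
  }
  if (is.null(price_floor)) price_floor <- 5.00
  check_states(records$state)
  missing <- setdiff(names(populations), unique(records$state))
  if (length(missing)) {
    stopf("no survey records for state(s): %s",
          paste(missing, collapse = ", "))
  }
  w <- records$survey_weight
  state_w <- tapply(w, records$state, sum)

  sm <- records[records$smokes, , drop = FALSE]
  if (!nrow(sm)) stop("no smokers in the survey records")
  pc <- factor(pc_levels()[sm$price_category], levels = pc_levels())
  key <- interaction(factor(sm$state, levels = names(populations)), pc,
                     drop = FALSE, lex.order = TRUE)
  wsm <- sm$survey_weight
  cell_w <- tapply(wsm, key, sum, default = 0)
  cell_price <- tapply(wsm * sm$price_paid, key, sum, default = 0) /
    ifelse(cell_w > 0, cell_w, NA)
  cell_cpd <- tapply(wsm * sm$cigarettes_per_day, key, sum, default = 0) /
    ifelse(cell_w > 0, cell_w, NA)

  grid <- expand.grid(pc = pc_levels(), state = names(populations),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[c("state", "pc")]
  k <- paste(grid$state, grid$pc, sep = ".")
  smokers <- populations[grid$state] * (cell_w[k] / state_w[grid$state])
  mean_price <- as.numeric(cell_price[k])
  mean_cpd <- as.numeric(cell_cpd[k])

  # national weighted category means as placeholders for empty cells
  for (j in seq_along(pc_levels())) {
    sel <- grid$pc == pc_levels()[j]
    empty <- sel & (is.na(mean_price) | smokers == 0)
    if (any(empty)) {
      np <- weighted_mean(mean_price[sel & !empty], smokers[sel & !empty])
      nc <- weighted_mean(mean_cpd[sel & !empty], smokers[sel & !empty])
      mean_price[empty] <- np
      mean_cpd[empty] <- nc
    }
  }

  market_state(data.frame(state = grid$state, pc = grid$pc,
                          smokers = as.numeric(smokers),
                          mean_price = mean_price, mean_cpd = mean_cpd,
                          stringsAsFactors = FALSE),
               populations = populations, price_floor = price_floor)
}

#' @export
print.market_state <- function(x, ...) {
  cat(sprintf("<market_state> 27 states x 4 price categories, floor %.2f BRL\n",
              attr(x, "price_floor")))
  tot <- sum(x$smokers)
  cat(sprintf("  %.2f million smokers; illicit (PC1) share %.1f%%\n",
              tot / 1e6, 100 * sum(x$smokers[x$pc == "PC1"]) / tot))
  by_pc <- vapply(split(x, x$pc), function(d) {
    weighted_mean(d$mean_price, d$smokers)
  }, numeric(1))
  cat("  mean prices (BRL/pack): ",
      paste(sprintf("%s %.2f", names(by_pc), by_pc), collapse = ", "), "\n")
  invisible(x)
}

#' Total yearly cigarette consumption per market cell, in packs
#'
#' `packs/year = smokers * cigarettes/day * 365 / 20`.
#'
#' @param market A [market_state()].
#' @return Numeric vector aligned with the market rows.
#' @export
packs_per_year <- function(market) {
  market$smokers * market$mean_cpd * 365 / 20
}

#' Read or write a market state as CSV
#'
#' @param market A [market_state()].
#' @param path File path.
#' @return `read_market()` returns a [market_state()]; `write_market()`
#'   returns `path` invisibly.
#' @export
write_market <- function(market, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# price_floor: %.2f", attr(market, "price_floor")), con)
  pops <- attr(market, "populations")
  writeLines(paste0("# populations: ",
                    paste(sprintf("%s=%0.f", names(pops), pops),
                          collapse = ";")), con)
  utils::write.csv(as.data.frame(market)[c("state", "pc", "smokers",
                                           "mean_price", "mean_cpd")],
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_market
#' @export
read_market <- function(path) {
  hdr <- readLines(path, n = 2L)
  floor <- as.numeric(sub("# price_floor:", "", hdr[1]))
  pop_str <- strsplit(sub("# populations: ", "", hdr[2]), ";")[[1]]
  kv <- strsplit(pop_str, "=")
  pops <- stats::setNames(as.numeric(vapply(kv, `[`, character(1), 2)),
                          vapply(kv, `[`, character(1), 1))
  cells <- utils::read.csv(path, skip = 2L, stringsAsFactors = FALSE)
  market_state(cells, populations = pops, price_floor = floor)
}
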