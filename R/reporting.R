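# Reporting arithmetic and output writing.

#' Percentage change
#'
#' `100 * (new - old) / old`, reported at the conventional one-decimal
#' precision (internal arithmetic is unrounded; set `digits = NULL` to
#' skip rounding).
#'
#' @param new,old Numeric; `old` must be positive.
#' @param digits Decimal places of the reported value (default 1).
#' @return Percentage change.
#' @examples
#' percent_change(23.20e9, 17.75e9)  # 30.7
#' percent_change(8.40, 7.90)        # 6.3
#' @export
percent_change <- function(new, old, digits = 1) {
  if (any(old <= 0)) stop("old must be > 0")
  pc <- 100 * (new - old) / old
  if (is.null(digits)) pc else round(pc, digits)
}

#' Revenue shares by price category
#'
#' The percentage of total cigarette tax revenue collected from each legal
#' price category of a scenario result; shares sum to 100 within rounding.
#'
#' @param result A `"scenario_result"`.
#' @param digits Decimal places (default 2).
#' @return Named vector of percentages for `PC2`, `PC3`, `PC4`.
#' @export
revenue_shares <- function(result, digits = 2) {
  stopifnot(inherits(result, "scenario_result"))
  round(100 * result$revenue_by_pc / result$revenue_total, digits)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
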