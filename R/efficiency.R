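# Expenditure deflation and operational-efficiency metrics.

#' Deflate and convert an expenditure series to real USD
#'
#' `real_usd(y) = nominal_brl(y) * index(base_year) / index(y) /
#' exchange_rate`. The convention mirrors standard practice for Brazilian
#' budget series: consumer-price (IPCA-style) deflation to a base year,
#' then conversion at a fixed rate of R$ 5 per USD 1.
#'
#' @param series data.frame with `year`, `nominal_brl`.
#' @param index data.frame with `year`, `index` (strictly positive).
#' @param base_year year whose price level defines the real values.
#' @param exchange_rate_brl_per_usd fixed conversion rate (default 5).
#' @return data.frame `year`, `nominal_brl`, `real_usd` (attributes record
#'   base year and rate).
#' @export
deflate_convert <- function(series, index, base_year,
                            exchange_rate_brl_per_usd = 5.0) {
  if (exchange_rate_brl_per_usd <= 0)
    stop("exchange rate must be > 0", call. = FALSE)
  if (any(index$index <= 0))
    stop("price index must be strictly positive", call. = FALSE)
  idx <- stats::setNames(index$index, index$year)
  need <- unique(c(series$year, base_year))
  miss <- setdiff(need, index$year)
  if (length(miss))
    stop("price index missing year(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  real <- series$nominal_brl * idx[as.character(base_year)] /
    idx[as.character(series$year)] / exchange_rate_brl_per_usd
  out <- data.frame(year = series$year, nominal_brl = series$nominal_brl,
                    real_usd = as.numeric(real))
  attr(out, "base_year") <- base_year
  attr(out, "exchange_rate_brl_per_usd") <- exchange_rate_brl_per_usd
  out
}

#' Operational efficiency: expenditure per sanction
#'
#' `OE[i, y] = E[y] / I[i, y]` for each sanction type i (infraction notice,
#' embargo, confiscation/destruction) and year y, where `E[y]` is the total
#' (real USD) expenditure of year y and `I[i, y]` the number of sanctions of
#' type i issued that year. The same `E[y]` is used for every sanction type
#' -- the three unit costs are alternative readings of one budget, not
#' additive components. Cells with zero sanctions are reported missing.
#'
#' @param expenditure data.frame with `year`, `real_usd`.
#' @param indicators an [annual_indicators()] data.frame.
#' @return data.frame of class `efficiency_table`: `year`, `sanction_type`,
#'   `count`, `expenditure_usd`, `oe_usd`.
#' @export
operational_efficiency <- function(expenditure, indicators) {
  years <- intersect(expenditure$year, indicators$year)
  if (length(years) == 0) stop("no overlapping years", call. = FALSE)
  cnt_cols <- c(infraction_notice = "notices_count",
                embargo = "embargoes_count",
                confiscation_destruction = "confiscations_count")
  rows <- lapply(years, function(y) {
    e <- expenditure$real_usd[expenditure$year == y][1]
    counts <- vapply(cnt_cols, function(cc)
      indicators[[cc]][indicators$year == y][1], 0)
    data.frame(year = y, sanction_type = names(cnt_cols),
               count = as.numeric(counts), expenditure_usd = e,
               oe_usd = ifelse(counts > 0, e / counts, NA_real_),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("efficiency_table", "data.frame")
  out
}

#' Average unit cost of a sanction type over a period
#'
#' Pooled ratio-of-sums (default): total expenditure over the period divided
#' by total sanctions of the type over the period -- the quantity behind
#' multi-year statements like "the average cost of issuing an infraction
#' notice". `mean_of_ratios` averages the annual unit costs instead.
#'
#' @param table an [operational_efficiency()] result.
#' @param period `c(first, last)` years.
#' @param sanction_type one of `"infraction_notice"`, `"embargo"`,
#'   `"confiscation_destruction"`; default all three.
#' @param mode `"pooled"` or `"mean_of_ratios"`.
#' @return named numeric vector of unit costs (USD per sanction).
#' @export
period_unit_cost <- function(table, period,
                             sanction_type = c("infraction_notice", "embargo",
                                               "confiscation_destruction"),
                             mode = c("pooled", "mean_of_ratios")) {
  mode <- match.arg(mode)
  if (length(period) == 1) period <- c(period, period)
  sub <- table[table$year >= period[1] & table$year <= period[2] &
                 table$sanction_type %in% sanction_type, , drop = FALSE]
  if (nrow(sub) == 0) stop("period outside table coverage", call. = FALSE)
  vapply(sanction_type, function(st) {
    s <- sub[sub$sanction_type == st, ]
    if (mode == "pooled") {
      tot <- sum(s$count)
      if (tot == 0) return(NA_real_)
      sum(s$expenditure_usd) / tot
    } else {
      mean(s$oe_usd, na.rm = TRUE)
    }
  }, 0)
}
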