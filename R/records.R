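# Enforcement-record ingestion and annual indicator construction.

#' Filter configuration for record ingestion
#'
#' The default state set is the nine states of the Legal Amazon. With
#' `flora_only = TRUE`, infraction notices (and their fines) are restricted
#' to theme "flora" while embargoes and confiscations are retained
#' regardless of theme: no unique key separates deforestation embargoes from
#' other flora-crime embargoes, so all are kept.
#'
#' @param legal_amazon_states character vector of two-letter state codes.
#' @param flora_only logical; restrict notices/fines to flora theme.
#' @param study_window `c(first_year, last_year)` inclusive.
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(legal_amazon_states = LEGAL_AMAZON_STATES,
                          flora_only = TRUE,
                          study_window = c(2000L, 2020L)) {
  if (length(legal_amazon_states) == 0)
    stop("state set must be non-empty", call. = FALSE)
  structure(list(legal_amazon_states = legal_amazon_states,
                 flora_only = flora_only,
                 study_window = as.integer(study_window)),
            class = "filter_config")
}

REQUIRED_RECORD_COLS <- c("record_id", "process_id", "date", "state", "theme",
                          "sanction_type", "fine_value_brl")

#' Ingest a raw enforcement-record table
#'
#' Cleans a raw export into an analysis-ready record collection: rejects
#' rows with unparseable dates, collapses duplicates (exact all-field
#' duplicates or repeated `record_id`s), and drops records outside the state
#' set, outside the study window, or -- for infraction notices when
#' `flora_only` -- with a non-flora theme. The ingest report counts rows
#' dropped per reason.
#'
#' @param raw data.frame with at least the columns `record_id, process_id,
#'   date, state, theme, sanction_type, fine_value_brl` (optional `x`, `y`).
#' @param filters a [filter_config()].
#' @return an object of class `ingest_result`: list with `records`
#'   (clean data.frame with added `year`) and `report` (named counts).
#' @export
ingest_records <- function(raw, filters = filter_config()) {
  missing_cols <- setdiff(REQUIRED_RECORD_COLS, names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!"x" %in% names(raw)) raw$x <- NA_real_
  if (!"y" %in% names(raw)) raw$y <- NA_real_
  raw <- raw[, c(REQUIRED_RECORD_COLS, "x", "y")]
  report <- c(n_input = nrow(raw), bad_date = 0L, duplicates = 0L,
              out_of_region = 0L, out_of_window = 0L, wrong_theme = 0L)
  if (nrow(raw) == 0) {
    raw$year <- integer(0)
    return(structure(list(records = raw, report = as.list(report)),
                     class = "ingest_result"))
  }

  d <- as.Date(as.character(raw$date), format = "%Y-%m-%d")
  bad <- is.na(d)
  report["bad_date"] <- sum(bad)
  raw <- raw[!bad, , drop = FALSE]
  d <- d[!bad]
  raw$year <- as.integer(format(d, "%Y"))

  dup <- duplicated(raw[, c(REQUIRED_RECORD_COLS, "x", "y")]) |
    duplicated(raw$record_id)
  report["duplicates"] <- sum(dup)
  raw <- raw[!dup, , drop = FALSE]

  out_region <- !(raw$state %in% filters$legal_amazon_states)
  report["out_of_region"] <- sum(out_region)
  raw <- raw[!out_region, , drop = FALSE]

  out_window <- raw$year < filters$study_window[1] |
    raw$year > filters$study_window[2]
  report["out_of_window"] <- sum(out_window)
  raw <- raw[!out_window, , drop = FALSE]

  if (isTRUE(filters$flora_only)) {
    wrong <- raw$sanction_type == "infraction_notice" & raw$theme != "flora"
    report["wrong_theme"] <- sum(wrong)
    raw <- raw[!wrong, , drop = FALSE]
  }
  rownames(raw) <- NULL
  structure(list(records = raw, report = as.list(report)),
            class = "ingest_result")
}

#' @export
print.ingest_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0(
    "<ingest_result> %d rows in, %d retained\n",
    "  dropped: %d bad date, %d duplicate, %d out of region, ",
    "%d out of window, %d wrong theme\n"),
    r$n_input, nrow(x$records), r$bad_date, r$duplicates,
    r$out_of_region, r$out_of_window, r$wrong_theme))
  invisible(x)
}

#' Annual enforcement indicators
#'
#' Per calendar year in the window: counts per sanction type, sum and mean
#' of fine values over notices (mean over notices with a nonzero fine),
#' share of geolocated notices (NA when there are no notices), and the
#' number of prosecution processes reaching the paid stage that year.
#'
#' @param records clean record data.frame (from [ingest_records()]).
#' @param prosecutions optional prosecution data.frame with `stage`,
#'   `stage_date`.
#' @param window optional `c(first, last)` years; defaults to the span of
#'   the data.
#' @return data.frame with one row per year, class `annual_indicators`.
#' @export
annual_indicators <- function(records, prosecutions = NULL, window = NULL) {
  if (!"year" %in% names(records))
    records$year <- as.integer(substr(records$date, 1, 4))
  if (is.null(window)) {
    if (nrow(records) == 0) stop("no records and no window given", call. = FALSE)
    window <- range(records$year)
  }
  years <- seq(window[1], window[2])
  paid_years <- integer(0)
  if (!is.null(prosecutions) && nrow(prosecutions) > 0) {
    paid <- prosecutions[prosecutions$stage == "paid", , drop = FALSE]
    paid_years <- as.integer(substr(paid$stage_date, 1, 4))
  }
  out <- do.call(rbind, lapply(years, function(y) {
    ry <- records[records$year == y, , drop = FALSE]
    nt <- ry[ry$sanction_type == "infraction_notice", , drop = FALSE]
    n_not <- nrow(nt)
    fines <- nt$fine_value_brl
    pos <- fines > 0
    data.frame(
      year = y,
      notices_count = n_not,
      embargoes_count = sum(ry$sanction_type == "embargo"),
      confiscations_count = sum(ry$sanction_type == "confiscation_destruction"),
      fines_total_brl = sum(fines),
      fines_mean_brl = if (any(pos)) mean(fines[pos]) else NA_real_,
      geolocated_share = if (n_not > 0) mean(!is.na(nt$x)) else NA_real_,
      paid_fines_count = sum(paid_years == y))
  }))
  class(out) <- c("annual_indicators", "data.frame")
  out
}

#' Aggregate annual indicators over a period
#'
#' Element-wise sum or annual mean of the indicator columns over an
#' inclusive year range. Under `mode = "sum"` the ratio column
#' `geolocated_share` is reported `NA` (a sum of shares has no meaning);
#' under `mode = "mean"` missing ratio values are excluded.
#'
#' @param indicators an [annual_indicators()] data.frame.
#' @param period `c(first, last)` years, within the series window.
#' @param mode `"sum"` or `"mean"`.
#' @return one-row data.frame of aggregated indicators.
#' @export
period_aggregate <- function(indicators, period, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  if (length(period) == 1) period <- c(period, period)
  rows <- indicators[indicators$year >= period[1] &
                       indicators$year <= period[2], , drop = FALSE]
  if (nrow(rows) == 0) stop("empty period", call. = FALSE)
  num <- setdiff(names(rows), "year")
  agg <- lapply(num, function(col) {
    v <- rows[[col]]
    if (mode == "mean") return(mean(v, na.rm = TRUE))
    if (col %in% c("geolocated_share")) return(NA_real_)
    sum(v)
  })
  out <- data.frame(period_start = period[1], period_end = period[2],
                    mode = mode, stats::setNames(agg, num))
  out
}

#' Paid-fine ratio of a prosecution cohort
#'
#' Share of processes filed within the cohort years whose terminal stage is
#' "paid" -- the ratio of lawsuits resulting in paid fines over filed ones.
#'
#' @param prosecutions data.frame with `process_id`, `filed_date`, `stage`.
#' @param cohort `c(first, last)` filing years.
#' @return fraction in \[0, 1\].
#' @export
paid_fine_ratio <- function(prosecutions, cohort) {
  if (length(cohort) == 1) cohort <- c(cohort, cohort)
  fy <- as.integer(substr(prosecutions$filed_date, 1, 4))
  sub <- prosecutions[fy >= cohort[1] & fy <= cohort[2], , drop = FALSE]
  # one terminal stage per process: paid dominates any other row
  stage_rank <- c(filed = 1, conciliation = 2, judged_first = 3,
                  judged_second = 4, suspended = 5, paid = 6)
  term <- tapply(stage_rank[sub$stage], sub$process_id, max)
  n <- length(term)
  if (n == 0) stop("no processes filed in the cohort: ratio undefined",
                   call. = FALSE)
  sum(term == stage_rank["paid"]) / n
}

#' Share of embargoes cross-referenced to flora infraction notices
#'
#' Fraction of embargo records whose `process_id` matches at least one
#' flora-theme infraction notice.
#'
#' @param embargoes record data.frame of embargoes.
#' @param notices record data.frame of infraction notices.
#' @return fraction in \[0, 1\].
#' @export
cross_reference_embargoes <- function(embargoes, notices) {
  emb <- embargoes[embargoes$sanction_type == "embargo", , drop = FALSE]
  if (nrow(emb) == 0)
    stop("no embargoes: share undefined", call. = FALSE)
  flora <- notices$process_id[notices$sanction_type == "infraction_notice" &
                                notices$theme == "flora"]
  mean(emb$process_id %in% flora)
}
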