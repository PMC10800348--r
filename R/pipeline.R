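# Pipeline orchestration: simulate -> ingest -> spatial match -> legality
# -> efficiency -> report, from one configuration, with a run manifest.

#' Pipeline configuration
#'
#' Bundles the per-stage configurations. Exactly one input mode is active:
#' a synthetic-landscape block (the default) or a directory of real input
#' files (`input_dir`, expecting the layout of [write_landscape()] plus
#' `records.csv`, `prosecutions.csv`, `expenditure.csv`,
#' `price_index.csv`).
#'
#' @param landscape a [landscape_config()] or NULL when `input_dir` is set.
#' @param rules a [rule_config()].
#' @param filters a [filter_config()].
#' @param match a [spatial_match_config()].
#' @param base_year deflation base year (defaults to the last study year).
#' @param exchange_rate_brl_per_usd fixed conversion rate.
#' @param input_dir optional directory of real inputs.
#' @param seed master seed; overrides the landscape config seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(landscape = landscape_config(),
                            rules = rule_config(),
                            filters = NULL,
                            match = NULL,
                            base_year = NULL,
                            exchange_rate_brl_per_usd = 5.0,
                            input_dir = NULL, seed = NULL) {
  if (!is.null(landscape) && !is.null(input_dir))
    stop("exactly one of synthetic landscape and input_dir may be active",
         call. = FALSE)
  if (is.null(landscape) && is.null(input_dir))
    stop("either a synthetic landscape config or input_dir is required",
         call. = FALSE)
  if (!is.null(seed) && !is.null(landscape)) landscape$seed <- as.integer(seed)
  if (is.null(filters)) {
    window <- if (!is.null(landscape)) range(landscape$years) else c(2000L, 2020L)
    filters <- filter_config(study_window = window)
  }
  if (is.null(match)) {
    # desk-scale default: bandwidth ~6% of the region extent resolves
    # sub-regional hotspots the way a 30 km bandwidth does at biome scale
    bw <- if (!is.null(landscape)) 0.06 * min(landscape$region_width_m,
                                              landscape$region_height_m)
          else 30000
    cell <- if (!is.null(landscape)) landscape$cell_size_m else 100
    match <- spatial_match_config(bandwidth_m = bw, cell_size_m = cell)
  }
  if (is.null(base_year))
    base_year <- if (!is.null(landscape)) max(landscape$years) else 2020L
  structure(list(landscape = landscape, rules = rules, filters = filters,
                 match = match, base_year = base_year,
                 exchange_rate_brl_per_usd = exchange_rate_brl_per_usd,
                 input_dir = input_dir,
                 seed = if (!is.null(landscape)) landscape$seed else
                   as.integer(seed %||% 1L)),
            class = "pipeline_config")
}

#' Run the full enforcement-analysis pipeline
#'
#' Executes simulate (or load) -> ingest -> annual indicators -> spatial
#' match -> legality -> efficiency, writes the output tables as CSV plus a
#' JSON run manifest when `out_dir` is given, and returns all stage results.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return an object of class `enforcement_run` with elements `landscape`,
#'   `bundle`, `ingest`, `indicators`, `match_series`, `balances`, `labels`,
#'   `attribution`, `overlap_flags`, `breakdown`, `illegality`,
#'   `efficiency`, `unit_costs`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "simulate"
  res <- tryCatch({
    if (!is.null(config$landscape)) {
      landscape <- generate_landscape(config$landscape, config$rules)
      bundle <- generate_enforcement(landscape, config$landscape)
    } else {
      raw <- read_landscape(config$input_dir)
      landscape <- structure(
        c(raw, list(config = NULL, rules = config$rules)),
        class = "synthetic_landscape")
      bundle <- list(
        records = read_records_csv(file.path(config$input_dir, "records.csv")),
        prosecutions = utils::read.csv(
          file.path(config$input_dir, "prosecutions.csv"),
          stringsAsFactors = FALSE),
        expenditure = utils::read.csv(
          file.path(config$input_dir, "expenditure.csv"),
          stringsAsFactors = FALSE),
        price_index = utils::read.csv(
          file.path(config$input_dir, "price_index.csv"),
          stringsAsFactors = FALSE))
    }

    stage <- "ingest"
    ing <- ingest_records(bundle$records, config$filters)
    window <- config$filters$study_window
    indicators <- annual_indicators(ing$records, bundle$prosecutions,
                                    window = window)

    stage <- "spatial-match"
    notices <- ing$records[ing$records$sanction_type == "infraction_notice", ]
    grid <- landscape$grid
    ms <- spatial_match_series(
      data.frame(year = notices$year, x = notices$x, y = notices$y),
      landscape$patches, grid, config$match)

    stage <- "legality"
    app <- derive_app_zones(landscape$streams, config$rules)
    balances <- compute_fc_balance(landscape$holdings, landscape$native_map,
                                   grid, config$rules)
    labels <- classify_patches(landscape$patches, landscape$holdings,
                               balances, app, config$rules)
    attribution <- attribute_notices(notices, landscape$patches,
                                     landscape$holdings, config$rules)
    flags <- protected_overlap_flags(landscape$holdings,
                                     landscape$protected_areas, config$rules)
    breakdown <- land_category_breakdown(landscape$patches,
                                         landscape$holdings,
                                         landscape$protected_areas)
    illegality <- illegality_enforcement_series(labels, attribution)

    stage <- "efficiency"
    spend <- deflate_convert(bundle$expenditure, bundle$price_index,
                             config$base_year,
                             config$exchange_rate_brl_per_usd)
    eff <- operational_efficiency(spend, indicators)
    uc <- period_unit_cost(eff, range(indicators$year))

    list(landscape = landscape, bundle = bundle, ingest = ing,
         indicators = indicators, match_series = ms, balances = balances,
         labels = labels, attribution = attribution, overlap_flags = flags,
         breakdown = breakdown, illegality = illegality, efficiency = eff,
         unit_costs = uc)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  manifest <- list(
    config_hash = config_hash(unclass_deep(config)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("enforcelens")),
    counts = list(
      records = nrow(res$bundle$records),
      records_retained = nrow(res$ingest$records),
      prosecutions = nrow(res$bundle$prosecutions),
      patches = nrow(res$landscape$patches),
      holdings = nrow(res$landscape$holdings)),
    warnings = res$bundle$warnings %||% character(0))
  res$manifest <- manifest

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name)
      utils::write.csv(format(df, digits = 10, trim = TRUE),
                       file.path(out_dir, name), row.names = FALSE)
    wr(res$indicators, "annual_indicators.csv")
    wr(as.data.frame(res$match_series), "spatial_match_series.csv")
    wr(res$balances, "fc_balance.csv")
    wr(as.data.frame(res$labels), "legality_labels.csv")
    wr(res$overlap_flags, "protected_overlap_flags.csv")
    wr(res$breakdown, "land_category_breakdown.csv")
    wr(as.data.frame(res$illegality), "illegality_series.csv")
    wr(as.data.frame(res$efficiency), "efficiency_table.csv")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  class(res) <- "enforcement_run"
  res
}

#' Build a pipeline configuration from a YAML file
#'
#' The YAML file may contain `landscape`, `rules`, `filters`, `match`,
#' `base_year`, `exchange_rate_brl_per_usd`, `input_dir` and `seed` blocks;
#' each key overrides the corresponding default.
#'
#' @param path YAML file path.
#' @param seed optional seed overriding the file's value.
#' @return a [pipeline_config()].
#' @export
pipeline_config_from_yaml <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$landscape) && !is.null(y$input_dir))
    stop("config conflict: both synthetic landscape and input_dir given",
         call. = FALSE)
  ls_cfg <- if (is.null(y$input_dir))
    do.call(landscape_config, y$landscape %||% list()) else NULL
  rules <- do.call(rule_config, y$rules %||% list())
  filters <- if (is.null(y$filters)) NULL else
    do.call(filter_config, y$filters)
  match <- if (is.null(y$match)) NULL else
    do.call(spatial_match_config, y$match)
  pipeline_config(landscape = ls_cfg, rules = rules, filters = filters,
                  match = match, base_year = y$base_year,
                  exchange_rate_brl_per_usd =
                    y$exchange_rate_brl_per_usd %||% 5.0,
                  input_dir = y$input_dir, seed = seed %||% y$seed)
}

#' Published headline enforcement figures
#'
#' Compiled summary statistics of federal environmental enforcement in the
#' Legal Amazon (IBAMA sanction records, PRODES deforestation rates, CAR
#' registry counts), as publicly reported: phase subtotals of embargoes,
#' fines and embargoed area, the 2004/2007 deforestation rates, and the
#' counts of deforesting and potentially-illegally-deforesting registered
#' holdings. Used to exercise the arithmetic of the reporting layer on real
#' published magnitudes.
#'
#' @return data.frame with `quantity`, `period`, `value`, `unit`.
#' @export
reported_figures <- function() {
  utils::read.csv(system.file("extdata", "reported_headline_figures.csv",
                              package = "enforcelens"),
                  stringsAsFactors = FALSE)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}

#' @export
print.enforcement_run <- function(x, ...) {
  ov <- attr(x$illegality, "overall")
  cat("<enforcement_run>\n")
  cat(sprintf("  manifest hash %s, seed %d\n", x$manifest$config_hash,
              x$manifest$seed))
  cat(sprintf("  %d records ingested (%d retained), %d patches, %d holdings\n",
              x$manifest$counts$records, x$manifest$counts$records_retained,
              x$manifest$counts$patches, x$manifest$counts$holdings))
  cat(sprintf("  mean spatial-match r: %.3f\n",
              mean(x$match_series$pearson_r, na.rm = TRUE)))
  cat(sprintf("  potentially illegal area noticed: %.1f%%; deforesting holdings noticed: %.1f%%\n",
              ov$pct_illegal_area_noticed, ov$pct_holdings_noticed))
  invisible(x)
}

#' Summary tables in the style of the enforcement analysis
#'
#' Assembles the headline tables from a pipeline run: annual indicators,
#' period aggregates with integer-rounded percent changes between two
#' sub-periods, the spatial-match series, the illegality series and the
#' efficiency table.
#'
#' @param run an [run_pipeline()] result.
#' @param split_year year separating the two comparison periods (defaults
#'   to the midpoint of the window).
#' @return named list of data.frames; percent changes carry the rounding
#'   rule in the column name (`_pct_rounded`).
#' @export
report_tables <- function(run, split_year = NULL) {
  ind <- run$indicators
  if (is.null(split_year))
    split_year <- floor(mean(range(ind$year)))
  p1 <- c(min(ind$year), split_year)
  p2 <- c(split_year + 1, max(ind$year))
  a1 <- period_aggregate(ind, p1, "mean")
  a2 <- period_aggregate(ind, p2, "mean")
  chg <- data.frame(
    indicator = c("notices_count", "embargoes_count", "confiscations_count"),
    period1_mean = c(a1$notices_count, a1$embargoes_count,
                     a1$confiscations_count),
    period2_mean = c(a2$notices_count, a2$embargoes_count,
                     a2$confiscations_count))
  chg$change_pct_rounded <- ifelse(
    chg$period1_mean == 0, NA_real_,
    report_percent(percent_change(chg$period1_mean, chg$period2_mean)))
  list(annual_indicators = ind,
       period_totals = rbind(period_aggregate(ind, p1, "sum"),
                             period_aggregate(ind, p2, "sum"),
                             period_aggregate(ind, range(ind$year), "sum")),
       period_changes = chg,
       spatial_match = as.data.frame(run$match_series),
       illegality = as.data.frame(run$illegality),
       efficiency = as.data.frame(run$efficiency))
}
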