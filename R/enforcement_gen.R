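# Synthetic enforcement, prosecution and expenditure records.

LEGAL_AMAZON_STATES <- c("AC", "AP", "AM", "MA", "MT", "PA", "RO", "RR", "TO")

#' Generate synthetic enforcement records coupled to a landscape
#'
#' Issues infraction notices per year whose locations are drawn from a
#' mixture: with probability `coupling_rho` near a same-year patch centroid
#' (isotropic Gaussian jitter of scale `jitter_sigma_m`, clamped to the
#' region), otherwise uniform over the region. Each notice carries
#' coordinates with probability `geolocation_prob`, spawns embargo /
#' confiscation records on the same process with the configured shares, and
#' opens a prosecution process that advances filed -> judged -> paid under
#' the configured transition probabilities. A whole-agency expenditure
#' series and a consumer price index are generated alongside.
#'
#' When `config$coverage_fraction` is set the spatial mixture is replaced by
#' holding-coverage sampling: each deforesting holding (>= 1 above-MMU patch)
#' is independently selected with that probability and receives one
#' geolocated notice at a contained patch centroid in the patch year.
#'
#' @param landscape a [generate_landscape()] result.
#' @param config the same [landscape_config()] used for the landscape.
#' @return an object of class `enforcement_bundle`: list with `records`,
#'   `prosecutions`, `expenditure`, `price_index`, `notice_truth` (per-notice
#'   target patch/holding), and `warnings`.
#' @export
generate_enforcement <- function(landscape, config = landscape$config) {
  W <- config$region_width_m; H <- config$region_height_m
  patches <- landscape$patches
  warn <- character(0)

  notices <- with_seed(substream_seed(config$seed, "notices"), {
    if (!is.null(config$coverage_fraction)) {
      coverage_notices(landscape, config)
    } else {
      rows <- list()
      for (year in config$years) {
        py <- patches[patches$year == year, ]
        if (nrow(py) == 0 && config$coupling_rho > 0) {
          warn <- c(warn, sprintf(
            "year %d has no patches; coupled notices fall back to uniform", year))
        }
        n <- config$notices_per_year
        if (n == 0) next
        coupled <- stats::runif(n) < config$coupling_rho & nrow(py) > 0
        tgt <- rep(NA_character_, n)
        x <- stats::runif(n, 0, W); y <- stats::runif(n, 0, H)
        for (i in which(coupled)) {
          j <- sample.int(nrow(py), 1)
          tgt[i] <- py$patch_id[j]
          x[i] <- min(max(py$cx[j] + stats::rnorm(1, 0, config$jitter_sigma_m), 0), W)
          y[i] <- min(max(py$cy[j] + stats::rnorm(1, 0, config$jitter_sigma_m), 0), H)
        }
        geo <- stats::runif(n) < config$geolocation_prob
        rows[[length(rows) + 1]] <- data.frame(
          year = year, x = ifelse(geo, x, NA_real_),
          y = ifelse(geo, y, NA_real_),
          true_x = x, true_y = y, target_patch = tgt, coupled = coupled,
          stringsAsFactors = FALSE)
      }
      if (length(rows)) do.call(rbind, rows) else empty_notice_draw()
    }
  })

  n <- nrow(notices)
  records <- if (n == 0) empty_records() else
    with_seed(substream_seed(config$seed, "records"), {
    theme <- ifelse(stats::runif(n) < config$flora_share, "flora", "other")
    if (!is.null(config$coverage_fraction)) theme <- rep("flora", n)
    fine <- stats::rlnorm(n, log(5e4), 1)
    day <- sample.int(364, n, replace = TRUE)
    date <- as.Date(sprintf("%d-01-01", notices$year)) + day
    state <- sample(LEGAL_AMAZON_STATES, n, replace = TRUE)
    base <- data.frame(
      record_id = sprintf("N%06d", seq_len(n)),
      process_id = sprintf("P%06d", seq_len(n)),
      date = as.character(date), state = state, theme = theme,
      sanction_type = "infraction_notice",
      fine_value_brl = round(fine, 2),
      x = notices$x, y = notices$y, stringsAsFactors = FALSE)
    spawn <- function(share, type, offset) {
      pick <- which(stats::runif(n) < share)
      if (!length(pick)) return(NULL)
      s <- base[pick, ]
      s$record_id <- sprintf("%s%06d", toupper(substr(type, 1, 1)), pick)
      s$sanction_type <- type
      s$fine_value_brl <- 0
      s$date <- as.character(as.Date(s$date) + offset)
      s
    }
    emb <- spawn(config$embargo_share, "embargo", 3L)
    conf <- spawn(config$confiscation_share, "confiscation_destruction", 1L)
    rbind(base, emb, conf)
  })

  nt <- records[records$sanction_type == "infraction_notice", ]
  prosecutions <- if (nrow(nt) == 0) empty_prosecutions() else
    with_seed(substream_seed(config$seed, "prosecution"), {
    p1 <- config$prosecution_transition_probs[1]
    p2 <- config$prosecution_transition_probs[2]
    m <- nrow(nt)
    judged <- stats::runif(m) < p1
    paid <- judged & stats::runif(m) < p2
    stage <- ifelse(paid, "paid", ifelse(judged, "judged_first", "filed"))
    lag <- ifelse(paid, 700L, ifelse(judged, 400L, 0L))
    data.frame(
      process_id = nt$process_id,
      filed_date = nt$date,
      stage = stage,
      stage_date = as.character(as.Date(nt$date) + lag),
      amount_paid_brl = ifelse(paid,
                               round(nt$fine_value_brl * stats::runif(m, 0.6, 1), 2),
                               0),
      stringsAsFactors = FALSE)
  })

  money <- with_seed(substream_seed(config$seed, "expenditure"), {
    yrs <- config$years
    y0 <- yrs[1]
    nominal <- 1e8 * 1.05^(yrs - y0) * exp(stats::rnorm(length(yrs), 0, 0.08))
    index <- 1.045^(yrs - y0)
    list(expenditure = data.frame(year = yrs, nominal_brl = round(nominal, 2),
                                  agency = "ibama",
                                  budget_item = "inspection",
                                  stringsAsFactors = FALSE),
         price_index = data.frame(year = yrs, index = index))
  })

  for (w in warn) warning(w, call. = FALSE)
  notice_truth <- cbind(
    record_id = sprintf("N%06d", seq_len(n)),
    notices[, c("year", "true_x", "true_y", "target_patch", "coupled"),
            drop = FALSE])
  structure(list(records = records, prosecutions = prosecutions,
                 expenditure = money$expenditure,
                 price_index = money$price_index,
                 notice_truth = notice_truth, warnings = warn),
            class = "enforcement_bundle")
}

coverage_notices <- function(landscape, config) {
  gt <- landscape$ground_truth
  above <- gt[gt$true_label != "below_mmu", ]
  defo_holdings <- unique(above$holding_id)
  if (length(defo_holdings) == 0) return(empty_notice_draw())
  sel <- defo_holdings[stats::runif(length(defo_holdings)) <
                         config$coverage_fraction]
  if (length(sel) == 0) return(empty_notice_draw())
  rows <- lapply(sel, function(h) {
    ph <- landscape$patches[landscape$patches$holding_id == h &
                              landscape$patches$area_ha >=
                                landscape$rules$mmu_ha, ]
    ph <- ph[order(ph$year), ][1, ]
    data.frame(year = ph$year, x = ph$cx, y = ph$cy,
               true_x = ph$cx, true_y = ph$cy,
               target_patch = ph$patch_id, coupled = TRUE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

empty_notice_draw <- function() {
  data.frame(year = integer(0), x = numeric(0), y = numeric(0),
             true_x = numeric(0), true_y = numeric(0),
             target_patch = character(0), coupled = logical(0),
             stringsAsFactors = FALSE)
}

empty_records <- function() {
  data.frame(record_id = character(0), process_id = character(0),
             date = character(0), state = character(0), theme = character(0),
             sanction_type = character(0), fine_value_brl = numeric(0),
             x = numeric(0), y = numeric(0), stringsAsFactors = FALSE)
}

empty_prosecutions <- function() {
  data.frame(process_id = character(0), filed_date = character(0),
             stage = character(0), stage_date = character(0),
             amount_paid_brl = numeric(0), stringsAsFactors = FALSE)
}

#' @export
print.enforcement_bundle <- function(x, ...) {
  cat(sprintf(paste0(
    "<enforcement_bundle> %d records (%d notices), %d prosecution processes,\n",
    "  expenditure series over %d years\n"),
    nrow(x$records),
    sum(x$records$sanction_type == "infraction_notice"),
    nrow(x$prosecutions), nrow(x$expenditure)))
  invisible(x)
}
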