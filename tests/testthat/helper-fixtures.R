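# Shared fixtures, built in code at test time.

# Small, fast landscape configuration for unit tests.
small_cfg <- function(seed = 7, ...) {
  args <- utils::modifyList(
    list(region_width_m = 20000, region_height_m = 20000, n_holdings = 40,
         patches_per_year = 20, years = 2010:2014, notices_per_year = 40,
         seed = seed),
    list(...))
  do.call(landscape_config, args)
}

# A holdings data.frame with a single square holding of the given side (m),
# in the shape compute_fc_balance()/classify_patches() expect.
square_holding <- function(side = 1000, origin = c(0, 0),
                           id = "H0001", category = "landholding") {
  poly <- rect_sq(origin[1], origin[2], origin[1] + side, origin[2] + side)
  h <- data.frame(holding_id = id, seed_x = origin[1] + side / 2,
                  seed_y = origin[2] + side / 2, category = category,
                  area_ha = side^2 / 1e4, lr_deficit_true = FALSE,
                  stringsAsFactors = FALSE)
  attr(h, "polygons") <- list(poly)
  h
}

rect_sq <- function(xmin, ymin, xmax, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}

# A balances row marking the given holding compliant or not.
balance_row <- function(holdings, compliant = TRUE) {
  data.frame(holding_id = holdings$holding_id,
             area_ha = holdings$area_ha,
             native_fraction = if (compliant) 1 else 0.5,
             lr_requirement = 0.8,
             deficit_ha = if (compliant) 0 else 0.3 * holdings$area_ha,
             app_area_ha = 0, compliant = compliant,
             stringsAsFactors = FALSE)
}

# A rectangular patch row centered at (cx, cy) with the given area (ha) and
# aspect ratio.
patch_row <- function(cx, cy, area_ha, year = 2015, id = "D00001",
                      aspect = 1) {
  w <- sqrt(area_ha * 1e4 * aspect); h <- area_ha * 1e4 / w
  data.frame(patch_id = id, year = year, cx = cx, cy = cy,
             xmin = cx - w / 2, ymin = cy - h / 2,
             xmax = cx + w / 2, ymax = cy + h / 2,
             area_ha = area_ha, stringsAsFactors = FALSE)
}

# Independent brute-force kernel-sum oracle: density at every cell center is
# the direct sum of kernel contributions over all events (no windowing).
brute_force_kde <- function(x, y, grid, h, kernel = "quartic",
                            weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(x))
  cx <- grid$origin[1] + (seq_len(grid$n_cols) - 0.5) * grid$cell_size_m
  cy <- grid$origin[2] + (seq_len(grid$n_rows) - 0.5) * grid$cell_size_m
  out <- matrix(0, grid$n_rows, grid$n_cols)
  sigma <- h / 3
  gnorm <- 1 / (2 * pi * sigma^2 * (1 - exp(-h^2 / (2 * sigma^2))))
  for (r in seq_len(grid$n_rows)) {
    for (cc in seq_len(grid$n_cols)) {
      d2 <- (x - cx[cc])^2 + (y - cy[r])^2
      inside <- d2 <= h^2
      if (!any(inside)) next
      k <- if (kernel == "quartic")
        3 / (pi * h^2) * (1 - d2[inside] / h^2)^2
      else gnorm * exp(-d2[inside] / (2 * sigma^2))
      out[r, cc] <- sum(weights[inside] * k)
    }
  }
  out
}

# Minimal raw-records fixture for ingest tests: 10 rows, 2 exact duplicates,
# 1 out-of-region row.
ingest_fixture <- function() {
  base <- data.frame(
    record_id = sprintf("R%02d", 1:8),
    process_id = sprintf("P%02d", 1:8),
    date = sprintf("2010-0%d-15", rep(1:8, length.out = 8)),
    state = c("PA", "MT", "AM", "RO", "SP", "PA", "MT", "AC"),
    theme = "flora",
    sanction_type = c(rep("infraction_notice", 5), "embargo", "embargo",
                      "confiscation_destruction"),
    fine_value_brl = c(1000, 2000, 1500, 800, 1200, 0, 0, 0),
    x = NA_real_, y = NA_real_, stringsAsFactors = FALSE)
  rbind(base, base[c(1, 3), ])   # 2 exact duplicates
}
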