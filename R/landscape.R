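# Synthetic study region with known ground truth.
#
# The generator emulates the statistical structure of the real inputs of the
# enforcement analysis -- a CAR-like cadastre of landholdings, protected
# areas, a stream network, annual deforestation patches, and enforcement
# records spatially coupled to deforestation -- on one flat projected plane
# in meters. Holdings are Voronoi cells of uniform seed points (gapless,
# non-overlapping cadastre); deforestation patches are axis-aligned
# rectangles with log-normal areas so area bookkeeping stays exact; riparian
# illegality is induced by centering a patch on a stream vertex, legal-reserve
# illegality by pre-clearing a holding's native vegetation below the
# requirement.

#' Configuration for the synthetic landscape generator
#'
#' Defaults define a desk-scale study region: a 50 x 50 km plane with 120
#' holdings, ten years (2009-2018) of 60 deforestation patches per year with
#' log-normal areas (median 20 ha), a target of 80% truly illegal patches
#' (riparian or legal-reserve mechanism), enforcement notices spatially
#' coupled to same-year patches with strength `coupling_rho`, 60% geolocation
#' coverage, and a filed -> judged -> paid prosecution funnel whose product
#' (0.5 x 0.34 = 0.17) matches the historically observed paid-fine ratio.
#'
#' @param region_width_m,region_height_m region dimensions in meters.
#' @param n_holdings number of cadastre holdings (Voronoi cells).
#' @param n_protected number of protected-area rectangles.
#' @param protected_area_fraction fraction of the region covered by
#'   protected areas.
#' @param stream_count number of streams crossing the region.
#' @param years integer vector of years (inclusive range).
#' @param patches_per_year deforestation patches per year.
#' @param patch_area_lognormal_params `c(meanlog, sdlog)` of patch area in ha.
#' @param illegal_fraction_target probability that a patch is generated
#'   through an illegal mechanism.
#' @param app_placement_share share of illegal patches made illegal via
#'   riparian placement (the rest via legal-reserve deficit).
#' @param coupling_rho probability that a notice is placed near a same-year
#'   patch centroid rather than uniformly.
#' @param jitter_sigma_m isotropic jitter (meters) of coupled notices around
#'   the target patch centroid.
#' @param geolocation_prob probability that a record carries coordinates.
#' @param notices_per_year infraction notices issued per year.
#' @param prosecution_transition_probs `c(filed_to_judged, judged_to_paid)`.
#' @param embargo_share,confiscation_share probability that a notice spawns
#'   an embargo / confiscation record on the same process.
#' @param flora_share share of notices with theme "flora".
#' @param cell_size_m native-vegetation raster resolution in meters.
#' @param coverage_fraction optional; when set, notices are instead issued by
#'   selecting each deforesting holding independently with this probability
#'   (one geolocated notice at a contained patch centroid, in the patch
#'   year). Used to study notice coverage recovery.
#' @param seed master RNG seed; every component draws from a named
#'   sub-stream derived from it.
#' @return an object of class `landscape_config`.
#' @export
landscape_config <- function(region_width_m = 50000, region_height_m = 50000,
                             n_holdings = 120, n_protected = 6,
                             protected_area_fraction = 0.15,
                             stream_count = 8,
                             years = 2009:2018, patches_per_year = 60,
                             patch_area_lognormal_params = c(log(20), 1),
                             illegal_fraction_target = 0.8,
                             app_placement_share = 0.4,
                             coupling_rho = 0.7, jitter_sigma_m = 500,
                             geolocation_prob = 0.6, notices_per_year = 100,
                             prosecution_transition_probs = c(0.5, 0.34),
                             embargo_share = 0.35, confiscation_share = 0.2,
                             flora_share = 0.9, cell_size_m = 100,
                             coverage_fraction = NULL, seed = 1L) {
  cfg <- list(region_width_m = region_width_m,
              region_height_m = region_height_m,
              n_holdings = as.integer(n_holdings),
              n_protected = as.integer(n_protected),
              protected_area_fraction = protected_area_fraction,
              stream_count = as.integer(stream_count),
              years = as.integer(years),
              patches_per_year = as.integer(patches_per_year),
              patch_area_lognormal_params = as.numeric(patch_area_lognormal_params),
              illegal_fraction_target = illegal_fraction_target,
              app_placement_share = app_placement_share,
              coupling_rho = coupling_rho,
              jitter_sigma_m = jitter_sigma_m,
              geolocation_prob = geolocation_prob,
              notices_per_year = as.integer(notices_per_year),
              prosecution_transition_probs = as.numeric(prosecution_transition_probs),
              embargo_share = embargo_share,
              confiscation_share = confiscation_share,
              flora_share = flora_share,
              cell_size_m = cell_size_m,
              coverage_fraction = coverage_fraction,
              seed = as.integer(seed))
  validate_landscape_config(cfg)
  structure(cfg, class = "landscape_config")
}

validate_landscape_config <- function(cfg) {
  fr <- c("protected_area_fraction", "illegal_fraction_target",
          "app_placement_share", "coupling_rho", "geolocation_prob",
          "embargo_share", "confiscation_share", "flora_share")
  for (f in fr) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop(sprintf("%s must be a fraction in [0, 1]", f), call. = FALSE)
  }
  if (any(cfg$prosecution_transition_probs < 0) ||
      any(cfg$prosecution_transition_probs > 1) ||
      length(cfg$prosecution_transition_probs) != 2)
    stop("prosecution_transition_probs must be two fractions in [0, 1]",
         call. = FALSE)
  cnt <- c("n_holdings", "n_protected", "stream_count", "patches_per_year",
           "notices_per_year")
  for (f in cnt) if (cfg[[f]] < 0)
    stop(sprintf("%s must be >= 0", f), call. = FALSE)
  if (cfg$region_width_m <= 0 || cfg$region_height_m <= 0)
    stop("region dimensions must be > 0", call. = FALSE)
  if (length(cfg$years) == 0)
    stop("year range must be non-empty", call. = FALSE)
  if (!is.null(cfg$coverage_fraction) &&
      (cfg$coverage_fraction < 0 || cfg$coverage_fraction > 1))
    stop("coverage_fraction must be in [0, 1]", call. = FALSE)
  invisible(cfg)
}

#' @export
print.landscape_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<landscape_config> %g x %g km, %d holdings, %d years x %d patches,\n",
    "  illegal target %.2f (APP share %.2f), coupling %.2f, seed %d\n"),
    x$region_width_m / 1000, x$region_height_m / 1000, x$n_holdings,
    length(x$years), x$patches_per_year, x$illegal_fraction_target,
    x$app_placement_share, x$coupling_rho, x$seed))
  invisible(x)
}

# ---------------------------------------------------------------------------

#' Generate a synthetic study landscape
#'
#' Produces the full vector + raster scene with per-patch ground truth:
#' Voronoi holdings clipped to the region, disjoint protected-area
#' rectangles, streams crossing the region west to east, a native-vegetation
#' raster in which a subset of holdings is pre-cleared below the
#' legal-reserve requirement, and `length(years) * patches_per_year`
#' deforestation patches. Each patch is drawn through one of three placement
#' mechanisms (riparian, legal-reserve deficit, legal) and its true legality
#' label follows from the mechanism plus the minimum-mapping-unit rule.
#'
#' @param config a [landscape_config()].
#' @param rules a [rule_config()]; the generator shares the legality rule
#'   parameters (MMU, LR requirement, APP buffer) with the classifier so
#'   ground truth and classification are commensurable.
#' @return an object of class `synthetic_landscape`: list with `holdings`
#'   (data.frame + `polygons` attribute), `protected_areas`, `streams`,
#'   `patches`, `native_map` (matrix), `grid`, `ground_truth`, `config`,
#'   `rules`.
#' @export
generate_landscape <- function(config, rules = rule_config()) {
  validate_landscape_config(config)
  W <- config$region_width_m; H <- config$region_height_m
  lr_share <- 1 - config$app_placement_share
  if (config$illegal_fraction_target > 0 && config$stream_count == 0 &&
      lr_share <= 0)
    stop(paste("illegal_fraction_target > 0 but there are no streams and",
               "the LR-deficit share is 0: illegality is unachievable"),
         call. = FALSE)

  # -- holdings: Voronoi tessellation of uniform seed points ----------------
  hold <- with_seed(substream_seed(config$seed, "holdings"), {
    sx <- stats::runif(config$n_holdings, 0, W)
    sy <- stats::runif(config$n_holdings, 0, H)
    cat_draw <- sample(c("landholding", "settlement", "traditional_community"),
                       config$n_holdings, replace = TRUE,
                       prob = c(0.85, 0.10, 0.05))
    list(sx = sx, sy = sy, category = cat_draw)
  })
  polys <- voronoi_cells(hold$sx, hold$sy, W, H)
  holdings <- data.frame(
    holding_id = sprintf("H%04d", seq_len(config$n_holdings)),
    seed_x = hold$sx, seed_y = hold$sy,
    category = hold$category,
    area_ha = vapply(polys, polygon_area_ha, 0),
    stringsAsFactors = FALSE)
  attr(holdings, "polygons") <- polys

  # -- protected areas: disjoint rectangles ---------------------------------
  protected <- with_seed(substream_seed(config$seed, "protected"), {
    target_total <- config$protected_area_fraction * W * H
    n <- config$n_protected
    out <- data.frame(pa_id = character(0), pa_class = character(0),
                      xmin = numeric(0), ymin = numeric(0),
                      xmax = numeric(0), ymax = numeric(0))
    if (n > 0) {
      per <- target_total / n
      placed <- list()
      for (i in seq_len(n)) {
        a <- per * stats::runif(1, 0.7, 1.3)
        ok <- FALSE
        for (try in 1:300) {
          ar <- stats::runif(1, 1, 2)
          w <- sqrt(a * ar); h <- a / w
          if (w > W || h > H) { a <- a * 0.8; next }
          x0 <- stats::runif(1, 0, W - w); y0 <- stats::runif(1, 0, H - h)
          cand <- c(x0, y0, x0 + w, y0 + h)
          clash <- any(vapply(placed, function(p) bbox_overlap(p, cand), TRUE))
          if (!clash) { placed[[length(placed) + 1]] <- cand; ok <- TRUE; break }
          if (try %% 100 == 0) a <- a * 0.8
        }
        if (!ok) next
      }
      if (length(placed)) {
        m <- do.call(rbind, placed)
        out <- data.frame(
          pa_id = sprintf("PA%02d", seq_len(nrow(m))),
          pa_class = rep(c("indigenous_land", "conservation_unit"),
                         length.out = nrow(m)),
          xmin = m[, 1], ymin = m[, 2], xmax = m[, 3], ymax = m[, 4],
          stringsAsFactors = FALSE)
      }
    }
    out
  })

  # -- streams: west-east random-walk polylines -----------------------------
  streams <- with_seed(substream_seed(config$seed, "streams"), {
    if (config$stream_count == 0) {
      data.frame(stream_id = character(0), x = numeric(0), y = numeric(0))
    } else {
      step <- 1000
      xs <- seq(0, W, by = step)
      do.call(rbind, lapply(seq_len(config$stream_count), function(s) {
        y0 <- stats::runif(1, 0.1 * H, 0.9 * H)
        ys <- y0 + cumsum(c(0, stats::rnorm(length(xs) - 1, 0, 400)))
        ys <- pmin(pmax(ys, 0), H)
        data.frame(stream_id = sprintf("S%02d", s), x = xs, y = ys,
                   stringsAsFactors = FALSE)
      }))
    }
  })
  segs <- stream_segments(streams)

  # -- native map and LR-deficit holdings -----------------------------------
  grid <- grid_spec(c(0, 0), config$cell_size_m,
                    ceiling(W / config$cell_size_m),
                    ceiling(H / config$cell_size_m))
  cellsets <- lapply(polys, cells_in_poly, grid = grid)
  native <- matrix(1, grid$n_rows, grid$n_cols)
  deficit_info <- with_seed(substream_seed(config$seed, "native"), {
    n_def <- max(3L, round(0.25 * config$n_holdings))
    n_def <- min(n_def, config$n_holdings)
    deficit_ids <- sample(seq_len(config$n_holdings), n_def)
    is_deficit <- seq_len(config$n_holdings) %in% deficit_ids
    for (i in seq_len(config$n_holdings)) {
      cs <- cellsets[[i]]
      ncell <- nrow(cs)
      if (ncell == 0) next
      target <- if (is_deficit[i]) stats::runif(1, 0.5, 0.7)
                else 1 - stats::runif(1, 0, 0.05)
      n_clear <- round((1 - target) * ncell)
      if (n_clear > 0) {
        pick <- sample(ncell, n_clear)
        native[cs[pick, , drop = FALSE]] <- 0
      }
    }
    is_deficit
  })
  holdings$lr_deficit_true <- deficit_info

  # -- deforestation patches ------------------------------------------------
  patches <- with_seed(substream_seed(config$seed, "patches"), {
    place_patches(config, rules, holdings, polys, streams, segs, W, H)
  })

  gt <- patches[, c("patch_id", "year", "mechanism", "designated_illegal",
                    "holding_id", "true_label", "true_reason")]
  ls <- structure(list(holdings = holdings, protected_areas = protected,
                       streams = streams, patches = patches,
                       native_map = native, grid = grid,
                       ground_truth = gt, config = config, rules = rules),
                  class = "synthetic_landscape")
  ls
}

stream_segments <- function(streams) {
  if (nrow(streams) == 0)
    return(matrix(numeric(0), 0, 4,
                  dimnames = list(NULL, c("ax", "ay", "bx", "by"))))
  pieces <- lapply(split(streams, streams$stream_id), function(s) {
    n <- nrow(s)
    cbind(ax = s$x[-n], ay = s$y[-n], bx = s$x[-1], by = s$y[-1])
  })
  do.call(rbind, pieces)
}

# Draw and place all patches; runs inside the "patches" sub-stream.
place_patches <- function(config, rules, holdings, polys, streams, segs, W, H) {
  mu <- config$patch_area_lognormal_params[1]
  sigma <- config$patch_area_lognormal_params[2]
  buffer <- rules$app_buffer_m
  margin <- 50
  deficit_idx <- which(holdings$lr_deficit_true)
  compliant_idx <- which(!holdings$lr_deficit_true)
  vert_ok <- nrow(streams) > 0
  n_total <- length(config$years) * config$patches_per_year
  rows <- vector("list", n_total)
  k <- 0L
  for (year in config$years) {
    for (p in seq_len(config$patches_per_year)) {
      k <- k + 1L
      illegal <- stats::runif(1) < config$illegal_fraction_target
      mech <- if (!illegal) "legal"
              else if (vert_ok && stats::runif(1) < config$app_placement_share) "app"
              else "deficit"
      if (mech == "deficit" && length(deficit_idx) == 0) mech <- "app"
      placed <- NULL
      for (try in 1:400) {
        area_ha <- min(stats::rlnorm(1, mu, sigma), 500)
        ar <- stats::runif(1, 1, 3)
        w <- sqrt(area_ha * 1e4 * ar); h <- area_ha * 1e4 / w
        hw <- w / 2; hh <- h / 2
        if (mech == "app") {
          cand <- streams[streams$x >= hw & streams$x <= W - hw &
                          streams$y >= hh & streams$y <= H - hh, ]
          if (nrow(cand) == 0) next
          v <- cand[sample(nrow(cand), 1), ]
          cx <- v$x + stats::runif(1, -hw / 2, hw / 2)
          cy <- v$y + stats::runif(1, -hh / 2, hh / 2)
          if (cx - hw < 0 || cx + hw > W || cy - hh < 0 || cy + hh > H) next
          placed <- c(cx, cy, hw, hh, area_ha)
          break
        }
        idx_pool <- if (mech == "deficit") deficit_idx else compliant_idx
        hi <- idx_pool[sample(length(idx_pool), 1)]
        poly <- polys[[hi]]
        bb <- poly_bbox(poly)
        if (bb[3] - bb[1] < w || bb[4] - bb[2] < h) next
        cx <- stats::runif(1, bb[1] + hw, bb[3] - hw)
        cy <- stats::runif(1, bb[2] + hh, bb[4] - hh)
        corners_x <- c(cx - hw, cx + hw, cx + hw, cx - hw)
        corners_y <- c(cy - hh, cy - hh, cy + hh, cy + hh)
        if (!all(points_in_poly(corners_x, corners_y, poly))) next
        if (nrow(segs) > 0) {
          halfdiag <- sqrt(hw^2 + hh^2)
          d <- min_dist_point_segs(cx, cy, segs)
          if (d <= buffer + halfdiag + margin) next
        }
        placed <- c(cx, cy, hw, hh, area_ha)
        attr(placed, "holding") <- hi
        break
      }
      if (is.null(placed))
        stop("patch placement failed; region too crowded for the configured ",
             "patch sizes", call. = FALSE)
      hi <- attr(placed, "holding")
      if (is.null(hi)) {
        # riparian patches may straddle holdings; assign by the center's cell
        d2 <- (holdings$seed_x - placed[1])^2 + (holdings$seed_y - placed[2])^2
        hi <- which.min(d2)
      }
      rows[[k]] <- data.frame(
        patch_id = sprintf("D%05d", k), year = year,
        cx = placed[1], cy = placed[2],
        xmin = placed[1] - placed[3], ymin = placed[2] - placed[4],
        xmax = placed[1] + placed[3], ymax = placed[2] + placed[4],
        area_ha = placed[5], mechanism = mech,
        designated_illegal = mech != "legal",
        holding_id = holdings$holding_id[hi],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$true_label <- ifelse(out$area_ha < rules$mmu_ha, "below_mmu",
                    ifelse(out$mechanism == "app", "potentially_illegal",
                    ifelse(out$mechanism == "deficit", "potentially_illegal",
                           "presumed_legal")))
  out$true_reason <- ifelse(out$true_label != "potentially_illegal", "none",
                     ifelse(out$mechanism == "app", "riparian_app",
                            "lr_deficit"))
  out
}

#' @export
print.synthetic_landscape <- function(x, ...) {
  cat(sprintf(paste0(
    "<synthetic_landscape> %g x %g km, %d holdings (%d LR-deficit),\n",
    "  %d protected areas, %d streams, %d patches over %d years ",
    "(%.1f%% truly illegal)\n"),
    x$config$region_width_m / 1000, x$config$region_height_m / 1000,
    nrow(x$holdings), sum(x$holdings$lr_deficit_true),
    nrow(x$protected_areas), length(unique(x$streams$stream_id)),
    nrow(x$patches), length(x$config$years),
    100 * mean(x$patches$designated_illegal)))
  invisible(x)
}
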