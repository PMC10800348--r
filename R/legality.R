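# Forest Code balance and potentially-illegal-deforestation classification.
#
# Two legal rules are applied, mirroring what enforcement practice can test
# at scale: clearing inside a Riparian Preservation Area (APP, a buffer
# strip along streams), and clearing on a holding whose native vegetation
# is below the Legal Reserve requirement (80% in the Legal Amazon forest
# zone). Patches below the minimum mapping unit (6.25 ha, the effective
# resolution of annual deforestation mapping) are excluded from the
# statistics.

#' Legality rule parameters
#'
#' @param mmu_ha minimum mapping unit in hectares; smaller patches are not
#'   counted (default 6.25, the effective resolution of the annual
#'   deforestation maps).
#' @param lr_requirement Legal Reserve requirement as a fraction of holding
#'   area (default 0.80).
#' @param overlap_threshold protected-area overlap fraction above which a
#'   holding is flagged (strictly greater; default 0.25).
#' @param app_buffer_m riparian buffer half-width in meters (default 30).
#' @return an object of class `rule_config`.
#' @export
rule_config <- function(mmu_ha = 6.25, lr_requirement = 0.80,
                        overlap_threshold = 0.25, app_buffer_m = 30) {
  if (mmu_ha <= 0 || app_buffer_m <= 0)
    stop("thresholds must be > 0", call. = FALSE)
  if (lr_requirement <= 0 || lr_requirement >= 1 ||
      overlap_threshold <= 0 || overlap_threshold >= 1)
    stop("fractions must be in (0, 1)", call. = FALSE)
  structure(list(mmu_ha = mmu_ha, lr_requirement = lr_requirement,
                 overlap_threshold = overlap_threshold,
                 app_buffer_m = app_buffer_m),
            class = "rule_config")
}

#' Riparian preservation (APP) zones from a stream network
#'
#' The APP zone is the union of buffers of half-width `app_buffer_m` around
#' every stream segment. The zone is kept in implicit form (segments +
#' width); membership and intersection tests are exact, area is measured by
#' grid sampling.
#'
#' @param streams data.frame with `stream_id`, `x`, `y` (ordered vertices).
#' @param rules a [rule_config()].
#' @return an object of class `app_zones`.
#' @export
derive_app_zones <- function(streams, rules = rule_config()) {
  if (rules$app_buffer_m <= 0)
    stop("nonpositive buffer width", call. = FALSE)
  segs <- stream_segments(streams)
  structure(list(segments = segs, width = rules$app_buffer_m),
            class = "app_zones")
}

#' @export
print.app_zones <- function(x, ...) {
  cat(sprintf("<app_zones> %d stream segments, buffer half-width %g m\n",
              nrow(x$segments), x$width))
  invisible(x)
}

# TRUE where points fall inside the APP union.
points_in_app <- function(px, py, app) {
  if (nrow(app$segments) == 0) return(rep(FALSE, length(px)))
  min_dist_point_segs(px, py, app$segments) <= app$width
}

# Does an axis-aligned rectangle c(xmin, ymin, xmax, ymax) intersect the APP?
rect_intersects_app <- function(rect, app) {
  segs <- app$segments
  if (nrow(segs) == 0) return(FALSE)
  grown <- c(rect[1] - app$width, rect[2] - app$width,
             rect[3] + app$width, rect[4] + app$width)
  for (k in seq_len(nrow(segs))) {
    sb <- c(min(segs[k, 1], segs[k, 3]), min(segs[k, 2], segs[k, 4]),
            max(segs[k, 1], segs[k, 3]), max(segs[k, 2], segs[k, 4]))
    if (!bbox_overlap(sb, grown)) next
    if (seg_rect_dist(segs[k, 1], segs[k, 2], segs[k, 3], segs[k, 4],
                      rect) <= app$width)
      return(TRUE)
  }
  FALSE
}

#' Area of the APP union in hectares
#'
#' Measured by regular grid sampling over the buffered bounding box of the
#' stream network (union handled naturally: a point is counted once however
#' many buffers cover it).
#'
#' @param app an [derive_app_zones()] result.
#' @param cell_m sampling cell size in meters (discretization error scales
#'   with `cell_m` / buffer width).
#' @return area in hectares.
#' @export
app_zone_area_ha <- function(app, cell_m = 5) {
  segs <- app$segments
  if (nrow(segs) == 0) return(0)
  bb <- c(min(segs[, c(1, 3)]), min(segs[, c(2, 4)]),
          max(segs[, c(1, 3)]), max(segs[, c(2, 4)])) +
    c(-1, -1, 1, 1) * (app$width + cell_m)
  xs <- seq(bb[1] + cell_m / 2, bb[3], by = cell_m)
  ys <- seq(bb[2] + cell_m / 2, bb[4], by = cell_m)
  total <- 0
  # row-block the sampling to bound memory
  for (y in ys) {
    inside <- points_in_app(xs, rep(y, length(xs)), app)
    total <- total + sum(inside)
  }
  total * cell_m^2 / 1e4
}

#' Forest Code balance per holding
#'
#' `native_fraction` is the share of the holding's raster cells (cell-center
#' rule) that are native vegetation; the deficit is
#' `max(0, lr_requirement - native_fraction) * area_ha` and a holding is
#' compliant iff its deficit is zero.
#'
#' @param holdings holdings data.frame with a `polygons` attribute (as
#'   produced by [generate_landscape()]).
#' @param native_map binary matrix (1 = native, 0 = cleared) on `grid`.
#' @param grid the [grid_spec()] of `native_map`.
#' @param rules a [rule_config()].
#' @param app optional [derive_app_zones()] result; when given, the
#'   holding's APP area is reported.
#' @return data.frame of class `fc_balance` with one row per holding.
#' @export
compute_fc_balance <- function(holdings, native_map, grid,
                               rules = rule_config(), app = NULL) {
  polys <- attr(holdings, "polygons")
  n <- nrow(holdings)
  native_fraction <- rep(NA_real_, n)
  app_area <- rep(0, n)
  for (i in seq_len(n)) {
    cs <- cells_in_poly(polys[[i]], grid)
    if (nrow(cs) == 0)
      stop("holding ", holdings$holding_id[i],
           " has no raster coverage", call. = FALSE)
    native_fraction[i] <- mean(native_map[cs] == 1)
    if (!is.null(app) && nrow(app$segments) > 0) {
      px <- grid$origin[1] + (cs[, "col"] - 0.5) * grid$cell_size_m
      py <- grid$origin[2] + (cs[, "row"] - 0.5) * grid$cell_size_m
      app_area[i] <- sum(points_in_app(px, py, app)) *
        grid$cell_size_m^2 / 1e4
    }
  }
  deficit <- pmax(0, rules$lr_requirement - native_fraction) * holdings$area_ha
  out <- data.frame(holding_id = holdings$holding_id,
                    area_ha = holdings$area_ha,
                    native_fraction = native_fraction,
                    lr_requirement = rules$lr_requirement,
                    deficit_ha = deficit,
                    app_area_ha = app_area,
                    compliant = deficit == 0,
                    stringsAsFactors = FALSE)
  class(out) <- c("fc_balance", "data.frame")
  out
}

#' Classify deforestation patches as potentially illegal
#'
#' Decision rule per patch: area below the minimum mapping unit ->
#' `below_mmu`; else intersecting the APP zone -> `potentially_illegal`
#' with reason `riparian_app`; else on a non-compliant (Legal Reserve
#' deficit) holding -> `potentially_illegal` with reason `lr_deficit`; else
#' `presumed_legal`. The riparian reason takes precedence when both apply.
#' Patches are assigned to the holding with the largest area overlap
#' (representative-point fallback for slivers).
#'
#' @param patches data.frame with `patch_id`, `year`, `xmin`, `ymin`,
#'   `xmax`, `ymax`, `area_ha`.
#' @param holdings holdings data.frame with `polygons` attribute.
#' @param balances a [compute_fc_balance()] result.
#' @param app an [derive_app_zones()] result.
#' @param rules a [rule_config()].
#' @return data.frame of class `legality_labels`: `patch_id`, `year`,
#'   `holding_id`, `label`, `reason`, `area_ha`.
#' @export
classify_patches <- function(patches, holdings, balances, app,
                             rules = rule_config()) {
  polys <- attr(holdings, "polygons")
  bboxes <- lapply(polys, poly_bbox)
  compliant <- stats::setNames(balances$compliant, balances$holding_id)
  n <- nrow(patches)
  holding_id <- character(n)
  label <- character(n)
  reason <- character(n)
  for (i in seq_len(n)) {
    rect <- c(patches$xmin[i], patches$ymin[i],
              patches$xmax[i], patches$ymax[i])
    rp <- rect_poly(rect[1], rect[2], rect[3], rect[4])
    # largest-overlap holding assignment among bbox candidates
    best <- NA_integer_; best_a <- -1
    for (j in seq_along(polys)) {
      if (!bbox_overlap(bboxes[[j]], rect)) next
      a <- polygon_area(clip_convex(rp, polys[[j]]))
      if (a > best_a) { best_a <- a; best <- j }
    }
    if (is.na(best) || best_a <= 0) {
      # sliver fallback: holding containing the representative point
      cx <- (rect[1] + rect[3]) / 2; cy <- (rect[2] + rect[4]) / 2
      for (j in seq_along(polys)) {
        if (points_in_poly(cx, cy, polys[[j]])) { best <- j; break }
      }
    }
    holding_id[i] <- if (is.na(best)) NA_character_ else
      holdings$holding_id[best]
    if (patches$area_ha[i] < rules$mmu_ha) {
      label[i] <- "below_mmu"; reason[i] <- "none"
    } else if (rect_intersects_app(rect, app)) {
      label[i] <- "potentially_illegal"; reason[i] <- "riparian_app"
    } else if (!is.na(holding_id[i]) && !isTRUE(compliant[holding_id[i]])) {
      label[i] <- "potentially_illegal"; reason[i] <- "lr_deficit"
    } else {
      label[i] <- "presumed_legal"; reason[i] <- "none"
    }
  }
  out <- data.frame(patch_id = patches$patch_id, year = patches$year,
                    holding_id = holding_id, label = label, reason = reason,
                    area_ha = patches$area_ha, stringsAsFactors = FALSE)
  class(out) <- c("legality_labels", "data.frame")
  out
}

#' Attribute geolocated notices to holdings and deforestation
#'
#' A notice links to the holding whose polygon contains its point. The link
#' is deforestation-related when the holding contains at least one patch
#' with `patch.year <= notice year` -- only notices applied after
#' deforestation took place are treated as related to it.
#'
#' @param notices record data.frame with `record_id`, `date` (or `year`),
#'   `x`, `y`.
#' @param patches patch data.frame with `holding_id`, `year`, `area_ha`.
#' @param holdings holdings data.frame with `polygons` attribute.
#' @param rules a [rule_config()]; only above-MMU patches count as
#'   deforestation for the temporal link.
#' @return data.frame `attribution`: per notice `record_id`, `year`,
#'   `holding_id` (NA when unlinked), `deforestation_related`.
#' @export
attribute_notices <- function(notices, patches, holdings,
                              rules = rule_config()) {
  polys <- attr(holdings, "polygons")
  if (!"year" %in% names(notices))
    notices$year <- as.integer(substr(notices$date, 1, 4))
  geo <- !is.na(notices$x) & !is.na(notices$y)
  n <- nrow(notices)
  holding_id <- rep(NA_character_, n)
  for (j in seq_along(polys)) {
    if (!any(geo)) break
    unres <- geo & is.na(holding_id)
    if (!any(unres)) break
    hit <- points_in_poly(notices$x[unres], notices$y[unres], polys[[j]])
    holding_id[which(unres)[hit]] <- holdings$holding_id[j]
  }
  pat <- patches[patches$area_ha >= rules$mmu_ha, , drop = FALSE]
  first_year <- tapply(pat$year, pat$holding_id, min)
  related <- !is.na(holding_id) &
    !is.na(first_year[holding_id]) &
    notices$year >= as.integer(first_year[holding_id])
  data.frame(record_id = notices$record_id, year = notices$year,
             holding_id = holding_id,
             deforestation_related = as.logical(related),
             stringsAsFactors = FALSE)
}

#' Protected-area overlap fraction and land-grabbing flag per holding
#'
#' Overlap fraction = area(holding intersected with the union of protected
#' areas) / area(holding); a holding is flagged when the fraction strictly
#' exceeds `overlap_threshold`. Protected areas are assumed mutually
#' disjoint rectangles (as generated), so the union area is a sum of exact
#' convex clips.
#'
#' @param holdings holdings data.frame with `polygons` attribute.
#' @param protected_areas data.frame with `xmin`, `ymin`, `xmax`, `ymax`.
#' @param rules a [rule_config()].
#' @return data.frame `holding_id`, `overlap_fraction`, `flagged`.
#' @export
protected_overlap_flags <- function(holdings, protected_areas,
                                    rules = rule_config()) {
  polys <- attr(holdings, "polygons")
  n <- nrow(holdings)
  frac <- numeric(n)
  for (i in seq_len(n)) {
    a_hold <- polygon_area(polys[[i]])
    if (a_hold <= 0) { frac[i] <- 0; next }
    a_pa <- 0
    for (k in seq_len(nrow(protected_areas))) {
      rp <- rect_poly(protected_areas$xmin[k], protected_areas$ymin[k],
                      protected_areas$xmax[k], protected_areas$ymax[k])
      a_pa <- a_pa + polygon_area(clip_convex(polys[[i]], rp))
    }
    frac[i] <- min(1, a_pa / a_hold)
  }
  data.frame(holding_id = holdings$holding_id, overlap_fraction = frac,
             flagged = frac > rules$overlap_threshold,
             stringsAsFactors = FALSE)
}

#' Annual deforestation area per land category
#'
#' Apportions each patch's area to land categories by intersection with
#' precedence indigenous land > conservation unit > settlement /
#' traditional community > landholding > undesignated, so overlapping
#' claims are not double counted. Each patch is sampled on a regular
#' subgrid; every sample point is assigned to exactly one category, so
#' per-year totals conserve total patch area.
#'
#' @param patches patch data.frame with `year`, `xmin`, `ymin`, `xmax`,
#'   `ymax`, `area_ha`.
#' @param holdings holdings data.frame with `polygons` attribute and
#'   `category`.
#' @param protected_areas data.frame with `pa_class`, `xmin`, `ymin`,
#'   `xmax`, `ymax`.
#' @param n_sample subgrid resolution per patch side.
#' @return data.frame with one row per year and one column per category
#'   (areas in ha), plus `total_ha`.
#' @export
land_category_breakdown <- function(patches, holdings, protected_areas,
                                    n_sample = 40L) {
  cats <- c("indigenous_land", "conservation_unit", "settlement",
            "traditional_community", "landholding", "undesignated")
  polys <- attr(holdings, "polygons")
  bboxes <- lapply(polys, poly_bbox)
  years <- sort(unique(patches$year))
  acc <- matrix(0, length(years), length(cats),
                dimnames = list(NULL, cats))
  for (i in seq_len(nrow(patches))) {
    rect <- c(patches$xmin[i], patches$ymin[i],
              patches$xmax[i], patches$ymax[i])
    gx <- seq(rect[1], rect[3], length.out = n_sample + 1)
    gy <- seq(rect[2], rect[4], length.out = n_sample + 1)
    px <- rep((gx[-1] + gx[-length(gx)]) / 2, times = n_sample)
    py <- rep((gy[-1] + gy[-length(gy)]) / 2, each = n_sample)
    cat_pt <- rep("undesignated", length(px))
    # landholding layer (candidates by bbox)
    unassigned <- rep(TRUE, length(px))
    for (j in seq_along(polys)) {
      if (!bbox_overlap(bboxes[[j]], rect)) next
      if (!any(unassigned)) break
      hit <- unassigned &
        points_in_poly(px, py, polys[[j]])
      cat_pt[hit] <- holdings$category[j]
      unassigned <- unassigned & !hit
    }
    # protected areas take precedence over everything
    for (k in seq_len(nrow(protected_areas))) {
      hit <- px >= protected_areas$xmin[k] & px <= protected_areas$xmax[k] &
             py >= protected_areas$ymin[k] & py <= protected_areas$ymax[k]
      cat_pt[hit] <- protected_areas$pa_class[k]
    }
    w <- patches$area_ha[i] / length(px)
    yi <- match(patches$year[i], years)
    tab <- table(factor(cat_pt, levels = cats))
    acc[yi, ] <- acc[yi, ] + as.numeric(tab) * w
  }
  out <- data.frame(year = years, acc, total_ha = rowSums(acc))
  out
}

#' Annual illegality-with-enforcement series
#'
#' Two statistics per year: the areal share of potentially illegal
#' deforestation that received an infraction notice (a patch counts as
#' noticed when its holding has a deforestation-related notice dated in or
#' after the patch year), and the share of deforesting holdings (>= 1
#' above-MMU patch that year) with a deforestation-related notice. Pooled
#' whole-period shares are attached as the `"overall"` attribute.
#'
#' @param labels a [classify_patches()] result.
#' @param attribution an [attribute_notices()] result.
#' @return data.frame of class `illegality_series` with columns `year`,
#'   `illegal_area_ha`, `noticed_illegal_area_ha`, `pct_illegal_area_noticed`,
#'   `n_deforesting_holdings`, `n_noticed_holdings`,
#'   `pct_holdings_noticed`.
#' @export
illegality_enforcement_series <- function(labels, attribution) {
  rel <- attribution[attribution$deforestation_related %in% TRUE, , drop = FALSE]
  years <- sort(unique(labels$year))
  rows <- lapply(years, function(y) {
    ly <- labels[labels$year == y, , drop = FALSE]
    ill <- ly[ly$label == "potentially_illegal", , drop = FALSE]
    noticed_patch <- vapply(seq_len(nrow(ill)), function(i) {
      any(rel$holding_id == ill$holding_id[i] & rel$year >= ill$year[i],
          na.rm = TRUE)
    }, TRUE)
    ill_area <- sum(ill$area_ha)
    defo_h <- unique(ly$holding_id[ly$label != "below_mmu" &
                                     !is.na(ly$holding_id)])
    noticed_h <- vapply(defo_h, function(h) {
      any(rel$holding_id == h & rel$year >= y, na.rm = TRUE)
    }, TRUE)
    data.frame(
      year = y,
      illegal_area_ha = ill_area,
      noticed_illegal_area_ha = sum(ill$area_ha[noticed_patch]),
      pct_illegal_area_noticed = if (ill_area > 0)
        100 * sum(ill$area_ha[noticed_patch]) / ill_area else NA_real_,
      n_deforesting_holdings = length(defo_h),
      n_noticed_holdings = sum(noticed_h),
      pct_holdings_noticed = if (length(defo_h) > 0)
        100 * mean(noticed_h) else NA_real_)
  })
  out <- do.call(rbind, rows)
  # pooled over the whole window: holdings that ever deforested vs ever
  # received a related notice; illegal area likewise pooled
  ill_all <- labels[labels$label == "potentially_illegal", , drop = FALSE]
  noticed_all <- vapply(seq_len(nrow(ill_all)), function(i) {
    any(rel$holding_id == ill_all$holding_id[i] &
          rel$year >= ill_all$year[i], na.rm = TRUE)
  }, TRUE)
  defo_h <- unique(labels$holding_id[labels$label != "below_mmu" &
                                       !is.na(labels$holding_id)])
  noticed_h <- vapply(defo_h, function(h)
    any(rel$holding_id == h, na.rm = TRUE), TRUE)
  attr(out, "overall") <- list(
    pct_illegal_area_noticed = if (nrow(ill_all) > 0)
      100 * sum(ill_all$area_ha[noticed_all]) / sum(ill_all$area_ha)
      else NA_real_,
    n_deforesting_holdings = length(defo_h),
    n_noticed_holdings = sum(noticed_h),
    pct_holdings_noticed = if (length(defo_h) > 0) 100 * mean(noticed_h)
      else NA_real_)
  class(out) <- c("illegality_series", "data.frame")
  out
}
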