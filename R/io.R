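# Plain-text I/O: GeoJSON for vector layers, ESRI ASCII grid for rasters,
# CSV for tabular records. One documented CSV schema is supported for
# enforcement records (see REQUIRED_RECORD_COLS).

geojson_feature <- function(geometry, properties) {
  list(type = "Feature", properties = properties, geometry = geometry)
}

geom_polygon <- function(poly) {
  ring <- rbind(poly, poly[1, , drop = FALSE])
  list(type = "Polygon",
       coordinates = list(lapply(seq_len(nrow(ring)),
                                 function(i) as.numeric(ring[i, ]))))
}

geom_linestring <- function(xy) {
  list(type = "LineString",
       coordinates = lapply(seq_len(nrow(xy)),
                            function(i) as.numeric(xy[i, ])))
}

write_geojson <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 8,
                       null = "null", na = "null")
  invisible(path)
}

#' Write a synthetic landscape to a directory
#'
#' Emits `holdings.geojson`, `protected_areas.geojson`, `streams.geojson`,
#' `patches.geojson`, `native_map.asc` (ESRI ASCII grid, 1 = native,
#' 0 = cleared) and `ground_truth.csv`. Coordinates are planar meters.
#'
#' @param landscape a [generate_landscape()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  h <- landscape$holdings
  polys <- attr(h, "polygons")
  write_geojson(lapply(seq_len(nrow(h)), function(i)
    geojson_feature(geom_polygon(polys[[i]]),
                    list(holding_id = h$holding_id[i],
                         category = h$category[i],
                         area_ha = h$area_ha[i],
                         seed_x = h$seed_x[i], seed_y = h$seed_y[i],
                         lr_deficit_true = h$lr_deficit_true[i]))),
    file.path(dir, "holdings.geojson"))
  pa <- landscape$protected_areas
  write_geojson(lapply(seq_len(nrow(pa)), function(i)
    geojson_feature(geom_polygon(rect_poly(pa$xmin[i], pa$ymin[i],
                                           pa$xmax[i], pa$ymax[i])),
                    list(pa_id = pa$pa_id[i], pa_class = pa$pa_class[i]))),
    file.path(dir, "protected_areas.geojson"))
  st <- split(landscape$streams, landscape$streams$stream_id)
  write_geojson(lapply(st, function(s)
    geojson_feature(geom_linestring(cbind(s$x, s$y)),
                    list(stream_id = s$stream_id[1]))),
    file.path(dir, "streams.geojson"))
  p <- landscape$patches
  write_geojson(lapply(seq_len(nrow(p)), function(i)
    geojson_feature(geom_polygon(rect_poly(p$xmin[i], p$ymin[i],
                                           p$xmax[i], p$ymax[i])),
                    list(patch_id = p$patch_id[i], year = p$year[i],
                         area_ha = p$area_ha[i],
                         holding_id = p$holding_id[i]))),
    file.path(dir, "patches.geojson"))
  write_ascii_grid(landscape$native_map, landscape$grid,
                   file.path(dir, "native_map.asc"))
  utils::write.csv(landscape$ground_truth,
                   file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(dir)
}

read_geojson_features <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)$features
}

#' Read a landscape bundle written by [write_landscape()]
#'
#' @param dir directory containing the bundle.
#' @return a list with `holdings` (+ `polygons` attribute),
#'   `protected_areas`, `streams`, `patches`, `native_map`, `grid`,
#'   `ground_truth`.
#' @export
read_landscape <- function(dir) {
  hf <- read_geojson_features(file.path(dir, "holdings.geojson"))
  polys <- lapply(hf, function(f) {
    m <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    m[-nrow(m), , drop = FALSE]
  })
  holdings <- do.call(rbind, lapply(hf, function(f)
    data.frame(f$properties, stringsAsFactors = FALSE)))
  attr(holdings, "polygons") <- polys
  paf <- read_geojson_features(file.path(dir, "protected_areas.geojson"))
  protected <- if (length(paf)) do.call(rbind, lapply(paf, function(f) {
    m <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    data.frame(pa_id = f$properties$pa_id, pa_class = f$properties$pa_class,
               xmin = min(m[, 1]), ymin = min(m[, 2]),
               xmax = max(m[, 1]), ymax = max(m[, 2]),
               stringsAsFactors = FALSE)
  })) else data.frame(pa_id = character(0), pa_class = character(0),
                      xmin = numeric(0), ymin = numeric(0),
                      xmax = numeric(0), ymax = numeric(0))
  stf <- read_geojson_features(file.path(dir, "streams.geojson"))
  streams <- if (length(stf)) do.call(rbind, lapply(stf, function(f) {
    m <- do.call(rbind, lapply(f$geometry$coordinates, unlist))
    data.frame(stream_id = f$properties$stream_id, x = m[, 1], y = m[, 2],
               stringsAsFactors = FALSE)
  })) else data.frame(stream_id = character(0), x = numeric(0),
                      y = numeric(0))
  pf <- read_geojson_features(file.path(dir, "patches.geojson"))
  patches <- do.call(rbind, lapply(pf, function(f) {
    m <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    data.frame(patch_id = f$properties$patch_id,
               year = f$properties$year,
               xmin = min(m[, 1]), ymin = min(m[, 2]),
               xmax = max(m[, 1]), ymax = max(m[, 2]),
               cx = mean(range(m[, 1])), cy = mean(range(m[, 2])),
               area_ha = f$properties$area_ha,
               holding_id = f$properties$holding_id,
               stringsAsFactors = FALSE)
  }))
  nm <- read_ascii_grid(file.path(dir, "native_map.asc"))
  gt <- utils::read.csv(file.path(dir, "ground_truth.csv"),
                        stringsAsFactors = FALSE)
  list(holdings = holdings, protected_areas = protected, streams = streams,
       patches = patches, native_map = nm$values, grid = nm$grid,
       ground_truth = gt)
}

#' Write / read enforcement record CSVs
#'
#' Columns: `record_id, process_id, date` (ISO-8601), `state, theme,
#' sanction_type, fine_value_brl, x, y`.
#'
#' @param records record data.frame.
#' @param path CSV path.
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(record_id = "character",
                                       process_id = "character",
                                       date = "character",
                                       state = "character"))
  for (cc in c("x", "y"))
    if (cc %in% names(df)) df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  df
}
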