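# Grid and raster containers.
#
# Rasters are plain numeric matrices indexed [row, col] with row 1 at the
# SOUTH edge (y increasing with row), column 1 at the west edge. A grid_spec
# fixes the georeferencing; ESRI ASCII grid I/O flips rows to the
# north-to-south order the format requires.

#' Define a raster grid
#'
#' @param origin numeric length-2, planar coordinates of the grid's
#'   south-west corner in meters.
#' @param cell_size_m cell edge length in meters.
#' @param n_cols,n_rows grid dimensions.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(origin = c(0, 0), cell_size_m, n_cols, n_rows) {
  stopifnot(length(origin) == 2, cell_size_m > 0, n_cols > 0, n_rows > 0)
  structure(list(origin = as.numeric(origin),
                 cell_size_m = as.numeric(cell_size_m),
                 n_cols = as.integer(n_cols), n_rows = as.integer(n_rows)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g m, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size_m, x$origin[1], x$origin[2]))
  invisible(x)
}

grid_equal <- function(a, b) {
  isTRUE(all.equal(a$origin, b$origin)) &&
    a$cell_size_m == b$cell_size_m &&
    a$n_cols == b$n_cols && a$n_rows == b$n_rows
}

cell_centers_x <- function(grid) grid$origin[1] + (seq_len(grid$n_cols) - 0.5) * grid$cell_size_m
cell_centers_y <- function(grid) grid$origin[2] + (seq_len(grid$n_rows) - 0.5) * grid$cell_size_m

# Matrix (row, col) indices of cells whose centers fall inside a polygon,
# restricted to the polygon's bounding box for speed.
cells_in_poly <- function(poly, grid) {
  bb <- poly_bbox(poly)
  cs <- grid$cell_size_m
  c0 <- max(1L, floor((bb[1] - grid$origin[1]) / cs) + 1L)
  c1 <- min(grid$n_cols, ceiling((bb[3] - grid$origin[1]) / cs))
  r0 <- max(1L, floor((bb[2] - grid$origin[2]) / cs) + 1L)
  r1 <- min(grid$n_rows, ceiling((bb[4] - grid$origin[2]) / cs))
  if (c1 < c0 || r1 < r0) return(cbind(row = integer(0), col = integer(0)))
  cols <- c0:c1; rows <- r0:r1
  cx <- grid$origin[1] + (cols - 0.5) * cs
  cy <- grid$origin[2] + (rows - 0.5) * cs
  px <- rep(cx, times = length(cy))
  py <- rep(cy, each = length(cx))
  inside <- points_in_poly(px, py, poly)
  cbind(row = rep(rows, each = length(cols))[inside],
        col = rep(cols, times = length(rows))[inside])
}

#' Construct a density raster
#'
#' Container for a gridded surface with an explicit validity mask, as
#' produced by [kernel_density()] and consumed by [quartile_mask()] and
#' [spatial_match_correlation()].
#'
#' @param grid a [grid_spec()].
#' @param values numeric matrix `n_rows x n_cols` (row 1 = south edge).
#' @param mask logical matrix, `TRUE` where the cell is valid.
#' @param year integer year the surface describes, or `NA`.
#' @param meta named list of provenance fields (kernel, bandwidth, ...).
#' @return an object of class `density_raster`.
#' @export
density_raster <- function(grid, values, mask = NULL, year = NA_integer_,
                           meta = list()) {
  stopifnot(inherits(grid, "grid_spec"),
            nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  if (is.null(mask)) mask <- matrix(TRUE, grid$n_rows, grid$n_cols)
  stopifnot(all(dim(mask) == dim(values)))
  if (any(values[mask] < 0))
    stop("density values must be nonnegative on valid cells", call. = FALSE)
  structure(list(grid = grid, values = values, mask = mask,
                 year = as.integer(year), meta = meta),
            class = "density_raster")
}

#' @export
print.density_raster <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf(
    "<density_raster> year %s, %d x %d cells (%d valid), range [%.4g, %.4g]\n",
    ifelse(is.na(x$year), "?", x$year), x$grid$n_rows, x$grid$n_cols,
    sum(x$mask), if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Rasterize point events or rectangular patches onto a grid
#'
#' Points are binned into cells (each in-grid point adds its weight to one
#' cell). Axis-aligned rectangular patches contribute their exact covered-area
#' fraction per cell, so `values * cell_area` sums to the total in-grid patch
#' area.
#'
#' @param x,y point coordinates (for `type = "points"`).
#' @param rects data.frame with columns `xmin, ymin, xmax, ymax` (for
#'   `type = "rects"`).
#' @param grid a [grid_spec()].
#' @param weights optional per-point weights (points only).
#' @param type `"points"` or `"rects"`.
#' @return numeric matrix `n_rows x n_cols`.
#' @export
rasterize_events <- function(x = NULL, y = NULL, rects = NULL, grid,
                             weights = NULL, type = c("points", "rects")) {
  type <- match.arg(type)
  out <- matrix(0, grid$n_rows, grid$n_cols)
  cs <- grid$cell_size_m
  if (type == "points") {
    if (length(x) == 0) return(out)
    if (is.null(weights)) weights <- rep(1, length(x))
    col <- floor((x - grid$origin[1]) / cs) + 1
    row <- floor((y - grid$origin[2]) / cs) + 1
    keep <- col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows
    if (!any(keep)) return(out)
    idx <- (col[keep] - 1) * grid$n_rows + row[keep]
    tab <- tapply(weights[keep], idx, sum)
    out[as.integer(names(tab))] <- as.numeric(tab)
    return(out)
  }
  if (is.null(rects) || nrow(rects) == 0) return(out)
  gx0 <- grid$origin[1]; gy0 <- grid$origin[2]
  for (k in seq_len(nrow(rects))) {
    x0 <- rects$xmin[k]; x1 <- rects$xmax[k]
    y0 <- rects$ymin[k]; y1 <- rects$ymax[k]
    if (x1 <= x0 || y1 <= y0) {
      warning("skipping degenerate (zero-area) patch at row ", k)
      next
    }
    c0 <- max(1L, floor((x0 - gx0) / cs) + 1L)
    c1 <- min(grid$n_cols, ceiling((x1 - gx0) / cs))
    r0 <- max(1L, floor((y0 - gy0) / cs) + 1L)
    r1 <- min(grid$n_rows, ceiling((y1 - gy0) / cs))
    if (c1 < c0 || r1 < r0) next
    cols <- c0:c1; rows <- r0:r1
    ox <- pmax(0, pmin(gx0 + cols * cs, x1) - pmax(gx0 + (cols - 1) * cs, x0))
    oy <- pmax(0, pmin(gy0 + rows * cs, y1) - pmax(gy0 + (rows - 1) * cs, y0))
    out[rows, cols] <- out[rows, cols] + (oy %o% ox) / cs^2
  }
  out
}

#' Write / read a raster as an ESRI ASCII grid
#'
#' Plain-text raster interchange format: a six-line header then rows from
#' north to south.
#'
#' @param values numeric matrix (row 1 = south edge).
#' @param grid a [grid_spec()].
#' @param path file path.
#' @param nodata value written for `NA` cells.
#' @export
write_ascii_grid <- function(values, grid, path, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.6f", grid$origin[1]),
    sprintf("yllcorner %.6f", grid$origin[2]),
    sprintf("cellsize %.6f", grid$cell_size_m),
    sprintf("NODATA_value %g", nodata)), con)
  v <- values
  v[is.na(v)] <- nodata
  for (r in rev(seq_len(grid$n_rows)))
    writeLines(paste(format(v[r, ], trim = TRUE, scientific = FALSE),
                     collapse = " "), con)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @return `read_ascii_grid()` returns a list with `values` and `grid`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  kv <- stats::setNames(vapply(hdr, function(p) as.numeric(p[2]), 0),
                        vapply(hdr, `[`, "", 1))
  nc <- as.integer(kv[["ncols"]]); nr <- as.integer(kv[["nrows"]])
  vals <- scan(text = paste(lines[-(1:6)], collapse = " "), quiet = TRUE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[rev(seq_len(nr)), , drop = FALSE]   # back to south-up
  m[m == kv[["nodata_value"]]] <- NA
  list(values = m,
       grid = grid_spec(c(kv[["xllcorner"]], kv[["yllcorner"]]),
                        kv[["cellsize"]], nc, nr))
}
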