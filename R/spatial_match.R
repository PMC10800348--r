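# Spatial-targeting statistic: kernel heatmaps of annual fines and
# deforestation, lowest-quartile masking, and masked pixel-wise Pearson
# correlation with a trailing 4-year moving average.

#' Configuration for the spatial-match statistic
#'
#' @param bandwidth_m kernel bandwidth (support radius) in meters. 30 km is
#'   the biome-scale reference value; smaller regions warrant
#'   proportionally smaller bandwidths.
#' @param kernel `"quartic"` (biweight, the common GIS kernel-density
#'   convention, support radius = bandwidth) or `"gaussian"`
#'   (sigma = bandwidth/3, truncated at the bandwidth and renormalized so
#'   mass is conserved).
#' @param mask_quantile quantile of strictly positive cells below which
#'   cells are nulled before correlating (default lowest quartile).
#' @param cell_size_m analysis cell size in meters.
#' @return an object of class `spatial_match_config`.
#' @export
spatial_match_config <- function(bandwidth_m = 30000,
                                 kernel = c("quartic", "gaussian"),
                                 mask_quantile = 0.25, cell_size_m = 100) {
  kernel <- match.arg(kernel)
  if (bandwidth_m <= 0) stop("bandwidth_m must be > 0", call. = FALSE)
  if (mask_quantile < 0 || mask_quantile >= 1)
    stop("mask_quantile must be in [0, 1)", call. = FALSE)
  structure(list(bandwidth_m = bandwidth_m, kernel = kernel,
                 mask_quantile = mask_quantile, cell_size_m = cell_size_m),
            class = "spatial_match_config")
}

#' Kernel density surface of point events
#'
#' Estimates a smooth event-density surface ("heatmap") on a grid. Each
#' event contributes a radially symmetric kernel of support radius
#' `bandwidth_m`; with unit weights the surface integrates to the event
#' count (up to edge losses for events nearer than one bandwidth to the
#' border -- no edge correction is applied). Values are densities per m2.
#'
#' @param x,y event coordinates in meters.
#' @param grid a [grid_spec()].
#' @param config a [spatial_match_config()].
#' @param weights optional event weights (e.g. patch areas).
#' @param year year tag for the output raster.
#' @return a [density_raster()].
#' @export
kernel_density <- function(x, y, grid, config = spatial_match_config(),
                           weights = NULL, year = NA_integer_) {
  inx <- x >= grid$origin[1] & x <= grid$origin[1] + grid$n_cols * grid$cell_size_m &
         y >= grid$origin[2] & y <= grid$origin[2] + grid$n_rows * grid$cell_size_m
  if (!any(inx)) stop("no in-grid events: empty density", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(x))
  x <- x[inx]; y <- y[inx]; weights <- weights[inx]
  h <- config$bandwidth_m
  cs <- grid$cell_size_m
  cx <- cell_centers_x(grid)
  cy <- cell_centers_y(grid)
  vals <- matrix(0, grid$n_rows, grid$n_cols)
  sigma <- h / 3
  gauss_norm <- 1 / (2 * pi * sigma^2 * (1 - exp(-h^2 / (2 * sigma^2))))
  for (i in seq_along(x)) {
    c0 <- max(1L, ceiling((x[i] - h - grid$origin[1]) / cs))
    c1 <- min(grid$n_cols, floor((x[i] + h - grid$origin[1]) / cs) + 1L)
    r0 <- max(1L, ceiling((y[i] - h - grid$origin[2]) / cs))
    r1 <- min(grid$n_rows, floor((y[i] + h - grid$origin[2]) / cs) + 1L)
    if (c1 < c0 || r1 < r0) next
    dx2 <- (cx[c0:c1] - x[i])^2
    dy2 <- (cy[r0:r1] - y[i])^2
    d2 <- outer(dy2, dx2, `+`)
    inside <- d2 <= h^2
    k <- matrix(0, nrow(d2), ncol(d2))
    if (config$kernel == "quartic") {
      k[inside] <- 3 / (pi * h^2) * (1 - d2[inside] / h^2)^2
    } else {
      k[inside] <- gauss_norm * exp(-d2[inside] / (2 * sigma^2))
    }
    vals[r0:r1, c0:c1] <- vals[r0:r1, c0:c1] + weights[i] * k
  }
  density_raster(grid, vals, year = year,
                 meta = list(kernel = config$kernel, bandwidth_m = h,
                             n_events = length(x)))
}

#' Null the lowest-density cells of a raster
#'
#' Sets to nodata every valid cell whose value is strictly below the
#' `q`-quantile of the strictly positive valid cells; zero-valued cells are
#' always nulled. The threshold is the `floor(q * n) + 1`-th order statistic
#' of the n positive cells, so at most a share `q` of positive cells is ever
#' removed and ties at the threshold are retained.
#'
#' @param raster a [density_raster()].
#' @param q quantile in `[0, 1)`; default the lowest quartile.
#' @return the masked [density_raster()].
#' @export
quartile_mask <- function(raster, q = 0.25) {
  pos <- raster$mask & raster$values > 0
  if (!any(pos)) stop("no positive cells to mask", call. = FALSE)
  v <- sort(raster$values[pos])
  thr <- v[floor(q * length(v)) + 1]
  raster$mask <- pos & raster$values >= thr
  raster$meta$mask_quantile <- q
  raster$meta$mask_threshold <- thr
  raster
}

#' Masked pixel-wise Pearson correlation between two density rasters
#'
#' Correlates the two surfaces over the cells valid in BOTH rasters
#' (intersection rule). 1 represents a perfect spatial match.
#'
#' @param a,b [density_raster()] objects on an identical grid.
#' @return list with `pearson_r` and `n_valid_cells`.
#' @export
spatial_match_correlation <- function(a, b) {
  if (!grid_equal(a$grid, b$grid))
    stop("rasters are on different grids", call. = FALSE)
  joint <- a$mask & b$mask
  n <- sum(joint)
  if (n < 2) stop("fewer than 2 jointly valid cells", call. = FALSE)
  av <- a$values[joint]; bv <- b$values[joint]
  if (stats::sd(av) == 0 || stats::sd(bv) == 0)
    stop("a raster is constant over the joint support: correlation undefined",
         call. = FALSE)
  list(pearson_r = stats::cor(av, bv), n_valid_cells = n)
}

#' Annual spatial-match series between fines and deforestation
#'
#' For each year: kernel density of geolocated fine locations and of
#' deforestation patch centroids (weighted by patch area), lowest-quantile
#' masking of both, then the masked pixel-wise Pearson correlation. A
#' trailing moving average (default window 4, defined only where the window
#' is full) smooths the series. Years with zero events in either layer get a
#' missing correlation.
#'
#' @param fines data.frame with `year`, `x`, `y` (rows without coordinates
#'   are ignored).
#' @param patches data.frame with `year`, `cx`, `cy`, `area_ha`.
#' @param grid a [grid_spec()].
#' @param config a [spatial_match_config()].
#' @param ma_window moving-average window length in years.
#' @return data.frame `(year, pearson_r, n_valid_cells, ma)` of class
#'   `spatial_match_series`.
#' @export
spatial_match_series <- function(fines, patches, grid,
                                 config = spatial_match_config(),
                                 ma_window = 4L) {
  fines <- fines[!is.na(fines$x) & !is.na(fines$y), , drop = FALSE]
  years <- sort(unique(c(fines$year, patches$year)))
  if (length(years) == 0) stop("no events in either layer", call. = FALSE)
  years <- seq(min(years), max(years))
  r <- rep(NA_real_, length(years))
  nv <- rep(NA_integer_, length(years))
  for (i in seq_along(years)) {
    fy <- fines[fines$year == years[i], , drop = FALSE]
    py <- patches[patches$year == years[i], , drop = FALSE]
    if (nrow(fy) == 0 || nrow(py) == 0) next
    df <- kernel_density(fy$x, fy$y, grid, config, year = years[i])
    dp <- kernel_density(py$cx, py$cy, grid, config,
                         weights = py$area_ha, year = years[i])
    res <- try(spatial_match_correlation(
      quartile_mask(df, config$mask_quantile),
      quartile_mask(dp, config$mask_quantile)), silent = TRUE)
    if (inherits(res, "try-error")) next
    r[i] <- res$pearson_r
    nv[i] <- res$n_valid_cells
  }
  out <- data.frame(year = years, pearson_r = r, n_valid_cells = nv,
                    ma = moving_average(r, ma_window))
  attr(out, "ma_window") <- ma_window
  attr(out, "config") <- config
  class(out) <- c("spatial_match_series", "data.frame")
  out
}

#' @export
print.spatial_match_series <- function(x, ...) {
  cat(sprintf("<spatial_match_series> %d years, mean r = %.3f (window %d MA)\n",
              nrow(x), mean(x$pearson_r, na.rm = TRUE),
              attr(x, "ma_window") %||% 4L))
  print.data.frame(x, digits = 3)
  invisible(x)
}
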