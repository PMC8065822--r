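# Coordinate, distance, and grid primitives shared by all analysis stages.
#
# Conventions (fixed so downstream results are bit-reproducible):
#   * geographic coordinates are lon-first decimal degrees, lon in [-180, 180],
#     lat in [-90, 90];
#   * projected coordinates are kilometres on an equal-area plane;
#   * grids use half-open cell intervals [edge, edge + cell_size) with row 1
#     at the minimum y ("south-up" in memory; file writers flip as needed).

#' Radius of the spherical Earth model, km
#'
#' All great-circle distances and the equal-area projection use a sphere of
#' this radius.
#' @export
EARTH_RADIUS_KM <- 6371

#' Construct a table of geographic points
#'
#' @param lon,lat numeric vectors of equal length; decimal degrees.
#' @return a data.frame with columns `lon`, `lat`.
#' @export
geo_points <- function(lon, lat) {
  if (length(lon) != length(lat)) {
    stop("lon and lat must have equal length", call. = FALSE)
  }
  check_lonlat(lon, lat)
  data.frame(lon = as.numeric(lon), lat = as.numeric(lat))
}

check_lonlat <- function(lon, lat) {
  if (!all(is.finite(lon)) || !all(is.finite(lat))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  if (any(lon < -180 | lon > 180) || any(lat < -90 | lat > 90)) {
    stop("coordinates out of range: lon in [-180,180], lat in [-90,90]",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius \code{EARTH_RADIUS_KM}.
#' Vectorized over both arguments (recycled).
#'
#' @param lon1,lat1,lon2,lat2 decimal degrees.
#' @return distance(s) in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  check_lonlat(lon1, lat1)
  check_lonlat(lon2, lat2)
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  # clamp guards against rounding slightly above 1 for near-antipodal pairs
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' Project lon/lat to an equal-area plane (km)
#'
#' The only supported projection tag is \code{"cea"}: the world cylindrical
#' equal-area projection with standard parallel 0 on the spherical Earth
#' model, x = R * lon_rad, y = R * sin(lat). It is exactly area-preserving
#' and has a closed-form inverse, which keeps density-per-km2 meaningful on
#' every grid cell.
#'
#' @param points data.frame with `lon`, `lat` columns (decimal degrees).
#' @param projection_tag projection identifier; only `"cea"` is supported.
#' @return data.frame with columns `x_km`, `y_km`.
#' @export
project_points <- function(points, projection_tag = "cea") {
  if (!identical(projection_tag, "cea")) {
    stop("unsupported projection_tag: ", projection_tag, call. = FALSE)
  }
  check_lonlat(points$lon, points$lat)
  to_rad <- pi / 180
  data.frame(x_km = EARTH_RADIUS_KM * points$lon * to_rad,
             y_km = EARTH_RADIUS_KM * sin(points$lat * to_rad))
}

#' Inverse of \code{project_points}
#'
#' @param xy data.frame with `x_km`, `y_km` columns.
#' @inheritParams project_points
#' @return data.frame with `lon`, `lat` in decimal degrees.
#' @export
unproject_points <- function(xy, projection_tag = "cea") {
  if (!identical(projection_tag, "cea")) {
    stop("unsupported projection_tag: ", projection_tag, call. = FALSE)
  }
  to_deg <- 180 / pi
  s <- xy$y_km / EARTH_RADIUS_KM
  if (any(abs(s) > 1)) stop("y_km outside the projectable range", call. = FALSE)
  data.frame(lon = xy$x_km / EARTH_RADIUS_KM * to_deg,
             lat = asin(s) * to_deg)
}

#' Define a regular analysis grid
#'
#' The grid always covers the requested extent: the column/row counts are
#' rounded up, never truncated, so a 10.5 km extent at 1 km cells gets 11
#' columns. Cell centres sit at \code{x_min + (j + 0.5) * cell_size}.
#'
#' @param extent numeric length-4 vector \code{c(x_min, y_min, x_max, y_max)}
#'   in projected km.
#' @param cell_size_km cell edge length, km, > 0.
#' @param projection_tag the projection the planar coordinates live in.
#' @return an object of class \code{grid_spec}.
#' @export
make_grid <- function(extent, cell_size_km, projection_tag = "cea") {
  stopifnot(length(extent) == 4)
  x_min <- extent[[1]]; y_min <- extent[[2]]
  x_max <- extent[[3]]; y_max <- extent[[4]]
  if (!all(is.finite(extent))) stop("extent must be finite", call. = FALSE)
  if (x_max <= x_min || y_max <= y_min) {
    stop("degenerate extent", call. = FALSE)
  }
  if (!is.finite(cell_size_km) || cell_size_km <= 0) {
    stop("cell_size_km must be > 0", call. = FALSE)
  }
  if (cell_size_km > (x_max - x_min) || cell_size_km > (y_max - y_min)) {
    stop("cell_size_km larger than the extent", call. = FALSE)
  }
  # ceiling with a tiny tolerance so an exact multiple is not bumped up by
  # floating-point noise
  n_of <- function(w) {
    n <- w / cell_size_km
    n_floor <- floor(n + 1e-9)
    if (n - n_floor > 1e-9) n_floor + 1 else n_floor
  }
  spec <- list(x_min = x_min, y_min = y_min,
               cell_size = cell_size_km,
               n_cols = as.integer(n_of(x_max - x_min)),
               n_rows = as.integer(n_of(y_max - y_min)),
               projection_tag = projection_tag)
  class(spec) <- "grid_spec"
  spec
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d cols x %d rows, cell %g km, origin (%g, %g), proj '%s'\n",
              x$n_cols, x$n_rows, x$cell_size, x$x_min, x$y_min,
              x$projection_tag))
  invisible(x)
}

#' Cell-centre coordinates of a grid
#'
#' @param spec a \code{grid_spec}.
#' @return list with vectors \code{x} (length n_cols) and \code{y}
#'   (length n_rows), km; row 1 is the minimum-y row.
#' @export
grid_centres <- function(spec) {
  list(x = spec$x_min + (seq_len(spec$n_cols) - 0.5) * spec$cell_size,
       y = spec$y_min + (seq_len(spec$n_rows) - 0.5) * spec$cell_size)
}

#' Construct a grid raster
#'
#' @param spec a \code{grid_spec}.
#' @param values numeric matrix of dimension n_rows x n_cols (row 1 at
#'   minimum y), or a single number to fill with. NA marks nodata.
#' @return object of class \code{grid_raster}.
#' @export
grid_raster <- function(spec, values = 0) {
  stopifnot(inherits(spec, "grid_spec"))
  if (length(values) == 1) {
    values <- matrix(as.numeric(values), nrow = spec$n_rows, ncol = spec$n_cols)
  }
  if (!is.matrix(values) ||
      nrow(values) != spec$n_rows || ncol(values) != spec$n_cols) {
    stop("values must be an n_rows x n_cols matrix", call. = FALSE)
  }
  if (any(is.infinite(values))) stop("raster values must be finite or NA",
                                     call. = FALSE)
  structure(list(spec = spec, values = values), class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("grid_raster: %d x %d cells (%d nodata); range [%g, %g]\n",
              x$spec$n_rows, x$spec$n_cols, sum(is.na(x$values)),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Summary statistics of a raster, ignoring nodata
#'
#' @param raster a \code{grid_raster}.
#' @return named list: n_valid, mean, sd, min, max, sum.
#' @export
raster_stats <- function(raster) {
  v <- raster$values[!is.na(raster$values)]
  list(n_valid = length(v),
       mean = if (length(v)) mean(v) else NA_real_,
       sd = if (length(v) > 1) stats::sd(v) else NA_real_,
       min = if (length(v)) min(v) else NA_real_,
       max = if (length(v)) max(v) else NA_real_,
       sum = sum(v))
}

#' Map projected points to grid cell indices
#'
#' Cells are half-open: a point exactly on the upper edge of the grid falls
#' outside it.
#'
#' @param spec a \code{grid_spec}.
#' @param x_km,y_km projected coordinates.
#' @return data.frame with integer columns `row`, `col`; NA for points
#'   outside the grid.
#' @export
cell_index <- function(spec, x_km, y_km) {
  col <- floor((x_km - spec$x_min) / spec$cell_size) + 1
  row <- floor((y_km - spec$y_min) / spec$cell_size) + 1
  bad <- col < 1 | col > spec$n_cols | row < 1 | row > spec$n_rows
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}
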