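# Point-density, kernel-density, and tessellated species-richness surfaces.
#
# All three operate on projected (equal-area, km) coordinates so that
# densities are per true km2.

#' Point density surface
#'
#' Each cell value is the number of points within \code{radius_km} of the
#' cell centre, divided by the neighbourhood area pi * radius_km^2 — the
#' classic GIS "point density" with a circular neighbourhood. Units:
#' points / km2.
#'
#' @param x_km,y_km projected point coordinates (km).
#' @param grid a \code{grid_spec}.
#' @param radius_km neighbourhood radius, > 0.
#' @return a \code{grid_raster}.
#' @export
point_density <- function(x_km, y_km, grid, radius_km) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.finite(radius_km) || radius_km <= 0) {
    stop("radius_km must be > 0", call. = FALSE)
  }
  counts <- accumulate_kernel(x_km, y_km, rep(1, length(x_km)), grid,
                              radius_km, function(d2, h2) 1)
  grid_raster(grid, counts / (pi * radius_km^2))
}

#' Quartic kernel density surface
#'
#' Kernel K(d) = 3 / (pi h^2) * (1 - d^2/h^2)^2 for d < h, 0 beyond — the
#' quartic (biweight) kernel used by the ArcMap Kernel Density tool. Each
#' cell holds sum_i w_i K(d_i) evaluated at the cell centre, so the surface
#' integrates (sum of cells times cell area) to the total weight for points
#' at least one bandwidth from the grid edge. No edge correction is applied.
#'
#' @param x_km,y_km projected point coordinates (km).
#' @param grid a \code{grid_spec}.
#' @param bandwidth_km kernel radius h, > 0.
#' @param weights per-point weights; default 1.
#' @return a \code{grid_raster} in weight / km2.
#' @export
kernel_density <- function(x_km, y_km, grid, bandwidth_km,
                           weights = rep(1, length(x_km))) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.finite(bandwidth_km) || bandwidth_km <= 0) {
    stop("bandwidth_km must be > 0", call. = FALSE)
  }
  if (length(weights) != length(x_km)) {
    stop("weights must match the number of points", call. = FALSE)
  }
  vals <- accumulate_kernel(x_km, y_km, weights, grid, bandwidth_km,
                            function(d2, h2) {
                              3 / (pi * h2) * (1 - d2 / h2)^2
                            })
  grid_raster(grid, vals)
}

# Shared accumulation: for each point, add w * f(d^2, h^2) to every cell
# whose centre lies strictly within distance h. Loops over points but
# vectorizes over each point's local cell window, so cost is
# O(N * (2h/cell)^2).
accumulate_kernel <- function(x_km, y_km, weights, grid, h, kernel_f) {
  out <- matrix(0, nrow = grid$n_rows, ncol = grid$n_cols)
  if (length(x_km) == 0) return(out)
  cen <- grid_centres(grid)
  h2 <- h^2
  for (i in seq_along(x_km)) {
    cols <- which(abs(cen$x - x_km[i]) < h)
    rows <- which(abs(cen$y - y_km[i]) < h)
    if (!length(cols) || !length(rows)) next
    dx2 <- (cen$x[cols] - x_km[i])^2
    dy2 <- (cen$y[rows] - y_km[i])^2
    d2 <- outer(dy2, dx2, `+`)
    inside <- d2 < h2
    if (!any(inside)) next
    add <- matrix(0, nrow = length(rows), ncol = length(cols))
    add[inside] <- weights[i] * kernel_f(d2[inside], h2)
    out[rows, cols] <- out[rows, cols] + add
  }
  out
}

#' Species richness on a square tessellation
#'
#' Overlays a square tessellation of cell edge \code{resolution_km} (anchored
#' at \code{origin}) on the projected occurrences and counts distinct species
#' per cell. Cells with no occurrences are omitted.
#'
#' @param table cleaned occurrence data.frame (columns `species`, `lon`,
#'   `lat`).
#' @param resolution_km tessellation cell edge, km.
#' @param origin planar anchor c(x, y) of the tessellation, km; defaults to
#'   the projected lower-left of the data.
#' @param projection_tag projection used to planarize the occurrences.
#' @return data.frame with columns `x_km`, `y_km` (cell centres), `richness`
#'   (distinct species), `n_points`; attribute `species_per_cell` lists the
#'   species set of each cell.
#' @export
richness_tessellation <- function(table, resolution_km, origin = NULL,
                                  projection_tag = "cea") {
  if (!is.finite(resolution_km) || resolution_km <= 0) {
    stop("resolution_km must be > 0", call. = FALSE)
  }
  if (nrow(table) == 0) {
    out <- data.frame(x_km = numeric(), y_km = numeric(),
                      richness = integer(), n_points = integer())
    attr(out, "species_per_cell") <- list()
    return(out)
  }
  xy <- project_points(table[, c("lon", "lat")], projection_tag)
  if (is.null(origin)) origin <- c(min(xy$x_km), min(xy$y_km))
  ci <- floor((xy$x_km - origin[1]) / resolution_km)
  ri <- floor((xy$y_km - origin[2]) / resolution_km)
  key <- paste(ci, ri)
  groups <- split(seq_len(nrow(table)), key)
  cells <- lapply(groups, function(idx) {
    list(ci = ci[idx[1]], ri = ri[idx[1]],
         species = sort(unique(table$species[idx])),
         n_points = length(idx))
  })
  out <- data.frame(
    x_km = origin[1] + (vapply(cells, `[[`, 0, "ci") + 0.5) * resolution_km,
    y_km = origin[2] + (vapply(cells, `[[`, 0, "ri") + 0.5) * resolution_km,
    richness = vapply(cells, function(c) length(c$species), 0L),
    n_points = vapply(cells, `[[`, 0L, "n_points"))
  ord <- order(out$x_km, out$y_km)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "species_per_cell") <- lapply(cells, `[[`, "species")[ord]
  out
}

#' Continuous richness surface from tessellation cells
#'
#' Converts richness cells to points at their centres and applies the
#' quartic kernel with the richness as the weight — the "richness to point
#' features to kernel density" chain used for continuous species-richness
#' maps. Identical to calling \code{kernel_density} with richness weights.
#'
#' @param cells output of \code{richness_tessellation}.
#' @param grid a \code{grid_spec}.
#' @param bandwidth_km kernel radius, km.
#' @return a \code{grid_raster}; mass approximates the summed richness.
#' @export
richness_surface <- function(cells, grid, bandwidth_km) {
  kernel_density(cells$x_km, cells$y_km, grid, bandwidth_km,
                 weights = cells$richness)
}
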