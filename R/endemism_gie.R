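# Geographical Interpolation of Endemism (GIE).
#
# Per species: centroid of its occurrences and an area-of-influence radius
# (great-circle distance from centroid to the farthest occurrence). Species
# are binned into endemism classes by radius (up to 100 km = class 1, up to
# 300 km = class 2 by default). Within a class, each species contributes a
# peak-normalized quartic kernel centred on its centroid; the summed surface
# reads directly in "number of overlapping species", and connected regions
# with at least `min_synendemic` species form the areas of endemism.

#' Centroid and area-of-influence radius of a species
#'
#' The centroid is the arithmetic mean of the occurrences in equal-area
#' projected coordinates, mapped back to lon/lat; the radius is the maximum
#' great-circle distance from the centroid to any occurrence.
#'
#' @param lon,lat occurrence coordinates of one species, decimal degrees.
#' @param species species label.
#' @return list of class \code{species_range}: `species`, `centroid`
#'   (lon/lat), `radius_km`, `n_points`.
#' @export
species_range <- function(lon, lat, species = "sp") {
  if (length(lon) == 0) stop("empty point set", call. = FALSE)
  xy <- project_points(data.frame(lon = lon, lat = lat))
  cen <- unproject_points(data.frame(x_km = mean(xy$x_km),
                                     y_km = mean(xy$y_km)))
  r <- max(haversine_km(cen$lon, cen$lat, lon, lat))
  structure(list(species = species,
                 centroid = c(lon = cen$lon, lat = cen$lat),
                 radius_km = r, n_points = length(lon)),
            class = "species_range")
}

#' Species ranges for every species of a table
#'
#' @param table cleaned occurrence data.frame (`species`, `lon`, `lat`).
#' @return list of \code{species_range}, ordered by species label.
#' @export
species_ranges <- function(table) {
  sp <- sort(unique(table$species))
  lapply(sp, function(s) {
    idx <- table$species == s
    species_range(table$lon[idx], table$lat[idx], s)
  })
}

#' Default endemism classes: up to 100 km (class 1), 100-300 km (class 2)
#'
#' @param bandwidths kernel bandwidths per class, km; defaults to each
#'   class's upper radius bound.
#' @return data.frame: `class_id`, `max_radius_km`, `bandwidth_km`.
#' @export
endemism_classes <- function(bandwidths = NULL) {
  cls <- data.frame(class_id = c(1L, 2L), max_radius_km = c(100, 300))
  cls$bandwidth_km <- if (is.null(bandwidths)) cls$max_radius_km else bandwidths
  cls
}

#' Assign species ranges to endemism classes
#'
#' A species goes to the first class whose radius bound is >= its radius
#' (classes are disjoint radius intervals, e.g. [0, 100] then (100, 300]).
#' With \code{nested = TRUE} a species also belongs to every wider class.
#' Radii beyond the last bound are unassigned (not endemic at these scales).
#'
#' @param ranges list of \code{species_range}.
#' @param classes data.frame as from \code{endemism_classes}, sorted by
#'   bound.
#' @param nested if TRUE, narrow-range species are included in wider
#'   classes too.
#' @return data.frame: `species`, `radius_km`, `class_id` (NA when
#'   unassigned); with \code{nested} one row per (species, class) pair.
#' @export
classify_ranges <- function(ranges, classes = endemism_classes(),
                            nested = FALSE) {
  stopifnot(all(diff(classes$max_radius_km) > 0))
  rows <- lapply(ranges, function(r) {
    fits <- which(classes$max_radius_km >= r$radius_km)
    if (!length(fits)) {
      return(data.frame(species = r$species, radius_km = r$radius_km,
                        class_id = NA_integer_))
    }
    ids <- if (nested) classes$class_id[fits] else classes$class_id[fits[1]]
    data.frame(species = r$species, radius_km = r$radius_km, class_id = ids)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kernel-interpolated endemism surface for one class
#'
#' Each species adds a peak-normalized quartic kernel
#' (1 - d^2/h^2)^2 for d < h around its centroid, with d the great-circle
#' distance from the cell centre and h the class bandwidth (or, with
#' \code{per_species_bandwidth}, the species' own radius floored at one cell
#' size). A cell value of v means v species-equivalents overlap there;
#' an isolated species peaks at exactly 1.
#'
#' @param ranges list of \code{species_range} assigned to this class.
#' @param grid a \code{grid_spec}.
#' @param class_spec one row of \code{endemism_classes}.
#' @param per_species_bandwidth if TRUE, use each species' own radius as its
#'   bandwidth (floored at one cell size) instead of the class bandwidth.
#' @return list of class \code{endemism_surface}: `class_id`, `raster`,
#'   `species` (labels), `centroids`, `bandwidths_km`.
#' @export
gie_surface <- function(ranges, grid, class_spec,
                        per_species_bandwidth = FALSE) {
  stopifnot(inherits(grid, "grid_spec"))
  cen <- grid_centres(grid)
  ll <- unproject_points(expand.grid(x_km = cen$x, y_km = cen$y),
                         grid$projection_tag)
  # expand.grid varies x fastest: entry (i) maps to col-major over (x, y)
  vals <- matrix(0, nrow = grid$n_rows, ncol = grid$n_cols)
  bws <- numeric(length(ranges))
  for (k in seq_along(ranges)) {
    r <- ranges[[k]]
    h <- if (per_species_bandwidth) {
      max(r$radius_km, grid$cell_size)
    } else {
      class_spec$bandwidth_km
    }
    bws[k] <- h
    d <- haversine_km(r$centroid[["lon"]], r$centroid[["lat"]],
                      ll$lon, ll$lat)
    kern <- ifelse(d < h, (1 - (d / h)^2)^2, 0)
    # expand.grid varied x fastest, so kern is x-fastest: reshape to
    # (col, row) and transpose into the row 1 = min y matrix layout
    vals <- vals + t(matrix(kern, nrow = grid$n_cols, ncol = grid$n_rows))
  }
  structure(list(class_id = class_spec$class_id,
                 raster = grid_raster(grid, vals),
                 species = vapply(ranges, `[[`, "", "species"),
                 centroids = do.call(rbind,
                                     lapply(ranges, `[[`, "centroid")),
                 bandwidths_km = bws),
            class = "endemism_surface")
}

#' Areas of endemism from an endemism surface
#'
#' Thresholds the surface at \code{min_synendemic} species-equivalents and
#' extracts 8-connected components of qualifying cells. Each area is
#' annotated with the species whose kernels are positive somewhere inside
#' it, and carries its exact cell-union geometry (row runs of cells,
#' convertible to polygons).
#'
#' @param surface an \code{endemism_surface}.
#' @param min_synendemic minimum overlapping species count (default 2).
#' @return list of class \code{areas_of_endemism}: `class_id`,
#'   `min_synendemic`, `areas` — a list with per-area `cells` (row/col
#'   matrix), `species`, `max_overlap`, `bbox_km`.
#' @export
areas_of_endemism <- function(surface, min_synendemic = 2) {
  grid <- surface$raster$spec
  mask <- !is.na(surface$raster$values) &
    surface$raster$values >= min_synendemic
  comp <- label_components(mask)
  cen <- grid_centres(grid)
  areas <- lapply(seq_len(comp$n), function(id) {
    cells <- which(comp$labels == id, arr.ind = TRUE)
    cx <- cen$x[cells[, 2]]
    cy <- cen$y[cells[, 1]]
    ll <- unproject_points(data.frame(x_km = cx, y_km = cy),
                           grid$projection_tag)
    # species contributing: kernel positive in at least one member cell
    contributes <- vapply(seq_along(surface$species), function(k) {
      h <- surface$bandwidths_km[k]
      any(haversine_km(surface$centroids[k, "lon"],
                       surface$centroids[k, "lat"],
                       ll$lon, ll$lat) < h)
    }, TRUE)
    half <- grid$cell_size / 2
    list(cells = cells,
         species = surface$species[contributes],
         max_overlap = max(surface$raster$values[cells]),
         bbox_km = c(x_min = min(cx) - half, y_min = min(cy) - half,
                     x_max = max(cx) + half, y_max = max(cy) + half))
  })
  structure(list(class_id = surface$class_id,
                 min_synendemic = min_synendemic,
                 grid = grid,
                 areas = areas),
            class = "areas_of_endemism")
}

# 8-connected component labelling of a logical matrix (iterative flood
# fill; no recursion so large grids are safe).
label_components <- function(mask) {
  labels <- matrix(0L, nrow = nrow(mask), ncol = ncol(mask))
  n <- 0L
  todo <- which(mask & labels == 0L)
  for (start in todo) {
    if (labels[start] != 0L) next
    n <- n + 1L
    stack <- start
    labels[start] <- n
    nr <- nrow(mask)
    while (length(stack)) {
      cell <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- (cell - 1L) %% nr + 1L
      c <- (cell - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= ncol(mask)) {
          if (mask[rr, cc] && labels[rr, cc] == 0L) {
            labels[rr, cc] <- n
            stack <- c(stack, (cc - 1L) * nr + rr)
          }
        }
      }
    }
  }
  list(labels = labels, n = n)
}

#' @export
print.areas_of_endemism <- function(x, ...) {
  cat(sprintf("areas_of_endemism (class %s, >= %g synendemic): %d areas\n",
              x$class_id, x$min_synendemic, length(x$areas)))
  for (i in seq_along(x$areas)) {
    cat(sprintf("  area %d: %d cells, species: %s\n", i,
                nrow(x$areas[[i]]$cells),
                paste(x$areas[[i]]$species, collapse = ", ")))
  }
  invisible(x)
}

#' Consensus map across endemism classes
#'
#' The union of per-class areas of endemism, each retained as a distinct
#' labelled layer (overlapping or nested class-1/class-2 areas are both
#' kept).
#'
#' @param areas_list list of \code{areas_of_endemism}, one per class.
#' @return list of class \code{consensus_map}: `layers` (the inputs, by
#'   class id) and `summary` (data.frame: class_id, area_index, n_cells,
#'   n_species, species).
#' @export
consensus_map <- function(areas_list) {
  stopifnot(length(areas_list) >= 1)
  rows <- list()
  for (a in areas_list) {
    for (i in seq_along(a$areas)) {
      rows[[length(rows) + 1]] <-
        data.frame(class_id = a$class_id, area_index = i,
                   n_cells = nrow(a$areas[[i]]$cells),
                   n_species = length(a$areas[[i]]$species),
                   species = paste(a$areas[[i]]$species, collapse = ";"))
    }
  }
  summary <- if (length(rows)) do.call(rbind, rows) else
    data.frame(class_id = integer(), area_index = integer(),
               n_cells = integer(), n_species = integer(),
               species = character())
  names(areas_list) <- vapply(areas_list,
                              function(a) as.character(a$class_id), "")
  structure(list(layers = areas_list, summary = summary),
            class = "consensus_map")
}

#' Export areas of endemism as GeoJSON
#'
#' Each area becomes a MultiPolygon of its member grid cells, merged into
#' per-row rectangle runs (the geometry is the exact cell union), with the
#' class id and contributing species as properties. Coordinates are
#' unprojected back to lon/lat.
#'
#' @param consensus a \code{consensus_map} (or a single
#'   \code{areas_of_endemism}).
#' @param path output file.
#' @export
write_consensus_geojson <- function(consensus, path) {
  layers <- if (inherits(consensus, "areas_of_endemism")) {
    list(consensus)
  } else {
    consensus$layers
  }
  features <- list()
  for (a in layers) {
    grid <- a$grid
    for (i in seq_along(a$areas)) {
      area <- a$areas[[i]]
      polys <- lapply(cell_runs(area$cells), function(run) {
        x0 <- grid$x_min + (run["c0"] - 1) * grid$cell_size
        x1 <- grid$x_min + run["c1"] * grid$cell_size
        y0 <- grid$y_min + (run["r"] - 1) * grid$cell_size
        y1 <- grid$y_min + run["r"] * grid$cell_size
        corners <- unproject_points(
          data.frame(x_km = c(x0, x1, x1, x0, x0),
                     y_km = c(y0, y0, y1, y1, y0)),
          grid$projection_tag)
        list(lapply(seq_len(5), function(k) c(corners$lon[k],
                                              corners$lat[k])))
      })
      features[[length(features) + 1]] <- list(
        type = "Feature",
        properties = list(class_id = a$class_id, area_index = i,
                          species = as.list(area$species)),
        geometry = list(type = "MultiPolygon", coordinates = polys))
    }
  }
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Merge an area's cells into horizontal runs: one rectangle per maximal run
# of consecutive columns within a row.
cell_runs <- function(cells) {
  runs <- list()
  for (r in sort(unique(cells[, 1]))) {
    cols <- sort(cells[cells[, 1] == r, 2])
    start <- cols[1]; prev <- cols[1]
    for (c in cols[-1]) {
      if (c != prev + 1) {
        runs[[length(runs) + 1]] <- c(r = r, c0 = start, c1 = prev)
        start <- c
      }
      prev <- c
    }
    runs[[length(runs) + 1]] <- c(r = r, c0 = start, c1 = prev)
  }
  runs
}
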