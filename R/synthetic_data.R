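# Synthetic landscapes with planted structure: a patchy polygon mosaic, 19
# smooth-plus-noise bioclim rasters, host-associated insect/plant point
# patterns with a tunable association strength, and narrow-range endemic
# assemblages — the ground truth every pipeline stage is validated against.

#' Simulation configuration
#'
#' Defaults mirror the scale of a continental occurrence study: a 4000 x
#' 3000 km extent in southern-hemisphere latitudes, 132 landscape patches
#' (the ecoregion count of the sub-Saharan layer the analysis emulates),
#' 6343 plant and 162 insect localities with 100 and 17 species, an
#' insect-plant association strength of 0.9 with a 30 km tether, and two
#' endemic assemblages (4 and 3 species) roughly 2000 km apart.
#'
#' @param extent_km landscape width and height, km.
#' @param lon_min,lat_min geographic anchor of the landscape's lower-left
#'   corner, decimal degrees.
#' @param cell_size_km analysis grid cell edge, km.
#' @param n_patches number of Voronoi landscape patches.
#' @param n_plant_points,n_plant_species plant localities and species.
#' @param n_insect_points,n_insect_species insect localities and species.
#' @param association_rho fraction in [0, 1] of insect points tethered to a
#'   plant point (the rest are uniform).
#' @param tether_sd_km s.d. of the isotropic displacement of tethered
#'   insect points, km.
#' @param plant_cluster_sd_km offspring spread of the Thomas-like plant
#'   process, km.
#' @param plants_per_parent mean offspring per Thomas parent.
#' @param climate_noise amplitude multiplier for the smooth bumps and white
#'   noise added to each planar climate gradient (0 = exact gradients).
#' @param endemic_assemblages list of assemblages, each a list with
#'   `k_species`, `centre` (lon/lat), `spread_km`, `points_per_species`.
#' @param seed integer RNG seed.
#' @return list of class \code{simulation_config}.
#' @export
simulation_config <- function(extent_km = c(4000, 3000),
                              lon_min = 10, lat_min = -35,
                              cell_size_km = 25,
                              n_patches = 132,
                              n_plant_points = 6343,
                              n_plant_species = 100,
                              n_insect_points = 162,
                              n_insect_species = 17,
                              association_rho = 0.9,
                              tether_sd_km = 30,
                              plant_cluster_sd_km = 50,
                              plants_per_parent = 20,
                              climate_noise = 1,
                              endemic_assemblages = NULL,
                              seed = 1) {
  stopifnot(association_rho >= 0, association_rho <= 1,
            all(extent_km > 0), n_patches >= 1)
  origin <- project_points(data.frame(lon = lon_min, lat = lat_min))
  if (is.null(endemic_assemblages)) {
    # two compact assemblages half the extent width apart (~2000 km at the
    # default extent), at mid-height
    c1 <- unproject_points(data.frame(x_km = origin$x_km + 0.2 * extent_km[1],
                                      y_km = origin$y_km + 0.5 * extent_km[2]))
    c2 <- unproject_points(data.frame(x_km = origin$x_km + 0.7 * extent_km[1],
                                      y_km = origin$y_km + 0.5 * extent_km[2]))
    endemic_assemblages <- list(
      list(k_species = 4, centre = c(c1$lon, c1$lat), spread_km = 40,
           points_per_species = 6),
      list(k_species = 3, centre = c(c2$lon, c2$lat), spread_km = 40,
           points_per_species = 6))
  }
  cfg <- list(extent_km = extent_km, lon_min = lon_min, lat_min = lat_min,
              x_min = origin$x_km, y_min = origin$y_km,
              cell_size_km = cell_size_km,
              n_patches = n_patches,
              n_plant_points = n_plant_points,
              n_plant_species = n_plant_species,
              n_insect_points = n_insect_points,
              n_insect_species = n_insect_species,
              association_rho = association_rho,
              tether_sd_km = tether_sd_km,
              plant_cluster_sd_km = plant_cluster_sd_km,
              plants_per_parent = plants_per_parent,
              climate_noise = climate_noise,
              endemic_assemblages = endemic_assemblages,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

#' Analysis grid implied by a simulation config
#'
#' @param config a \code{simulation_config}.
#' @return a \code{grid_spec} covering the configured extent.
#' @export
config_grid <- function(config) {
  make_grid(c(config$x_min, config$y_min,
              config$x_min + config$extent_km[1],
              config$y_min + config$extent_km[2]),
            config$cell_size_km)
}

# ------------------------------------------------------------- landscape --

# Sutherland-Hodgman: clip a convex-or-not polygon (closed matrix) by the
# half plane {p : dot(p, nrm) <= d}.
clip_halfplane <- function(poly, nrm, d) {
  n <- nrow(poly) - 1
  out <- matrix(numeric(0), ncol = 2)
  for (k in seq_len(n)) {
    a <- poly[k, ]; b <- poly[k + 1, ]
    da <- sum(a * nrm) - d
    db <- sum(b * nrm) - d
    if (da <= 0) out <- rbind(out, a)
    if ((da < 0) != (db < 0) && da != db) {
      t <- da / (da - db)
      out <- rbind(out, a + t * (b - a))
    }
  }
  if (nrow(out) >= 3) rbind(out, out[1, ]) else out
}

#' Generate a patchy polygon landscape
#'
#' Voronoi tessellation of \code{n_patches} uniformly seeded points, clipped
#' to the configured extent: patches are disjoint convex polygons covering
#' the extent exactly, standing in for an ecoregion mosaic. Each Voronoi
#' cell is built by clipping the extent rectangle with the perpendicular
#' bisector half-plane against every other seed. Polygons are reported in
#' lon/lat (the geometry the occurrence tables live in).
#'
#' @param config a \code{simulation_config}.
#' @return a \code{patch_layer}.
#' @export
make_landscape <- function(config) {
  set.seed(config$seed + 101L)
  w <- config$extent_km[1]; h <- config$extent_km[2]
  n <- config$n_patches
  sx <- config$x_min + stats::runif(n) * w
  sy <- config$y_min + stats::runif(n) * h
  rect <- rbind(c(config$x_min, config$y_min),
                c(config$x_min + w, config$y_min),
                c(config$x_min + w, config$y_min + h),
                c(config$x_min, config$y_min + h),
                c(config$x_min, config$y_min))
  patches <- vector("list", n)
  for (i in seq_len(n)) {
    poly <- rect
    for (j in seq_len(n)) {
      if (j == i || nrow(poly) < 4) next
      # keep the side of the bisector closer to seed i
      nrm <- c(sx[j] - sx[i], sy[j] - sy[i])
      d <- sum(nrm * c((sx[i] + sx[j]) / 2, (sy[i] + sy[j]) / 2))
      poly <- clip_halfplane(poly, nrm, d)
    }
    ll <- unproject_points(data.frame(x_km = poly[, 1], y_km = poly[, 2]))
    ring <- cbind(ll$lon, ll$lat)
    patches[[i]] <- list(patch_id = sprintf("P%03d", i),
                         name = sprintf("patch %d", i),
                         parts = list(list(ring)),
                         area_km2 = polygon_area(poly))
  }
  structure(patches, class = "patch_layer")
}

# planar shoelace area of a closed ring (km2)
polygon_area <- function(ring) {
  n <- nrow(ring) - 1
  x <- ring[seq_len(n), 1]; y <- ring[seq_len(n), 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# --------------------------------------------------------------- climate --

# plausible planar ranges for each bioclim layer: intercept at the extent's
# lower-left, plus per-km slopes scaled so the cross-extent swing stays in a
# field-realistic band for that variable's units
BIOCLIM_BASE <- list(
  BIO1 = c(base = 24, swing = -10),  BIO2 = c(base = 11, swing = 3),
  BIO3 = c(base = 68, swing = -12),  BIO4 = c(base = 150, swing = 200),
  BIO6 = c(base = 16, swing = -11),  BIO8 = c(base = 24, swing = -6),
  BIO9 = c(base = 22, swing = -7),   BIO10 = c(base = 26, swing = -5),
  BIO11 = c(base = 22, swing = -9),  BIO12 = c(base = 1100, swing = -600),
  BIO13 = c(base = 220, swing = -110), BIO14 = c(base = 12, swing = -8),
  BIO15 = c(base = 70, swing = 40),  BIO16 = c(base = 560, swing = -260),
  BIO17 = c(base = 45, swing = -30), BIO18 = c(base = 300, swing = -120),
  BIO19 = c(base = 60, swing = 40))

#' Generate 19 synthetic bioclim rasters
#'
#' Each layer is a planar gradient (random orientation, variable-specific
#' plausible range) plus \code{climate_noise} times a smooth low-frequency
#' bump field and white noise. Construction constraints: BIO5 = BIO6 + a
#' strictly positive annual range, and BIO7 = BIO5 - BIO6, so max monthly
#' temperature exceeds min everywhere. With \code{climate_noise = 0} every
#' layer is an exact plane. Deterministic per seed.
#'
#' @param config a \code{simulation_config}.
#' @param grid optional \code{grid_spec}; defaults to
#'   \code{config_grid(config)}.
#' @return named list of 19 \code{grid_raster}s, BIO1..BIO19.
#' @export
make_climate <- function(config, grid = config_grid(config)) {
  set.seed(config$seed + 202L)
  cen <- grid_centres(grid)
  w <- grid$n_cols * grid$cell_size
  h <- grid$n_rows * grid$cell_size
  u <- outer(rep(1, grid$n_rows), (cen$x - grid$x_min) / w)   # 0..1 east
  v <- outer((cen$y - grid$y_min) / h, rep(1, grid$n_cols))   # 0..1 north

  planar <- function(base, swing) {
    theta <- stats::runif(1, 0, 2 * pi)
    base + swing * (cos(theta) * u + sin(theta) * v)
  }
  bumps <- function(amp) {
    f <- matrix(0, grid$n_rows, grid$n_cols)
    for (b in 1:4) {
      cxy <- stats::runif(2)
      s <- stats::runif(1, 0.1, 0.3)
      a <- stats::runif(1, -1, 1) * amp
      f <- f + a * exp(-(((u - cxy[1])^2 + (v - cxy[2])^2) / (2 * s^2)))
    }
    f
  }
  layer <- function(base, swing, noise_amp, floor_at = NULL) {
    vals <- planar(base, swing) +
      config$climate_noise * (bumps(noise_amp) +
                                matrix(stats::rnorm(grid$n_rows * grid$n_cols,
                                                    sd = noise_amp / 4),
                                       grid$n_rows, grid$n_cols))
    if (!is.null(floor_at) && config$climate_noise > 0) {
      vals <- pmax(vals, floor_at)
    }
    vals
  }

  out <- list()
  for (nm in names(BIOCLIM_BASE)) {
    p <- BIOCLIM_BASE[[nm]]
    is_precip <- nm %in% c("BIO12", "BIO13", "BIO14", "BIO16", "BIO17",
                           "BIO18", "BIO19")
    out[[nm]] <- layer(p[["base"]], p[["swing"]],
                       noise_amp = abs(p[["swing"]]) * 0.15,
                       floor_at = if (is_precip) 0 else NULL)
  }
  # temperature extremes: BIO5 = BIO6 + positive range; BIO7 consistent
  range7 <- layer(17, 6, noise_amp = 0.9)
  range7 <- pmax(range7, 1)
  out$BIO5 <- out$BIO6 + range7
  out$BIO7 <- out$BIO5 - out$BIO6
  ord <- paste0("BIO", 1:19)
  rasters <- lapply(out[ord], function(v) grid_raster(grid, v))
  names(rasters) <- ord
  rasters
}

# ---------------------------------------------------------------- points --

# uniform points in the configured extent (projected km)
uniform_xy <- function(config, n) {
  data.frame(x_km = config$x_min + stats::runif(n) * config$extent_km[1],
             y_km = config$y_min + stats::runif(n) * config$extent_km[2])
}

clamp_xy <- function(config, xy) {
  xy$x_km <- pmin(pmax(xy$x_km, config$x_min),
                  config$x_min + config$extent_km[1])
  xy$y_km <- pmin(pmax(xy$y_km, config$y_min),
                  config$y_min + config$extent_km[2])
  xy
}

as_occurrences <- function(xy, species, taxon_group) {
  ll <- unproject_points(xy)
  data.frame(taxon_group = taxon_group,
             species = species,
             lon = ll$lon, lat = ll$lat,
             precision_m = NA_real_,
             source = "synthetic",
             stringsAsFactors = FALSE)
}

#' Generate host-associated plant and insect point patterns
#'
#' Plants follow a Thomas-like parent-offspring process (parents uniform,
#' offspring Gaussian around their parent), giving a clustered pattern.
#' Each insect point is, with probability \code{association_rho}, a
#' randomly chosen plant point plus an isotropic Gaussian displacement of
#' s.d. \code{tether_sd_km}; otherwise it is uniform on the extent. Species
#' labels are assigned round-robin. rho is therefore directly the fraction
#' of insect localities spatially tied to the plant pattern, and is
#' recoverable from the density-surface correlation.
#'
#' @param config a \code{simulation_config}.
#' @return list with occurrence data.frames `plants` and `insects`.
#' @export
make_associated_points <- function(config) {
  set.seed(config$seed + 303L)
  n_p <- config$n_plant_points
  n_parents <- max(1, round(n_p / config$plants_per_parent))
  parents <- uniform_xy(config, n_parents)
  pick <- sample.int(n_parents, n_p, replace = TRUE)
  plants <- clamp_xy(config, data.frame(
    x_km = parents$x_km[pick] + stats::rnorm(n_p, sd = config$plant_cluster_sd_km),
    y_km = parents$y_km[pick] + stats::rnorm(n_p, sd = config$plant_cluster_sd_km)))

  n_i <- config$n_insect_points
  tethered <- stats::runif(n_i) < config$association_rho
  host <- sample.int(n_p, n_i, replace = TRUE)
  insects <- uniform_xy(config, n_i)
  if (any(tethered)) {
    insects$x_km[tethered] <- plants$x_km[host[tethered]] +
      stats::rnorm(sum(tethered), sd = config$tether_sd_km)
    insects$y_km[tethered] <- plants$y_km[host[tethered]] +
      stats::rnorm(sum(tethered), sd = config$tether_sd_km)
    insects <- clamp_xy(config, insects)
  }
  sp_p <- sprintf("plant_%03d",
                  rep_len(seq_len(config$n_plant_species), n_p))
  sp_i <- sprintf("insect_%03d",
                  rep_len(seq_len(config$n_insect_species), n_i))
  list(plants = as_occurrences(plants, sp_p, "plant"),
       insects = as_occurrences(insects, sp_i, "insect"))
}

#' Generate narrow-range endemic assemblages
#'
#' Each configured assemblage plants \code{k_species} species whose points
#' are drawn uniformly within a disc of radius \code{spread_km} around the
#' assemblage centre, so every species' area-of-influence radius is bounded
#' by twice the spread.
#'
#' @param config a \code{simulation_config}.
#' @return an occurrence data.frame (taxon_group `"endemic"`), with species
#'   named `<assemblage>_sp<k>`.
#' @export
make_endemic_assemblage <- function(config) {
  set.seed(config$seed + 404L)
  rows <- list()
  for (a_idx in seq_along(config$endemic_assemblages)) {
    a <- config$endemic_assemblages[[a_idx]]
    cen <- project_points(data.frame(lon = a$centre[1], lat = a$centre[2]))
    for (k in seq_len(a$k_species)) {
      n <- a$points_per_species
      if (a$spread_km == 0) {
        xy <- data.frame(x_km = rep(cen$x_km, n), y_km = rep(cen$y_km, n))
      } else {
        r <- a$spread_km * sqrt(stats::runif(n))
        th <- stats::runif(n, 0, 2 * pi)
        xy <- data.frame(x_km = cen$x_km + r * cos(th),
                         y_km = cen$y_km + r * sin(th))
      }
      rows[[length(rows) + 1]] <-
        as_occurrences(xy, sprintf("assemblage%d_sp%02d", a_idx, k),
                       "endemic")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
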