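small_cfg <- function(...) {
  args <- utils::modifyList(
    list(extent_km = c(1000, 800), cell_size_km = 25,
         n_patches = 12, n_plant_points = 300,
         n_plant_species = 10, n_insect_points = 100,
         n_insect_species = 5, seed = 5),
    list(...))
  do.call(simulation_config, args)
}

test_that("the Voronoi landscape partitions the extent", {
  cfg <- small_cfg()
  layer <- make_landscape(cfg)
  expect_s3_class(layer, "patch_layer")
  expect_length(layer, 12)
  total <- sum(vapply(layer, `[[`, 0, "area_km2"))
  expect_equal(total, prod(cfg$extent_km), tolerance = 1e-6)
  # single patch = the whole extent
  one <- make_landscape(small_cfg(n_patches = 1))
  expect_equal(one[[1]]$area_km2, prod(cfg$extent_km), tolerance = 1e-9)
})

test_that("landscape generation is deterministic per seed", {
  a <- make_landscape(small_cfg())
  b <- make_landscape(small_cfg())
  expect_identical(a, b)
  c2 <- make_landscape(small_cfg(seed = 6))
  expect_false(identical(a, c2))
})

test_that("climate layers: planar when noiseless, BIO5 >= BIO6, deterministic", {
  cfg0 <- small_cfg(climate_noise = 0)
  clim0 <- make_climate(cfg0)
  expect_named(clim0, paste0("BIO", 1:19))
  # zero noise -> every layer is an exact plane (least squares R^2 = 1)
  g <- config_grid(cfg0)
  cen <- grid_centres(g)
  xx <- rep(cen$x, each = g$n_rows)
  yy <- rep(cen$y, times = g$n_cols)
  for (nm in c("BIO1", "BIO7", "BIO12")) {
    z <- as.vector(clim0[[nm]]$values)
    resid <- lsfit(cbind(xx, yy), z)$residuals
    expect_lt(max(abs(resid)) / max(abs(z)), 1e-9)
  }
  # construction constraints
  clim <- make_climate(small_cfg())
  expect_true(all(clim$BIO5$values >= clim$BIO6$values))
  expect_equal(clim$BIO7$values, clim$BIO5$values - clim$BIO6$values)
  expect_true(all(clim$BIO12$values >= 0))
  # bit-identical per seed
  expect_identical(clim, make_climate(small_cfg()))
})

test_that("rho = 1 with zero tether pins every insect to a plant point", {
  cfg <- small_cfg(association_rho = 1, tether_sd_km = 0)
  pts <- make_associated_points(cfg)
  pl <- project_points(pts$plants[, c("lon", "lat")])
  ins <- project_points(pts$insects[, c("lon", "lat")])
  nearest <- vapply(seq_len(nrow(ins)), function(i) {
    min((pl$x_km - ins$x_km[i])^2 + (pl$y_km - ins$y_km[i])^2)
  }, 0)
  expect_lt(max(nearest), 1e-12)
})

test_that("rho = 0 insects are spatially uniform (nearest-plant distance test)", {
  # with n plant points on area A, the uniform expectation of the nearest-
  # plant distance is ~ 1/(2 sqrt(n/A)); check the Monte-Carlo mean over
  # seeds stays within 3 relative sd of the analytic value
  dists <- c()
  for (seed in 1:20) {
    cfg <- small_cfg(association_rho = 0, seed = seed)
    pts <- make_associated_points(cfg)
    pl <- project_points(pts$plants[, c("lon", "lat")])
    ins <- project_points(pts$insects[, c("lon", "lat")])
    d <- vapply(seq_len(nrow(ins)), function(i) {
      sqrt(min((pl$x_km - ins$x_km[i])^2 + (pl$y_km - ins$y_km[i])^2))
    }, 0)
    dists <- c(dists, mean(d))
  }
  # oracle: uniform insects over the same extent, averaged over seeds
  oracle <- c()
  set.seed(999)
  for (rep in 1:20) {
    cfg <- small_cfg(association_rho = 0, seed = rep)
    pts <- make_associated_points(cfg)
    pl <- project_points(pts$plants[, c("lon", "lat")])
    ux <- runif(100, min(cfg$x_min), cfg$x_min + cfg$extent_km[1])
    uy <- runif(100, min(cfg$y_min), cfg$y_min + cfg$extent_km[2])
    d <- vapply(seq_along(ux), function(i) {
      sqrt(min((pl$x_km - ux[i])^2 + (pl$y_km - uy[i])^2))
    }, 0)
    oracle <- c(oracle, mean(d))
  }
  expect_equal(mean(dists), mean(oracle), tolerance = 0.15)
})

test_that("generated occurrence tables pass cleaning with zero drops", {
  cfg <- small_cfg()
  pts <- make_associated_points(cfg)
  endems <- make_endemic_assemblage(cfg)
  for (tab in list(pts$plants, pts$insects, endems)) {
    out <- clean_occurrences(tab)
    expect_equal(out$report$n_retained, nrow(tab))
  }
})

test_that("endemic assemblages respect the construction radius bound", {
  cfg <- small_cfg(endemic_assemblages = list(
    list(k_species = 4, centre = c(12, -30), spread_km = 20,
         points_per_species = 6)))
  tab <- make_endemic_assemblage(cfg)
  expect_equal(length(unique(tab$species)), 4)
  ranges <- species_ranges(tab)
  radii <- vapply(ranges, `[[`, 0, "radius_km")
  expect_true(all(radii <= 2 * 20))
  # spread 20 km -> all class 1
  cls <- classify_ranges(ranges)
  expect_true(all(cls$class_id == 1))
  # zero spread -> all radii 0, centroids at the centre
  cfg0 <- small_cfg(endemic_assemblages = list(
    list(k_species = 2, centre = c(12, -30), spread_km = 0,
         points_per_species = 5)))
  r0 <- species_ranges(make_endemic_assemblage(cfg0))
  expect_true(all(vapply(r0, `[[`, 0, "radius_km") == 0))
  expect_equal(unname(r0[[1]]$centroid), c(12, -30), tolerance = 1e-9)
})

test_that("two distant assemblages yield exactly two class-1 endemism areas", {
  cfg <- simulation_config(extent_km = c(3000, 800), cell_size_km = 25,
                           n_patches = 5, seed = 11,
                           endemic_assemblages = list(
                             list(k_species = 4, centre = c(14, -30),
                                  spread_km = 20, points_per_species = 6),
                             list(k_species = 3, centre = c(33, -30),
                                  spread_km = 20, points_per_species = 6)))
  tab <- make_endemic_assemblage(cfg)
  ranges <- species_ranges(tab)
  cls <- endemism_classes()[1, ]
  surf <- gie_surface(ranges, config_grid(cfg), cls)
  aoe <- areas_of_endemism(surf, 2)
  expect_length(aoe$areas, 2)
  sp_sets <- lapply(aoe$areas, function(a) sort(a$species))
  expect_setequal(unlist(lapply(sp_sets, paste, collapse = ",")),
                  c(paste(sprintf("assemblage1_sp%02d", 1:4), collapse = ","),
                    paste(sprintf("assemblage2_sp%02d", 1:3), collapse = ",")))
})
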