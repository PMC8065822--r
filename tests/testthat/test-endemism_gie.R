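test_that("species ranges: centroid and farthest-point radius", {
  # all points identical -> radius 0, centroid = the point
  r0 <- species_range(rep(12, 4), rep(-3, 4))
  expect_equal(unname(r0$centroid), c(12, -3))
  expect_equal(r0$radius_km, 0)
  # two points 2 degrees apart on the equator
  r2 <- species_range(c(10, 12), c(0, 0))
  expect_equal(unname(r2$centroid[["lon"]]), 11)
  expect_equal(r2$radius_km, pi / 180 * 6371, tolerance = 1e-6)
  # exhaustive oracle over random points
  set.seed(14)
  lon <- runif(20, 20, 25); lat <- runif(20, -15, -10)
  r <- species_range(lon, lat)
  expect_equal(r$radius_km,
               max(haversine_km(r$centroid[["lon"]], r$centroid[["lat"]],
                                lon, lat)))
  expect_error(species_range(numeric(0), numeric(0)), "empty")
})

test_that("range classification uses disjoint (0,100] and (100,300] intervals", {
  mk <- function(radius) {
    structure(list(species = paste0("r", radius),
                   centroid = c(lon = 0, lat = 0),
                   radius_km = radius, n_points = 2L),
              class = "species_range")
  }
  cls <- classify_ranges(list(mk(0), mk(100), mk(100.0001), mk(250),
                              mk(500)))
  expect_equal(cls$class_id, c(1L, 1L, 2L, 2L, NA))
  nested <- classify_ranges(list(mk(50)), nested = TRUE)
  expect_equal(nested$class_id, c(1L, 2L))
})

test_that("GIE surfaces peak at 1 per species and superpose", {
  g <- make_grid(c(-410, -410, 410, 410), 20)
  cls <- endemism_classes()[1, ]
  sp <- function(lon, lat, name) {
    structure(list(species = name, centroid = c(lon = lon, lat = lat),
                   radius_km = 50, n_points = 3L),
              class = "species_range")
  }
  s1 <- gie_surface(list(sp(0, 0, "a")), g, cls)
  expect_equal(max(s1$raster$values), 1, tolerance = 0.01)
  # two coincident centroids -> max 2
  s2 <- gie_surface(list(sp(0, 0, "a"), sp(0, 0, "b")), g, cls)
  expect_equal(max(s2$raster$values), 2, tolerance = 0.02)
  expect_equal(s2$raster$values, 2 * s1$raster$values)  # additivity
  # centroids > 2h apart: kernels disjoint, max stays 1
  far <- unproject_points(data.frame(x_km = 300, y_km = 0))
  s3 <- gie_surface(list(sp(0, 0, "a"), sp(far$lon, far$lat, "b")), g, cls)
  expect_lte(max(s3$raster$values), 1)
  # empty class -> zero surface
  s0 <- gie_surface(list(), g, cls)
  expect_true(all(s0$raster$values == 0))
})

test_that("areas of endemism require the synendemic threshold", {
  g <- make_grid(c(-410, -410, 410, 410), 20)
  cls <- endemism_classes()[1, ]
  sp <- function(lon, lat, name) {
    structure(list(species = name, centroid = c(lon = lon, lat = lat),
                   radius_km = 50, n_points = 3L),
              class = "species_range")
  }
  # single species -> no areas at threshold 2
  one <- areas_of_endemism(gie_surface(list(sp(0, 0, "a")), g, cls), 2)
  expect_length(one$areas, 0)
  # two coincident species -> one area containing both
  two <- areas_of_endemism(gie_surface(list(sp(0, 0, "a"), sp(0, 0, "b")),
                                       g, cls), 2)
  expect_length(two$areas, 1)
  expect_setequal(two$areas[[1]]$species, c("a", "b"))
})

test_that("a planted 4-species cluster is recovered and distant species excluded", {
  g <- make_grid(c(-1500, -300, 1500, 300), 20)
  cls <- endemism_classes()[1, ]
  set.seed(27)
  near <- lapply(1:4, function(k) {
    off <- unproject_points(data.frame(x_km = runif(1, -10, 10),
                                       y_km = runif(1, -10, 10)))
    structure(list(species = paste0("near", k),
                   centroid = c(lon = off$lon, lat = off$lat),
                   radius_km = 30, n_points = 3L),
              class = "species_range")
  })
  far_ll <- unproject_points(data.frame(x_km = 1000, y_km = 0))
  far <- structure(list(species = "far",
                        centroid = c(lon = far_ll$lon, lat = far_ll$lat),
                        radius_km = 30, n_points = 3L),
                   class = "species_range")
  aoe <- areas_of_endemism(gie_surface(c(near, list(far)), g, cls), 2)
  expect_length(aoe$areas, 1)
  expect_setequal(aoe$areas[[1]]$species, paste0("near", 1:4))

  # monotone thresholding: lowering min_synendemic never removes an area
  aoe1 <- areas_of_endemism(gie_surface(c(near, list(far)), g, cls), 1)
  expect_gte(length(aoe1$areas), length(aoe$areas))
})

test_that("consensus maps keep class layers distinct and preserve nesting", {
  cfg <- simulation_config(extent_km = c(3000, 1000), n_patches = 5,
                           cell_size_km = 25, seed = 3,
                           endemic_assemblages = list(
                             list(k_species = 3, centre = c(20, -25),
                                  spread_km = 30, points_per_species = 5),
                             list(k_species = 3, centre = c(30, -25),
                                  spread_km = 180, points_per_species = 5)))
  tab <- make_endemic_assemblage(cfg)
  ranges <- species_ranges(tab)
  classes <- endemism_classes()
  assign <- classify_ranges(ranges, classes)
  expect_equal(sum(assign$class_id == 1, na.rm = TRUE), 3)
  expect_equal(sum(assign$class_id == 2, na.rm = TRUE), 3)
  g <- config_grid(cfg)
  a1 <- areas_of_endemism(
    gie_surface(ranges[assign$class_id == 1], g, classes[1, ]), 2)
  a2 <- areas_of_endemism(
    gie_surface(ranges[assign$class_id == 2], g, classes[2, ]), 2)
  cons <- consensus_map(list(a1, a2))
  expect_equal(sort(unique(cons$summary$class_id)), c(1L, 2L))
  expect_equal(nrow(cons$summary), length(a1$areas) + length(a2$areas))
  # one class only -> consensus is that class's areas
  solo <- consensus_map(list(a1))
  expect_equal(nrow(solo$summary), length(a1$areas))
})

test_that("consensus GeoJSON export writes valid labelled polygons", {
  g <- make_grid(c(-410, -410, 410, 410), 20)
  cls <- endemism_classes()[1, ]
  sp <- function(name) {
    structure(list(species = name, centroid = c(lon = 0, lat = 0),
                   radius_km = 50, n_points = 3L),
              class = "species_range")
  }
  aoe <- areas_of_endemism(gie_surface(list(sp("a"), sp("b")), g, cls), 2)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_consensus_geojson(consensus_map(list(aoe)), path)
  gj <- jsonlite::read_json(path)
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, 1)
  expect_equal(gj$features[[1]]$properties$class_id, 1)
  expect_setequal(unlist(gj$features[[1]]$properties$species), c("a", "b"))
  expect_equal(gj$features[[1]]$geometry$type, "MultiPolygon")
})
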