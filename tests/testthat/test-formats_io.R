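write_csv_fixture <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE)
  path
}

test_that("occurrence loading parses rows and logs failures, never drops silently", {
  path <- write_csv_fixture(data.frame(species = c("a", "b", "c"),
                                       lon = c(1, 2, 3), lat = c(4, 5, 6)))
  tab <- load_occurrences(path)
  expect_equal(nrow(tab), 3)
  expect_equal(nrow(attr(tab, "parse_failures")), 0)

  path2 <- write_csv_fixture(data.frame(species = c("a", "b"),
                                        lon = c(1, 2), lat = c("4", "abc")))
  tab2 <- load_occurrences(path2)
  expect_equal(nrow(tab2), 1)
  expect_equal(attr(tab2, "parse_failures")$row, 2)

  path3 <- write_csv_fixture(data.frame(sp = "a", x = 1, y = 2))
  expect_error(load_occurrences(path3), "missing mandatory columns")
})

test_that("a column_map with swapped lon/lat names recovers the unswapped table", {
  df <- data.frame(species = c("a", "b"), longitude = c(10, 20),
                   latitude = c(-5, 15))
  p1 <- write_csv_fixture(df)
  swapped <- data.frame(species = df$species, latitude = df$longitude,
                        longitude = df$latitude)
  p2 <- write_csv_fixture(swapped)
  t1 <- load_occurrences(p1, c(species = "species", lon = "longitude",
                               lat = "latitude"))
  t2 <- load_occurrences(p2, c(species = "species", lon = "latitude",
                               lat = "longitude"))
  expect_equal(t1$lon, t2$lon)
  expect_equal(t1$lat, t2$lat)
})

test_that("cleaning applies the documented drop rules and reconciles counts", {
  tab <- occ_table(c("spA", "spA", "spB", "spC"),
                   lon = c(10, 10, 11, 200), lat = c(10, 10, 12, 10))
  out <- clean_occurrences(tab)
  expect_equal(out$report$n_retained, 2)
  expect_equal(out$report$n_dropped_duplicate, 1)
  expect_equal(out$report$n_dropped_invalid_coord, 1)
  expect_equal(sort(out$table$species), c("spA", "spB"))

  empty <- clean_occurrences(tab[0, ])
  expect_equal(nrow(empty$table), 0)
  expect_true(all(unlist(empty$report[1:6]) == 0))

  # low precision dropped only when stated precision exceeds the threshold
  tab2 <- occ_table(c("a", "b", "c"), lon = 1:3, lat = 1:3,
                    precision_m = c(NA, 500, 50000))
  out2 <- clean_occurrences(tab2, max_uncertainty_m = 10000)
  expect_equal(out2$report$n_dropped_low_precision, 1)
  expect_equal(out2$report$n_retained, 2)
})

test_that("cleaning report counts reconcile and cleaning is idempotent", {
  set.seed(11)
  n <- 100
  tab <- occ_table(sample(paste0("sp", 1:8), n, replace = TRUE),
                   lon = round(runif(n, -20, 40), 3),
                   lat = round(runif(n, -30, 10), 3))
  dup_rows <- sample(n, 10)
  tab <- rbind(tab, tab[dup_rows, ])
  out <- clean_occurrences(tab)
  r <- out$report
  expect_equal(r$n_input,
               r$n_retained + r$n_dropped_duplicate + r$n_dropped_missing +
                 r$n_dropped_invalid_coord + r$n_dropped_low_precision)
  # set-based oracle: retained set equals unique (species, lon, lat)
  key <- function(t) paste(t$species, t$lon, t$lat)
  expect_gte(r$n_dropped_duplicate, 10)
  expect_setequal(key(out$table), unique(key(tab)))
  # idempotence
  out2 <- clean_occurrences(out$table)
  expect_equal(out2$table, out$table)
  expect_equal(out2$report$n_retained, out2$report$n_input)
})

test_that("GeoJSON patch layers load with multipolygons and reject duplicate ids", {
  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(id = "P1", name = "one"),
         geometry = list(type = "Polygon", coordinates = list(
           list(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))))),
    list(type = "Feature", properties = list(id = "P2", name = "two"),
         geometry = list(type = "MultiPolygon", coordinates = list(
           list(list(c(2, 0), c(3, 0), c(3, 1), c(2, 0))),
           list(list(c(4, 0), c(5, 0), c(5, 1), c(4, 0))))))))
  path <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  layer <- load_patches(path)
  expect_s3_class(layer, "patch_layer")
  expect_length(layer, 2)
  expect_length(layer[[2]]$parts, 2)  # multipolygon -> one patch, two parts

  gj$features[[2]]$properties$id <- "P1"
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  expect_error(load_patches(path), "duplicated patch_id.*P1")
})

test_that("patch layers survive a write/load GeoJSON round trip", {
  layer <- rect_patches(data.frame(id = c("A", "B"),
                                   xmin = c(0, 2), ymin = c(0, 0),
                                   xmax = c(1, 3), ymax = c(1, 1)))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_patches(layer, path)
  back <- load_patches(path)
  expect_equal(back[[1]]$patch_id, "A")
  expect_equal(back[[2]]$parts[[1]][[1]], layer[[2]]$parts[[1]][[1]])
})

test_that("raster round trips are bit-exact and preserve the nodata mask", {
  g <- make_grid(c(0, 0, 50, 50), 1)
  set.seed(3)
  v <- matrix(rnorm(2500), 50, 50)
  v[sample(2500, 40)] <- NA
  r <- grid_raster(g, v)
  for (fmt in c("ascii", "geotiff")) {
    path <- withr::local_tempfile()
    write_raster(r, path, fmt)
    back <- read_raster(path, fmt)
    expect_identical(back$values, r$values)
    expect_equal(unclass(back$spec), unclass(r$spec))
  }
})

test_that("a tiny raster of ones and a nodata pair survive the round trip", {
  g <- make_grid(c(0, 0, 3, 3), 1)
  v <- matrix(1, 3, 3)
  v[c(2, 7)] <- NA
  r <- grid_raster(g, v)
  path <- withr::local_tempfile()
  write_raster(r, path, "geotiff")
  back <- read_raster(path, "geotiff")
  expect_identical(back$values, v)
})
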