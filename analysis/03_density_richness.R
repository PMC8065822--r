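#!/usr/bin/env Rscript
# Stage 3: occurrence-density and species-richness surfaces. Point density
# (circular 100 km neighbourhood) and quartic kernel density (bandwidth
# 100 km) for plants and insects, then species richness on a 100 km square
# tessellation turned into a continuous surface by kernel-smoothing the
# richness-weighted cell centres.
#
# Reads:  results/clean/*.csv
# Writes: results/density/{pd,kde}_{plants,insects}.asc,
#         results/density/richness_{plants,insects}.{csv,asc}

library(endemapr)

out <- "results/density"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- simulation_config(seed = 1)
grid <- config_grid(cfg)
radius_km <- 100
bandwidth_km <- 100
resolution_km <- 100

for (nm in c("plants", "insects")) {
  tab <- read.csv(file.path("results/clean", paste0(nm, ".csv")))
  xy <- project_points(tab[, c("lon", "lat")])

  pd <- point_density(xy$x_km, xy$y_km, grid, radius_km)
  kde <- kernel_density(xy$x_km, xy$y_km, grid, bandwidth_km)
  write_raster(pd, file.path(out, paste0("pd_", nm, ".asc")), "ascii")
  write_raster(kde, file.path(out, paste0("kde_", nm, ".asc")), "ascii")

  cells <- richness_tessellation(tab, resolution_km,
                                 origin = c(cfg$x_min, cfg$y_min))
  surf <- richness_surface(cells, grid, bandwidth_km)
  write.csv(cells[, c("x_km", "y_km", "richness")],
            file.path(out, paste0("richness_", nm, ".csv")),
            row.names = FALSE)
  write_raster(surf, file.path(out, paste0("richness_", nm, ".asc")),
               "ascii")

  mass <- sum(kde$values) * grid$cell_size^2
  cat(sprintf("%-8s kde mass %.0f (of %d localities; deficit is edge loss), %d occupied richness cells, max richness %d\n",
              nm, mass, nrow(tab), nrow(cells), max(cells$richness)))
}
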