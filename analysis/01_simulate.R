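#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study system — a patchy Voronoi landscape,
# 19 bioclim rasters, a clustered plant point pattern with an insect pattern
# tethered to it (association strength 0.9), and two planted narrow-range
# endemic assemblages ~2000 km apart.
#
# Writes: results/simdata/{landscape.geojson, plants.csv, insects.csv,
#         endemics.csv, BIO*.asc, config.yaml}

library(endemapr)

out <- "results/simdata"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- simulation_config(seed = 1)
yaml::write_yaml(list(seed = cfg$seed, extent_km = cfg$extent_km,
                      n_patches = cfg$n_patches,
                      n_plant_points = cfg$n_plant_points,
                      n_insect_points = cfg$n_insect_points,
                      association_rho = cfg$association_rho,
                      tether_sd_km = cfg$tether_sd_km,
                      cell_size_km = cfg$cell_size_km),
                 file.path(out, "config.yaml"))

land <- make_landscape(cfg)
write_patches(land, file.path(out, "landscape.geojson"))
cat(sprintf("landscape: %d patches covering %.0f x %.0f km\n",
            length(land), cfg$extent_km[1], cfg$extent_km[2]))

pts <- make_associated_points(cfg)
write.csv(pts$plants, file.path(out, "plants.csv"), row.names = FALSE)
write.csv(pts$insects, file.path(out, "insects.csv"), row.names = FALSE)
cat(sprintf("points: %d plant localities (%d species), %d insect localities (%d species), rho = %.1f\n",
            nrow(pts$plants), length(unique(pts$plants$species)),
            nrow(pts$insects), length(unique(pts$insects$species)),
            cfg$association_rho))

endems <- make_endemic_assemblage(cfg)
write.csv(endems, file.path(out, "endemics.csv"), row.names = FALSE)
cat(sprintf("endemics: %d localities across %d planted species in %d assemblages\n",
            nrow(endems), length(unique(endems$species)),
            length(cfg$endemic_assemblages)))

clim <- make_climate(cfg)
for (nm in c("BIO1", "BIO7", "BIO14", "BIO18")) {
  write_raster(clim[[nm]], file.path(out, paste0(nm, ".asc")), "ascii")
}
cat("climate: 19 bioclim layers generated; BIO1/BIO7/BIO14/BIO18 written as ASCII grids\n")
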