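# End-to-end orchestration: simulate -> clean -> density/richness ->
# specificity -> association -> overlap -> endemism -> consensus, with a
# run manifest recording every effective knob and per-stage summaries.

PIPELINE_STAGES <- c("simulate", "clean", "density", "richness",
                     "specificity", "associate", "overlap", "endemism",
                     "consensus")

#' Run the full analysis pipeline on a synthetic landscape
#'
#' Executes the requested stages in dependency order. Every stage is a pure
#' function of (config, seed), so two runs with the same config produce
#' bit-identical results. When \code{out_dir} is given, each stage also
#' writes its outputs (CSV / JSON / GeoJSON / ASCII rasters) there.
#'
#' @param config a \code{simulation_config}, or a path to a YAML file whose
#'   keys are \code{simulation_config} arguments.
#' @param stages character subset of
#'   simulate, clean, density, richness, specificity, associate, overlap,
#'   endemism, consensus (dependencies are pulled in automatically).
#' @param out_dir optional output directory.
#' @param point_density_radius_km neighbourhood radius for the point-density
#'   surface, km.
#' @param kde_bandwidth_km kernel bandwidth for density and richness
#'   surfaces, km.
#' @param richness_resolution_km tessellation resolution, km.
#' @param min_synendemic threshold for areas of endemism.
#' @param verbose narrate stages to the console.
#' @return a \code{run_manifest}: list with `config`, `stages` (per-stage
#'   summary lists), and `results` (the in-memory stage outputs).
#' @export
run_pipeline <- function(config = simulation_config(),
                         stages = PIPELINE_STAGES,
                         out_dir = NULL,
                         point_density_radius_km = 100,
                         kde_bandwidth_km = 100,
                         richness_resolution_km = 100,
                         min_synendemic = 2,
                         verbose = FALSE) {
  if (is.character(config)) config <- config_from_yaml(config)
  stopifnot(inherits(config, "simulation_config"))
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  # pull in everything a requested stage depends on, keep canonical order
  deps <- list(simulate = character(), clean = "simulate",
               density = "clean", richness = "clean",
               specificity = "clean", associate = c("density", "richness"),
               overlap = "clean", endemism = "clean",
               consensus = "endemism")
  want <- stages
  repeat {
    more <- unique(unlist(deps[want]))
    if (all(more %in% want)) break
    want <- union(want, more)
  }
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% want]

  say <- function(...) if (verbose) message(sprintf(...))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  manifest <- list(config = unclass(config),
                   parameters = list(
                     point_density_radius_km = point_density_radius_km,
                     kde_bandwidth_km = kde_bandwidth_km,
                     richness_resolution_km = richness_resolution_km,
                     min_synendemic = min_synendemic),
                   stages = list())
  res <- list()
  grid <- config_grid(config)

  run_stage <- function(name, f) {
    out <- tryCatch(f(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    out
  }

  if ("simulate" %in% stages) {
    res$landscape <- run_stage("simulate", function() make_landscape(config))
    res$points <- run_stage("simulate", function() make_associated_points(config))
    res$endemics <- run_stage("simulate", function() make_endemic_assemblage(config))
    res$climate <- run_stage("simulate", function() make_climate(config, grid))
    manifest$stages$simulate <- list(
      n_patches = length(res$landscape),
      n_plant = nrow(res$points$plants),
      n_insect = nrow(res$points$insects),
      n_endemic = nrow(res$endemics))
    say("simulate: %d patches, %d plant + %d insect + %d endemic localities",
        length(res$landscape), nrow(res$points$plants),
        nrow(res$points$insects), nrow(res$endemics))
    if (!is.null(out_dir)) {
      write_patches(res$landscape, file.path(out_dir, "landscape.geojson"))
      utils::write.csv(res$points$plants,
                       file.path(out_dir, "plants.csv"), row.names = FALSE)
      utils::write.csv(res$points$insects,
                       file.path(out_dir, "insects.csv"), row.names = FALSE)
      utils::write.csv(res$endemics,
                       file.path(out_dir, "endemics.csv"), row.names = FALSE)
    }
  }

  if ("clean" %in% stages) {
    res$clean <- run_stage("clean", function() {
      lapply(list(plants = res$points$plants,
                  insects = res$points$insects,
                  endemics = res$endemics),
             clean_occurrences)
    })
    manifest$stages$clean <- lapply(res$clean,
                                    function(cl) unclass(cl$report))
    say("clean: retained %s",
        paste(vapply(res$clean, function(cl) cl$report$n_retained, 0),
              collapse = " / "))
    if (!is.null(out_dir)) {
      for (nm in names(res$clean)) {
        write_cleaning_report(res$clean[[nm]]$report,
                              file.path(out_dir,
                                        paste0("clean_", nm, ".json")))
      }
    }
  }

  proj_xy <- function(tab) project_points(tab[, c("lon", "lat")])

  if ("density" %in% stages) {
    res$density <- run_stage("density", function() {
      lapply(list(plants = res$clean$plants$table,
                  insects = res$clean$insects$table), function(tab) {
        xy <- proj_xy(tab)
        list(point = point_density(xy$x_km, xy$y_km, grid,
                                   point_density_radius_km),
             kernel = kernel_density(xy$x_km, xy$y_km, grid,
                                     kde_bandwidth_km))
      })
    })
    manifest$stages$density <- lapply(res$density, function(d) {
      list(point_max = raster_stats(d$point)$max,
           kernel_mass = raster_stats(d$kernel)$sum * grid$cell_size^2)
    })
    say("density: plant kernel mass %.1f, insect kernel mass %.1f",
        manifest$stages$density$plants$kernel_mass,
        manifest$stages$density$insects$kernel_mass)
    if (!is.null(out_dir)) {
      for (nm in names(res$density)) {
        write_raster(res$density[[nm]]$kernel,
                     file.path(out_dir, paste0("kde_", nm, ".asc")), "ascii")
      }
    }
  }

  if ("richness" %in% stages) {
    res$richness <- run_stage("richness", function() {
      lapply(list(plants = res$clean$plants$table,
                  insects = res$clean$insects$table), function(tab) {
        cells <- richness_tessellation(tab, richness_resolution_km,
                                       origin = c(config$x_min,
                                                  config$y_min))
        list(cells = cells,
             surface = richness_surface(cells, grid, kde_bandwidth_km))
      })
    })
    manifest$stages$richness <- lapply(res$richness, function(r) {
      list(n_cells = nrow(r$cells), total_richness = sum(r$cells$richness))
    })
    say("richness: %d plant cells, %d insect cells",
        nrow(res$richness$plants$cells), nrow(res$richness$insects$cells))
    if (!is.null(out_dir)) {
      for (nm in names(res$richness)) {
        utils::write.csv(res$richness[[nm]]$cells,
                         file.path(out_dir,
                                   paste0("richness_", nm, ".csv")),
                         row.names = FALSE)
      }
    }
  }

  if ("specificity" %in% stages) {
    res$specificity <- run_stage("specificity", function() {
      occ <- build_occupancy(res$clean$insects$table, res$landscape)
      list(occupancy = occ, scores = specificity_scores(occ))
    })
    manifest$stages$specificity <- list(
      n_species = length(res$specificity$occupancy$species_ids),
      n_patches_occupied = sum(res$specificity$scores$m_j > 0),
      S_total = sum(res$specificity$scores$S),
      unassigned = res$specificity$occupancy$unassigned)
    say("specificity: S sums to %.6f over %d species",
        sum(res$specificity$scores$S),
        length(res$specificity$occupancy$species_ids))
    if (!is.null(out_dir)) {
      write_specificity(res$specificity$scores,
                        file.path(out_dir, "specificity.csv"))
    }
  }

  if ("associate" %in% stages) {
    res$associate <- run_stage("associate", function() {
      pd <- raster_pearson(res$density$insects$kernel,
                           res$density$plants$kernel,
                           "insect_kde", "plant_kde")
      pr <- raster_pearson(res$richness$insects$surface,
                           res$richness$plants$surface,
                           "insect_richness", "plant_richness")
      profs <- list(
        climate_profile(res$clean$insects$table, res$climate, "insects"),
        climate_profile(res$clean$plants$table, res$climate, "plants"))
      dm <- euclidean_matrix(profs)
      list(pearson_density = pd, pearson_richness = pr,
           profiles = profs, dist = dm)
    })
    manifest$stages$associate <- list(
      r_density = res$associate$pearson_density$r,
      r_richness = res$associate$pearson_richness$r)
    say("associate: density r = %.3f, richness r = %.3f",
        res$associate$pearson_density$r, res$associate$pearson_richness$r)
    if (!is.null(out_dir)) {
      jsonlite::write_json(list(density = res$associate$pearson_density,
                                richness = res$associate$pearson_richness),
                           file.path(out_dir, "correlation.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  if ("overlap" %in% stages) {
    res$overlap <- run_stage("overlap", function() {
      vars <- c("BIO1", "BIO7", "BIO14", "BIO18")
      sample_at <- function(tab) {
        xy <- proj_xy(tab)
        idx <- cell_index(grid, xy$x_km, xy$y_km)
        ok <- !is.na(idx$row)
        vapply(vars, function(v) {
          res$climate[[v]]$values[cbind(idx$row[ok], idx$col[ok])]
        }, numeric(sum(ok)))
      }
      hyperoverlap_detect(sample_at(res$clean$insects$table),
                          sample_at(res$clean$plants$table),
                          label_a = "insects", label_b = "plants")
    })
    manifest$stages$overlap <- unclass(res$overlap)
    say("overlap: %s, %.1f%% misclassified",
        if (res$overlap$overlap) "overlap" else "no overlap",
        res$overlap$misclassified_percent)
    if (!is.null(out_dir)) {
      jsonlite::write_json(unclass(res$overlap),
                           file.path(out_dir, "overlap.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  if ("endemism" %in% stages) {
    res$endemism <- run_stage("endemism", function() {
      ranges <- species_ranges(res$clean$endemics$table)
      classes <- endemism_classes()
      assign <- classify_ranges(ranges, classes)
      per_class <- lapply(seq_len(nrow(classes)), function(ci) {
        cls <- classes[ci, ]
        in_cls <- vapply(ranges, function(r) {
          a <- assign$class_id[assign$species == r$species]
          !is.na(a) && a == cls$class_id
        }, TRUE)
        surf <- gie_surface(ranges[in_cls], grid, cls)
        areas_of_endemism(surf, min_synendemic)
      })
      list(ranges = ranges, assignment = assign, areas = per_class)
    })
    manifest$stages$endemism <- list(
      n_class1_areas = length(res$endemism$areas[[1]]$areas),
      n_class2_areas = length(res$endemism$areas[[2]]$areas))
    say("endemism: %d class-1 areas, %d class-2 areas",
        length(res$endemism$areas[[1]]$areas),
        length(res$endemism$areas[[2]]$areas))
  }

  if ("consensus" %in% stages) {
    res$consensus <- run_stage("consensus", function() {
      consensus_map(res$endemism$areas)
    })
    manifest$stages$consensus <- list(
      n_areas = nrow(res$consensus$summary))
    say("consensus: %d areas across classes",
        nrow(res$consensus$summary))
    if (!is.null(out_dir)) {
      write_consensus_geojson(res$consensus,
                              file.path(out_dir, "consensus.geojson"))
      utils::write.csv(res$consensus$summary,
                       file.path(out_dir, "consensus_summary.csv"),
                       row.names = FALSE)
    }
  }

  structure(list(config = manifest$config,
                 parameters = manifest$parameters,
                 stages = manifest$stages,
                 results = res),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("run_manifest: seed %d, stages: %s\n",
              x$config$seed, paste(names(x$stages), collapse = ", ")))
  invisible(x)
}

#' Read a simulation config from YAML
#'
#' Keys are \code{simulation_config} arguments; unknown keys error.
#'
#' @param path YAML file.
#' @return a \code{simulation_config}.
#' @export
config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(simulation_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!is.null(vals$extent_km)) vals$extent_km <- as.numeric(vals$extent_km)
  do.call(simulation_config, vals)
}
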