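#!/usr/bin/env Rscript
# Stage 2: load the simulated occurrence tables back from CSV (exercising
# the same i/o path a museum/GBIF export would take) and clean them:
# duplicates, missing fields, out-of-range coordinates, and low-precision
# records are dropped and accounted for.
#
# Reads:  results/simdata/*.csv
# Writes: results/clean/{plants,insects,endemics}.csv + _report.json

library(endemapr)

ind <- "results/simdata"
out <- "results/clean"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cmap <- c(species = "species", lon = "lon", lat = "lat",
          taxon_group = "taxon_group", precision_m = "precision_m",
          source = "source")

for (nm in c("plants", "insects", "endemics")) {
  tab <- load_occurrences(file.path(ind, paste0(nm, ".csv")), cmap)
  res <- clean_occurrences(tab, max_uncertainty_m = 10000)
  write.csv(res$table, file.path(out, paste0(nm, ".csv")), row.names = FALSE)
  write_cleaning_report(res$report,
                        file.path(out, paste0(nm, "_report.json")))
  r <- res$report
  cat(sprintf("%-9s %5d in -> %5d retained (%d dup, %d missing, %d bad coord, %d low precision)\n",
              nm, r$n_input, r$n_retained, r$n_dropped_duplicate,
              r$n_dropped_missing, r$n_dropped_invalid_coord,
              r$n_dropped_low_precision))
}
cat("synthetic tables are clean by construction: any drops above would flag a generator bug\n")
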