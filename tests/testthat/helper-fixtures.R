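# Shared fixtures and independent oracles used across test files.

# small occurrence table builder
occ_table <- function(species, lon, lat, taxon_group = "taxon",
                      precision_m = NA_real_) {
  data.frame(taxon_group = taxon_group, species = species,
             lon = lon, lat = lat,
             precision_m = precision_m, source = NA_character_,
             stringsAsFactors = FALSE)
}

# a unit-square patch layer: rectangles given as (id, xmin, ymin, xmax, ymax)
# in lon/lat degrees
rect_patches <- function(rects) {
  patches <- lapply(seq_len(nrow(rects)), function(i) {
    r <- rects[i, ]
    ring <- cbind(c(r$xmin, r$xmax, r$xmax, r$xmin, r$xmin),
                  c(r$ymin, r$ymin, r$ymax, r$ymax, r$ymin))
    list(patch_id = r$id, name = r$id, parts = list(list(ring)))
  })
  structure(patches, class = "patch_layer")
}

# independent spherical law-of-cosines distance (different formula from the
# haversine implementation)
slc_km <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  p1 <- lat1 * to_rad; p2 <- lat2 * to_rad
  dl <- (lon2 - lon1) * to_rad
  6371 * acos(pmin(1, pmax(-1, sin(p1) * sin(p2) +
                             cos(p1) * cos(p2) * cos(dl))))
}

# brute-force quartic kernel density at one cell centre
brute_quartic <- function(cx, cy, px, py, w, h) {
  d2 <- (px - cx)^2 + (py - cy)^2
  sum(ifelse(d2 < h^2, w * 3 / (pi * h^2) * (1 - d2 / h^2)^2, 0))
}

# independent WPGMA reference: stats::hclust method "mcquitty"
wpgma_reference <- function(d) {
  stats::hclust(stats::as.dist(d), method = "mcquitty")
}

# cophenetic matrix of a wpgma_tree, via the embedded hclust
coph <- function(obj) {
  hc <- if (inherits(obj, "wpgma_tree")) obj$hclust else obj
  as.matrix(stats::cophenetic(hc))
}

# random symmetric distance matrix with labelled leaves
random_dist <- function(n) {
  m <- matrix(stats::runif(n * n, 0.1, 10), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(letters[seq_len(n)], letters[seq_len(n)])
  m
}
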