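# Species x patch occupancy and the corrected Habitat Specificity index.
#
# The per-patch index is S_j = sum over the m_j species present in patch j
# of 1/n_i, where n_i is the number of patches species i occupies across the
# whole landscape. The "area" term of the original habitat-specificity
# formula is excluded (Halvorsen-Edvardsen correction), so the index depends
# only on incidence. Summed over patches it equals the number of retained
# species exactly: sum_j sum_{i in j} 1/n_i = sum_i n_i * (1/n_i).

# Even-odd ray-casting containment of many points in one ring.
# Returns logical crossing parity; boundary handling is done separately.
pip_ring <- function(ring, px, py) {
  inside <- rep(FALSE, length(px))
  n <- nrow(ring) - 1  # last vertex repeats the first
  xj <- ring[n, 1]; yj <- ring[n, 2]
  for (k in seq_len(n)) {
    xi <- ring[k, 1]; yi <- ring[k, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    xj <- xi; yj <- yi
  }
  inside
}

# TRUE where (px, py) lies on a segment of the ring, within tolerance.
on_ring <- function(ring, px, py, tol = 1e-9) {
  hit <- rep(FALSE, length(px))
  n <- nrow(ring) - 1
  for (k in seq_len(n)) {
    ax <- ring[k, 1]; ay <- ring[k, 2]
    bx <- ring[k + 1, 1]; by <- ring[k + 1, 2]
    cross <- (bx - ax) * (py - ay) - (by - ay) * (px - ax)
    dot <- (px - ax) * (bx - ax) + (py - ay) * (by - ay)
    len2 <- (bx - ax)^2 + (by - ay)^2
    seg_hit <- abs(cross) <= tol * max(1, sqrt(len2)) &
      dot >= -tol & dot <= len2 + tol
    hit <- hit | seg_hit
  }
  hit
}

#' Point-in-patch test
#'
#' Even-odd containment over all rings of all parts (outer rings minus
#' holes). Points exactly on a ring are reported separately so callers can
#' apply a deterministic boundary rule.
#'
#' @param patch one element of a \code{patch_layer}.
#' @param lon,lat point coordinates, decimal degrees.
#' @return list of logical vectors `inside` (strict interior) and
#'   `boundary`.
#' @export
point_in_patch <- function(patch, lon, lat) {
  inside <- rep(FALSE, length(lon))
  boundary <- rep(FALSE, length(lon))
  for (part in patch$parts) {
    for (ring in part) {
      inside <- xor(inside, pip_ring(ring, lon, lat))
      boundary <- boundary | on_ring(ring, lon, lat)
    }
  }
  list(inside = inside & !boundary, boundary = boundary)
}

#' Build the species x patch occupancy matrix
#'
#' Assigns each occurrence to the patch containing it. A point strictly
#' inside two patches is an error (patches must be disjoint); a point
#' exactly on a shared boundary is assigned deterministically to the patch
#' with the lexicographically smallest patch_id. Points in no patch are
#' counted as unassigned; species with all their points unassigned are
#' dropped from the matrix and listed.
#'
#' @param table cleaned occurrence data.frame (`species`, `lon`, `lat`).
#' @param patches a \code{patch_layer}.
#' @return object of class \code{occupancy_matrix}: list with `incidence`
#'   (binary species x patch matrix), `species_ids`, `patch_ids`, `n_i`
#'   (row sums: patches per species), `m_j` (column sums: species per
#'   patch), `patch_counts` (occurrence localities per patch),
#'   `assignment` (per-record patch_id or NA), `unassigned` (count),
#'   `dropped_species`.
#' @export
build_occupancy <- function(table, patches) {
  stopifnot(inherits(patches, "patch_layer"))
  patch_ids <- vapply(patches, `[[`, "", "patch_id")
  n_rec <- nrow(table)
  assignment <- rep(NA_character_, n_rec)
  boundary_claims <- vector("list", n_rec)
  if (n_rec > 0) {
    for (p in seq_along(patches)) {
      hit <- point_in_patch(patches[[p]], table$lon, table$lat)
      clash <- hit$inside & !is.na(assignment)
      if (any(clash)) {
        stop("overlapping patches: record strictly inside both '",
             assignment[which(clash)[1]], "' and '", patch_ids[p], "'",
             call. = FALSE)
      }
      assignment[hit$inside] <- patch_ids[p]
      for (i in which(hit$boundary)) {
        boundary_claims[[i]] <- c(boundary_claims[[i]], patch_ids[p])
      }
    }
    # boundary rule: smallest patch_id among claimants, but only for records
    # not already strictly inside a patch
    for (i in which(!vapply(boundary_claims, is.null, TRUE))) {
      if (is.na(assignment[i])) {
        assignment[i] <- min(boundary_claims[[i]])
      }
    }
  }
  unassigned <- sum(is.na(assignment))
  assigned <- !is.na(assignment)
  species_all <- sort(unique(table$species))
  species_ids <- sort(unique(table$species[assigned]))
  dropped <- setdiff(species_all, species_ids)
  incidence <- matrix(0L, nrow = length(species_ids), ncol = length(patch_ids),
                      dimnames = list(species_ids, patch_ids))
  if (any(assigned)) {
    pairs <- unique(data.frame(sp = table$species[assigned],
                               pa = assignment[assigned]))
    incidence[cbind(match(pairs$sp, species_ids),
                    match(pairs$pa, patch_ids))] <- 1L
  }
  patch_counts <- table(factor(assignment[assigned], levels = patch_ids))
  structure(list(incidence = incidence,
                 species_ids = species_ids,
                 patch_ids = patch_ids,
                 n_i = rowSums(incidence),
                 m_j = colSums(incidence),
                 patch_counts = as.integer(patch_counts),
                 assignment = assignment,
                 unassigned = unassigned,
                 n_localities = n_rec,
                 dropped_species = dropped),
            class = "occupancy_matrix")
}

#' @export
print.occupancy_matrix <- function(x, ...) {
  cat(sprintf("occupancy_matrix: %d species x %d patches; %d unassigned localities\n",
              length(x$species_ids), length(x$patch_ids), x$unassigned))
  invisible(x)
}

#' Corrected Habitat Specificity scores per patch
#'
#' S_j = sum over species present in patch j of 1 / n_i (inverse
#' patch-occupancy), plus each patch's share of all occurrence localities.
#' The scores are incidence-based: extra localities of a species inside a
#' patch do not change S_j. Conservation: sum_j S_j equals the number of
#' retained species exactly.
#'
#' @param occ an \code{occupancy_matrix}.
#' @return data.frame with columns `patch_id`, `S`, `occurrence_percent`,
#'   `m_j`, `n_localities`.
#' @export
specificity_scores <- function(occ) {
  stopifnot(inherits(occ, "occupancy_matrix"))
  if (length(occ$species_ids) == 0) {
    return(data.frame(patch_id = occ$patch_ids,
                      S = rep(0, length(occ$patch_ids)),
                      occurrence_percent = rep(0, length(occ$patch_ids)),
                      m_j = rep(0L, length(occ$patch_ids)),
                      n_localities = rep(0L, length(occ$patch_ids))))
  }
  inv_n <- 1 / occ$n_i
  S <- as.numeric(crossprod(occ$incidence, inv_n))
  total <- occ$n_localities
  data.frame(patch_id = occ$patch_ids,
             S = S,
             occurrence_percent = if (total > 0) {
               100 * occ$patch_counts / total
             } else {
               rep(0, length(occ$patch_ids))
             },
             m_j = as.integer(occ$m_j),
             n_localities = occ$patch_counts)
}

#' Write specificity scores as CSV
#'
#' @param scores output of \code{specificity_scores}.
#' @param path output file.
#' @export
write_specificity <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}
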