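# Insect-plant association statistics: raster band correlation, per-taxon
# bioclim profiles, WPGMA clustering of those profiles, and SVM-based
# climatic niche-overlap detection.

#' Pearson correlation between two rasters
#'
#' Correlation over cells valid (non-nodata) in both rasters — the "band
#' collection statistics" comparison of two density surfaces on a shared
#' grid.
#'
#' @param a,b \code{grid_raster}s on the same \code{grid_spec}.
#' @param name_a,name_b identifiers carried into the report.
#' @return list: `raster_a`, `raster_b`, `r`, `n_cells`.
#' @export
raster_pearson <- function(a, b, name_a = "a", name_b = "b") {
  if (!identical(unclass(a$spec), unclass(b$spec))) {
    stop("rasters are on different grids", call. = FALSE)
  }
  ok <- !is.na(a$values) & !is.na(b$values)
  va <- a$values[ok]; vb <- b$values[ok]
  if (length(va) < 2) stop("fewer than 2 jointly valid cells", call. = FALSE)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("undefined correlation: a band has zero variance", call. = FALSE)
  }
  list(raster_a = name_a, raster_b = name_b,
       r = stats::cor(va, vb), n_cells = length(va))
}

#' Mean bioclim profile of a taxon
#'
#' Samples every climate raster at each occurrence and averages. Occurrences
#' falling on nodata (or off the grid) are excluded per variable and
#' counted.
#'
#' @param table occurrence data.frame (`lon`, `lat`) for one taxon.
#' @param rasters named list of \code{grid_raster}s sharing one grid.
#' @param taxon label for the profile.
#' @return list of class \code{climate_profile}: `taxon`, `means` (named
#'   numeric), `n_used`, `n_excluded` (named, per variable).
#' @export
climate_profile <- function(table, rasters, taxon = "taxon") {
  stopifnot(length(rasters) >= 1)
  spec <- rasters[[1]]$spec
  for (r in rasters) {
    if (!identical(unclass(r$spec), unclass(spec))) {
      stop("climate rasters are on different grids", call. = FALSE)
    }
  }
  xy <- project_points(table[, c("lon", "lat")], spec$projection_tag)
  idx <- cell_index(spec, xy$x_km, xy$y_km)
  on_grid <- !is.na(idx$row)
  if (!any(on_grid)) stop("all occurrences fall outside the grid",
                          call. = FALSE)
  means <- numeric(length(rasters))
  n_used <- integer(length(rasters))
  names(means) <- names(n_used) <- names(rasters)
  for (k in seq_along(rasters)) {
    v <- rep(NA_real_, nrow(table))
    v[on_grid] <- rasters[[k]]$values[cbind(idx$row[on_grid],
                                            idx$col[on_grid])]
    ok <- !is.na(v)
    if (!any(ok)) stop("all occurrences on nodata for variable ",
                       names(rasters)[k], call. = FALSE)
    means[k] <- mean(v[ok])
    n_used[k] <- sum(ok)
  }
  structure(list(taxon = taxon, means = means, n_used = n_used,
                 n_excluded = nrow(table) - n_used),
            class = "climate_profile")
}

#' Pairwise Euclidean distances between climate profiles
#'
#' @param profiles list of \code{climate_profile}s (or a matrix with taxa as
#'   rows and variables as columns).
#' @param standardize if TRUE, z-score each variable across profiles before
#'   computing distances. Default FALSE: raw variable scales, where
#'   large-magnitude variables (e.g. temperature seasonality, annual
#'   precipitation) dominate.
#' @return a symmetric distance matrix with taxon dimnames.
#' @export
euclidean_matrix <- function(profiles, standardize = FALSE) {
  if (is.matrix(profiles)) {
    m <- profiles
  } else {
    vars <- names(profiles[[1]]$means)
    for (p in profiles) {
      if (!identical(names(p$means), vars)) {
        stop("profiles carry different variable sets", call. = FALSE)
      }
      if (!all(is.finite(p$means))) stop("non-finite profile value",
                                         call. = FALSE)
    }
    m <- do.call(rbind, lapply(profiles, `[[`, "means"))
    rownames(m) <- vapply(profiles, `[[`, "", "taxon")
  }
  if (nrow(m) < 2) stop("need at least 2 profiles", call. = FALSE)
  if (standardize) m <- scale(m)
  as.matrix(stats::dist(m, method = "euclidean"))
}

#' WPGMA (McQuitty) hierarchical clustering
#'
#' Agglomerative clustering that repeatedly merges the closest pair of
#' clusters at a height equal to their current distance; the merged
#' cluster's distance to any other is the simple average (d1 + d2) / 2 of
#' its two members' distances, regardless of cluster sizes. Heights are
#' therefore non-decreasing. Ties on the minimum distance are broken
#' lexicographically on the (sorted) pair of cluster labels, where a
#' cluster's label is the smallest leaf label it contains.
#'
#' @param dist_mat symmetric distance matrix with dimnames (or a
#'   \code{dist}).
#' @return object of class \code{wpgma_tree}: list with `labels`, `merges`
#'   (data.frame: `a`, `b` — cluster labels, `height`), and `hclust` (the
#'   equivalent \code{stats::hclust} object, usable with
#'   \code{stats::cophenetic} and \code{ape::as.phylo}).
#' @export
wpgma <- function(dist_mat) {
  if (inherits(dist_mat, "dist")) dist_mat <- as.matrix(dist_mat)
  n <- nrow(dist_mat)
  if (n < 2) stop("need at least 2 leaves", call. = FALSE)
  if (!isSymmetric(unname(dist_mat), tol = 1e-12)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(dist_mat < 0)) stop("distances must be non-negative", call. = FALSE)
  labels <- rownames(dist_mat)
  if (is.null(labels)) labels <- paste0("L", seq_len(n))

  d <- dist_mat
  # active clusters tracked by: representative label (smallest member leaf),
  # hclust node id (negative = leaf), member count
  lab <- labels
  node <- -seq_len(n)
  active <- rep(TRUE, n)
  merge <- matrix(0L, nrow = n - 1, ncol = 2)
  height <- numeric(n - 1)
  merges_a <- merges_b <- character(n - 1)

  for (step in seq_len(n - 1)) {
    idx <- which(active)
    best <- NULL
    for (ii in seq_along(idx)[-length(idx)]) {
      for (jj in (ii + 1):length(idx)) {
        i <- idx[ii]; j <- idx[jj]
        dij <- d[i, j]
        pair_lab <- sort(c(lab[i], lab[j]))
        cand <- list(d = dij, i = i, j = j, lab = pair_lab)
        if (is.null(best) || dij < best$d ||
            (dij == best$d && (pair_lab[1] < best$lab[1] ||
                               (pair_lab[1] == best$lab[1] &&
                                pair_lab[2] < best$lab[2])))) {
          best <- cand
        }
      }
    }
    i <- best$i; j <- best$j
    height[step] <- best$d
    merge[step, ] <- sort(c(node[i], node[j]))
    merges_a[step] <- best$lab[1]
    merges_b[step] <- best$lab[2]
    # WPGMA update: plain average of the two merged clusters' distances
    for (k in idx) {
      if (k != i && k != j) {
        dk <- (d[i, k] + d[j, k]) / 2
        d[i, k] <- d[k, i] <- dk
      }
    }
    lab[i] <- min(lab[i], lab[j])
    node[i] <- step
    active[j] <- FALSE
  }

  hc <- structure(list(merge = merge, height = height,
                       order = hclust_order(merge, n),
                       labels = labels, method = "mcquitty",
                       call = match.call(), dist.method = "euclidean"),
                  class = "hclust")
  structure(list(labels = labels,
                 merges = data.frame(a = merges_a, b = merges_b,
                                     height = height,
                                     stringsAsFactors = FALSE),
                 hclust = hc),
            class = "wpgma_tree")
}

# leaf ordering for a valid hclust object (left-to-right traversal)
hclust_order <- function(merge, n) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  as.integer(walk(nrow(merge)))
}

#' @export
print.wpgma_tree <- function(x, ...) {
  cat(sprintf("wpgma_tree: %d leaves\n", length(x$labels)))
  for (i in seq_len(nrow(x$merges))) {
    cat(sprintf("  merge %d: {%s} + {%s} at height %.4g\n",
                i, x$merges$a[i], x$merges$b[i], x$merges$height[i]))
  }
  invisible(x)
}

#' Export a WPGMA tree as Newick
#'
#' Branch lengths are derived from merge heights (ultrametric: leaf depth =
#' half the root height under the usual hclust-to-phylo conversion).
#'
#' @param tree a \code{wpgma_tree}.
#' @param path optional file; if NULL the Newick string is returned.
#' @return the Newick string, invisibly if written to file.
#' @export
wpgma_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree$hclust)
  s <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Climatic niche overlap via support-vector classification
#'
#' Two taxa's environmental point clouds are declared non-overlapping iff
#' some decision boundary separates them perfectly. A near-hard-margin
#' linear SVM is tried first; if it misclassifies any training point, a
#' polynomial-kernel SVM is tried; if that still misclassifies points the
#' niches overlap, and the misclassified count from the polynomial stage
#' quantifies the overlap depth.
#'
#' @param points_a,points_b numeric matrices / data.frames of environmental
#'   attributes (same columns), one row per occurrence; typically the four
#'   bioclim variables BIO1, BIO7, BIO14, BIO18.
#' @param degree polynomial kernel degree (default 3).
#' @param cost regularization constant (default 1e3: near-hard margin).
#' @param coef0 polynomial kernel offset (default 1, so lower-order terms
#'   are included).
#' @param label_a,label_b taxon labels for the report.
#' @return list of class \code{overlap_report}: `pair`, `overlap`,
#'   `boundary_shape` ("linear" or "polynomial"), `n_misclassified`,
#'   `misclassified_percent`, `n_support_vectors`, `n_a`, `n_b`.
#' @export
hyperoverlap_detect <- function(points_a, points_b, degree = 3, cost = 1e3,
                                coef0 = 1, label_a = "A", label_b = "B") {
  points_a <- as.matrix(points_a)
  points_b <- as.matrix(points_b)
  if (ncol(points_a) != ncol(points_b)) {
    stop("attribute sets differ between groups", call. = FALSE)
  }
  if (nrow(points_a) < 2 || nrow(points_b) < 2) {
    stop("need at least 2 points per group", call. = FALSE)
  }
  if (!all(is.finite(points_a)) || !all(is.finite(points_b))) {
    stop("attributes must be finite", call. = FALSE)
  }
  x <- rbind(points_a, points_b)
  colnames(x) <- paste0("v", seq_len(ncol(x)))
  y <- factor(c(rep("A", nrow(points_a)), rep("B", nrow(points_b))))
  # standardize internally (zero-variance attributes left unscaled): an
  # affine transform that changes no separability outcome but keeps the
  # kernel matrices well conditioned when attributes differ by orders of
  # magnitude (e.g. precipitation vs temperature)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  x <- scale(x, center = mu, scale = sdv)

  fit_stage <- function(kernel) {
    m <- tryCatch(
      e1071::svm(x, y, kernel = kernel, degree = degree, cost = cost,
                 coef0 = coef0, scale = FALSE),
      error = function(e) NULL)
    if (is.null(m)) return(NULL)
    pred <- stats::predict(m, x)
    list(n_mis = sum(pred != y), n_sv = m$tot.nSV)
  }

  lin <- fit_stage("linear")
  if (!is.null(lin) && lin$n_mis == 0) {
    res <- list(overlap = FALSE, boundary_shape = "linear",
                n_misclassified = 0L, n_support_vectors = lin$n_sv)
  } else {
    pol <- fit_stage("polynomial")
    if (is.null(pol)) {
      # degenerate input (e.g. both groups a single duplicated point):
      # indistinguishable classes overlap completely
      pol <- list(n_mis = min(nrow(points_a), nrow(points_b)),
                  n_sv = nrow(x))
    }
    res <- list(overlap = pol$n_mis > 0,
                boundary_shape = "polynomial",
                n_misclassified = as.integer(pol$n_mis),
                n_support_vectors = pol$n_sv)
  }
  n_tot <- nrow(x)
  structure(c(list(pair = c(label_a, label_b)), res,
              list(misclassified_percent = 100 * res$n_misclassified / n_tot,
                   n_a = nrow(points_a), n_b = nrow(points_b))),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap_report %s-%s: %s (%s boundary), %d misclassified (%.1f%%), %d SVs\n",
              x$pair[1], x$pair[2],
              if (x$overlap) "overlap" else "no overlap",
              x$boundary_shape, x$n_misclassified,
              x$misclassified_percent, x$n_support_vectors))
  invisible(x)
}

#' Bundled mean bioclim profiles of the five study taxa
#'
#' Published per-taxon averages of the 19 bioclim variables (BIO1..BIO19;
#' degrees C, mm, or percent depending on the variable) for three flea
#' beetle taxa (Afroblepharida, Blepharidina, Calotheca) and two host-plant
#' genera (Searsia, Commiphora). Useful as a realistic worked example for
#' \code{euclidean_matrix} and \code{wpgma}.
#'
#' @return a matrix with taxa as rows and BIO1..BIO19 as columns.
#' @export
taxon_climate_means <- function() {
  path <- system.file("extdata", "bioclim_taxon_means.csv",
                      package = "endemapr")
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  t(m)
}
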