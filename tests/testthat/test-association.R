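make_r <- function(vals, g = NULL) {
  if (is.null(g)) g <- make_grid(c(0, 0, ncol(vals), nrow(vals)), 1)
  grid_raster(g, vals)
}

test_that("raster Pearson correlation matches hand-computed cases", {
  set.seed(2)
  a <- make_r(matrix(rnorm(12), 3, 4))
  expect_equal(raster_pearson(a, a)$r, 1)
  b <- make_r(5 - a$values)
  expect_equal(raster_pearson(a, b)$r, -1)
  # hand case: a = (1,2,3), b = (6,5,1): r = -5 / sqrt(28)
  a3 <- make_r(matrix(c(1, 2, 3), 1, 3))
  b3 <- make_r(matrix(c(6, 5, 1), 1, 3))
  expect_equal(raster_pearson(a3, b3)$r, -5 / sqrt(28))
  expect_equal(-5 / sqrt(28), -0.9449, tolerance = 1e-4)
  # symmetry and affine invariance
  expect_equal(raster_pearson(a3, b3)$r, raster_pearson(b3, a3)$r)
  expect_equal(raster_pearson(make_r(2 * a3$values + 7), b3)$r,
               raster_pearson(a3, b3)$r)
})

test_that("raster Pearson excludes nodata cells and rejects bad input", {
  v1 <- matrix(c(1, 2, 3, 4), 2, 2)
  v2 <- matrix(c(4, 3, 2, 1), 2, 2)
  v1[1, 1] <- NA
  r <- raster_pearson(make_r(v1), make_r(v2))
  expect_equal(r$n_cells, 3)
  expect_equal(r$r, stats::cor(v1[-1], v2[-1]))
  expect_error(raster_pearson(make_r(v2), make_r(matrix(1, 2, 2))),
               "zero variance")
  g2 <- make_grid(c(0, 0, 2, 2), 2)
  expect_error(raster_pearson(make_r(v2), grid_raster(g2, 1)),
               "different grids")
})

test_that("climate profiles average raster values at occurrences", {
  g <- make_grid(c(-200, -200, 400, 400), 10)
  const <- grid_raster(g, 7)
  tab <- occ_table(c("x", "x"), lon = c(0.5, 1.5), lat = c(0.5, 0.5))
  p <- climate_profile(tab, list(BIO1 = const), "t")
  expect_equal(unname(p$means["BIO1"]), 7)
  # gradient raster: mean equals per-point cell lookup
  set.seed(4)
  grad <- grid_raster(g, outer(seq_len(g$n_rows), seq_len(g$n_cols), `+`) * 1.5)
  n <- 100
  tab2 <- occ_table(rep("x", n), lon = runif(n, -1, 3), lat = runif(n, -1, 3))
  p2 <- climate_profile(tab2, list(G = grad), "t")
  xy <- project_points(tab2[, c("lon", "lat")])
  idx <- cell_index(g, xy$x_km, xy$y_km)
  expect_equal(unname(p2$means["G"]),
               mean(grad$values[cbind(idx$row, idx$col)]))
  # nodata exclusion is counted
  grad$values[cbind(idx$row[1:5], idx$col[1:5])] <- NA
  p3 <- climate_profile(tab2, list(G = grad), "t")
  expect_gte(unname(p3$n_excluded["G"]), 1)
  expect_error(climate_profile(occ_table("x", 150, 80), list(G = grad)),
               "outside the grid")
})

test_that("the published taxon profiles put Calotheca closest to Searsia", {
  m <- taxon_climate_means()
  expect_equal(dim(m), c(5, 19))
  d <- euclidean_matrix(m)
  # independent summation of the 19 squared differences
  direct <- sqrt(sum((m["Calotheca", ] - m["Searsia", ])^2))
  expect_equal(d["Calotheca", "Searsia"], direct)
  expect_equal(direct, 77.8, tolerance = 0.001 * 77.8)
  # brute force over all 10 pairs: the minimum is Calotheca-Searsia
  pairs <- t(combn(rownames(m), 2))
  dd <- apply(pairs, 1, function(p) d[p[1], p[2]])
  expect_equal(sort(unname(c(pairs[which.min(dd), ]))),
               c("Calotheca", "Searsia"))
  # WPGMA first merge pairs them
  tree <- wpgma(d)
  expect_equal(sort(c(tree$merges$a[1], tree$merges$b[1])),
               c("Calotheca", "Searsia"))
})

test_that("euclidean_matrix handles identical profiles and standardization", {
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(4, 8, 3))
  d <- euclidean_matrix(m)
  expect_equal(d["a", "b"], 0)
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 3))
  dz <- euclidean_matrix(m, standardize = TRUE)
  expect_equal(dz["a", "b"], 0)
  expect_gt(dz["a", "c"], 0)
})

test_that("WPGMA reproduces the hand-traced 3-leaf example", {
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "B"] <- d["B", "A"] <- 2
  d["A", "C"] <- d["C", "A"] <- 4
  d["B", "C"] <- d["C", "B"] <- 6
  tr <- wpgma(d)
  expect_equal(tr$merges$height, c(2, 5))
  expect_equal(c(tr$merges$a[1], tr$merges$b[1]), c("A", "B"))
  # 2-leaf case: single merge at the distance
  d2 <- matrix(c(0, 3.5, 3.5, 0), 2, 2,
               dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(wpgma(d2)$merges$height, 3.5)
  expect_error(wpgma(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("WPGMA agrees with the stats::hclust mcquitty reference on random matrices", {
  set.seed(19)
  for (rep in 1:200) {
    n <- sample(3:8, 1)
    d <- random_dist(n)
    tr <- wpgma(d)
    ref <- wpgma_reference(d)
    expect_equal(sort(tr$hclust$height), sort(ref$height), tolerance = 1e-12)
    expect_equal(coph(tr), coph(ref), tolerance = 1e-12)
    expect_true(all(diff(tr$merges$height) >= -1e-12))  # inversion-free
  }
})

test_that("WPGMA tie-breaks lexicographically on cluster labels", {
  # two pairs share the minimal distance 1: (a,d) and (b,c); (a,d) first
  d <- matrix(10, 4, 4,
              dimnames = list(c("a", "b", "c", "d"), c("a", "b", "c", "d")))
  diag(d) <- 0
  d["a", "d"] <- d["d", "a"] <- 1
  d["b", "c"] <- d["c", "b"] <- 1
  tr <- wpgma(d)
  expect_equal(c(tr$merges$a[1], tr$merges$b[1]), c("a", "d"))
  expect_equal(c(tr$merges$a[2], tr$merges$b[2]), c("b", "c"))
})

test_that("WPGMA trees export as Newick with all leaves", {
  d <- random_dist(5)
  nwk <- wpgma_newick(wpgma(d))
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, letters[1:5])
  expect_true(ape::is.ultrametric(phy, tol = 1e-8))
})

test_that("niche overlap detection: separable, identical, and XOR clouds", {
  # well separated -> linear boundary, no overlap
  a <- rbind(c(0, 0), c(0, 1))
  b <- rbind(c(5, 5), c(5, 6))
  rep1 <- hyperoverlap_detect(a, b)
  expect_false(rep1$overlap)
  expect_equal(rep1$boundary_shape, "linear")
  expect_equal(rep1$n_misclassified, 0L)

  # identical point sets -> indistinguishable, at least half misclassified
  set.seed(6)
  pts <- matrix(rnorm(40), 20, 2)
  rep2 <- hyperoverlap_detect(pts, pts)
  expect_true(rep2$overlap)
  expect_gte(rep2$misclassified_percent, 50)

  # XOR: linear stage fails, polynomial separates -> no overlap
  rep3 <- hyperoverlap_detect(rbind(c(0, 0), c(1, 1)),
                              rbind(c(0, 1), c(1, 0)))
  expect_false(rep3$overlap)
  expect_equal(rep3$boundary_shape, "polynomial")
})

test_that("niche overlap detection is label-symmetric", {
  set.seed(8)
  a <- matrix(rnorm(30, 0), 15, 2)
  b <- matrix(rnorm(30, 1), 15, 2)
  r1 <- hyperoverlap_detect(a, b, label_a = "A", label_b = "B")
  r2 <- hyperoverlap_detect(b, a, label_a = "B", label_b = "A")
  expect_equal(r1$overlap, r2$overlap)
  expect_equal(r1$boundary_shape, r2$boundary_shape)
  expect_equal(r1$n_misclassified, r2$n_misclassified)
  expect_equal(r1$misclassified_percent, r2$misclassified_percent)
})

test_that("degenerate duplicated-point groups are handled, not fatal", {
  a <- rbind(c(0, 0), c(0, 0))
  b <- rbind(c(0, 0), c(0, 0))
  rep <- hyperoverlap_detect(a, b)
  expect_true(rep$overlap)
  expect_error(hyperoverlap_detect(rbind(c(0, 0)), b), "at least 2")
})
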