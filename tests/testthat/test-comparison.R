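# Pseudotime binning, bin distances and mapping, layout, clustering,
# differential expression, signature scores.

fake_ds <- function(u) {
  structure(list(eigenvalues = c(1, rep(0.5, ncol(u))),
                 psi = cbind(1, u), n_selected = ncol(u), u = as.matrix(u)),
            class = "diffusion_space")
}

test_that("equal-width bins follow the histogram edges", {
  p <- pseudotime_bins(c(0.01, 0.99), n_bins = 2)
  expect_equal(p$cell_bins$interval, c(1L, 2L))

  set.seed(1)
  pt <- runif(500)
  p2 <- pseudotime_bins(pt, 20)
  expect_equal(p2$cell_bins$interval, pmin(floor(pt * 20), 19) + 1L)
  expect_equal(formals(pseudotime_bins)$n_bins, 20L)
  expect_error(pseudotime_bins(pt, 1), "at least 2")
  expect_warning(pseudotime_bins(c(0.05, 0.95), 10), "empty")
})

test_that("stratified bins never mix lineage labels", {
  set.seed(2)
  pt <- runif(200)
  lab <- sample(c("ICM", "EPI", "PrE"), 200, replace = TRUE)
  p <- pseudotime_bins(pt, 10, stratify_by = lab)
  per_bin <- split(lab, p$cell_bins$bin)
  expect_true(all(vapply(per_bin, function(x) length(unique(x)) == 1L,
                         logical(1))))
})

test_that("bin distances equal the brute-force mean pair distance", {
  u <- matrix(c(0, 1, 2), 3, 1)
  ds <- fake_ds(u)
  pa <- pseudotime_bins(c(0.1, 0.1, 0.9), 2)   # bin1 = {1,2}, bin2 = {3}
  pb <- pseudotime_bins(c(0.9), 2)
  suppressWarnings({
    pa <- pseudotime_bins(c(0.1, 0.1), 2)
  })
  # bins A = {cells 1,2} (coords 0,1), bin B = {cell 3} (coord 2)
  suppressWarnings({
    bd <- bin_distance_matrix(ds, pseudotime_bins(c(0.1, 0.1), 2),
                              pseudotime_bins(c(0.9), 2),
                              cells_a = c(1L, 2L), cells_b = 3L)
  })
  expect_equal(unname(bd$dist[1, 1]), mean(c(2, 1)))

  # singleton bin against itself
  suppressWarnings({
    bd2 <- bin_distance_matrix(ds, pseudotime_bins(0.5, 2),
                               pseudotime_bins(0.5, 2),
                               cells_a = 2L, cells_b = 2L)
  })
  expect_equal(unname(bd2$dist[1, 1]), 0)
})

test_that("pair subsampling approximates the full mean", {
  set.seed(3)
  u <- matrix(rnorm(4000), 2000, 2)
  ds <- fake_ds(u)
  pa <- pseudotime_bins(rep(0.25, 1000), 2, method = "width")
  pb <- pseudotime_bins(rep(0.75, 1000), 2, method = "width")
  suppressWarnings({
    full <- bin_distance_matrix(ds, pa, pb, cells_a = 1:1000,
                                cells_b = 1001:2000, max_pairs = 2e6)
    sub <- bin_distance_matrix(ds, pa, pb, cells_a = 1:1000,
                               cells_b = 1001:2000, max_pairs = 5e4,
                               seed = 1)
  })
  expect_lt(abs(full$dist[1, 1] - sub$dist[1, 1]) / full$dist[1, 1], 0.02)
})

test_that("bin self-comparison has its minimum on the diagonal", {
  set.seed(4)
  pt <- runif(800)
  u <- cbind(pt * 10 + rnorm(800, sd = 0.1), rnorm(800, sd = 0.1))
  ds <- fake_ds(u)
  pa <- pseudotime_bins(pt, 10)
  bd <- bin_distance_matrix(ds, pa, pa)
  mins <- apply(bd$dist, 1, which.min)
  expect_gte(mean(mins == seq_along(mins)), 0.95)
})

test_that("bin mapping takes the row argmin with ties toward lower index", {
  bd <- structure(list(dist = matrix(c(1, 0.5, 0.5,
                                       0.2, 0.9, 0.2), 2, 3, byrow = TRUE,
                                     dimnames = list(c("a1", "a2"),
                                                     c("b1", "b2", "b3"))),
                       bins_a = tibble::tibble(bin = c("a1", "a2"),
                                               label = NA_character_),
                       bins_b = tibble::tibble(bin = c("b1", "b2", "b3"),
                                               label = c("x", "y", "z"))),
                  class = "bin_distance")
  mp <- map_bins(bd)
  expect_equal(mp$bin_b, c("b2", "b1"))  # tie in row 2 resolves to b1
  expect_equal(mp$label_b, c("y", "x"))

  # invariance to row order
  bd2 <- bd
  bd2$dist <- bd$dist[2:1, ]
  bd2$bins_a <- bd$bins_a[2:1, ]
  mp2 <- map_bins(bd2)
  expect_equal(mp2$bin_b[match(mp$bin_a, mp2$bin_a)], mp$bin_b)
})

test_that("identical partitions of identical cells map to themselves", {
  set.seed(5)
  pt <- runif(300)
  u <- cbind(pt, pt^2)
  ds <- fake_ds(u)
  pa <- pseudotime_bins(pt, 10)
  bd <- bin_distance_matrix(ds, pa, pa)
  mp <- map_bins(bd)
  expect_equal(mp$bin_a, mp$bin_b)
})

test_that("force-directed layout is seeded and separates components", {
  A <- matrix(0, 20, 20)
  A[1:10, 1:10] <- 0.8; A[11:20, 11:20] <- 0.8
  diag(A) <- 0
  ag <- affinity_graph(Matrix::Matrix(A, sparse = TRUE))
  l1 <- coembed_layout(ag, iterations = 200, seed = 3)
  l2 <- coembed_layout(ag, iterations = 200, seed = 3)
  expect_equal(l1, l2)
  c1 <- colMeans(l1[1:10, c("x", "y")])
  c2 <- colMeans(l1[11:20, c("x", "y")])
  within <- max(dist(l1[1:10, c("x", "y")]))
  expect_gt(sqrt(sum((c1 - c2)^2)), within / 2)
})

test_that("longer layout runs reduce stress on a ring", {
  A <- matrix(0, 12, 12)
  for (i in 1:12) { j <- (i %% 12) + 1; A[i, j] <- A[j, i] <- 1 }
  ag <- affinity_graph(Matrix::Matrix(A, sparse = TRUE))
  s_short <- statemap:::layout_stress(ag, coembed_layout(ag, iterations = 2,
                                                         seed = 1))
  s_long <- statemap:::layout_stress(ag, coembed_layout(ag, iterations = 500,
                                                        seed = 1))
  expect_lt(s_long, s_short)
})

test_that("clustering recovers well-separated blobs with both methods", {
  set.seed(6)
  blobs <- make_blobs(40, matrix(c(0, 0, 10, 0, 0, 10), 3, byrow = TRUE))
  for (m in c("community", "kmeans_diffusion")) {
    cl <- cluster_cells(blobs$X, method = m, n_clusters = 3, seed = 1)
    expect_equal(ari(cl, blobs$labels), 1)
  }
  expect_error(cluster_cells(blobs$X, method = "other"), "arg")
  expect_equal(formals(cluster_cells)$n_clusters, 30L)
})

test_that("a planted 5-way partition is recovered across seeds", {
  scores <- vapply(1:10, function(s) {
    set.seed(s)
    repeat {  # well-separated centres: min pairwise distance >= 6 blob sds
      centers <- matrix(rnorm(10, sd = 8), 5, 2)
      if (min(dist(centers)) >= 5) break
    }
    blobs <- make_blobs(30, centers, sd = 0.8)
    cl <- cluster_cells(blobs$X, method = "community", seed = s)
    ari(cl, blobs$labels)
  }, numeric(1))
  expect_gte(mean(scores >= 0.9), 0.9)
})

test_that("rank-sum differential expression matches the exact permutation oracle", {
  x <- c(1.2, 3.4, 0.5, 7.8, 2.2)
  y <- c(4.4, 9.1, 6.3, 5.5, 8.0)
  p_pkg <- statemap:::ranksum_pvalues(matrix(x, 5), matrix(y, 5))
  expect_equal(p_pkg, perm_ranksum_p(x, y), tolerance = 1e-12)
})

test_that("identical groups yield no differential genes", {
  set.seed(7)
  X <- matrix(rnorm(400), 40, 10, dimnames = list(NULL, sprintf("g%02d", 1:10)))
  X[21:40, ] <- X[1:20, ]
  labels <- rep(c("a", "b"), each = 20)
  tab <- differential_genes(X, labels, "a", p_max = 0.05, lfc_min = 0)
  expect_equal(nrow(tab), 0)
  expect_error(differential_genes(X, rep(c("a", "b"), c(1, 39)), "a"),
               "at least 2")
  expect_equal(formals(differential_genes)$top_n, 50L)
})

test_that("planted markers are ranked first and capped at top_n", {
  set.seed(8)
  n <- 60; ng <- 30
  X <- matrix(rnorm(n * ng), n, ng, dimnames = list(NULL, sprintf("g%02d", 1:ng)))
  labels <- rep(c("t", "rest"), each = 30)
  X[labels == "t", 1:5] <- X[labels == "t", 1:5] + 5
  tab <- differential_genes(X, labels, "t", p_max = 0.01, lfc_min = 2,
                            top_n = 3)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$gene %in% sprintf("g%02d", 1:5)))
  expect_equal(tab$rank, 1:3)
})

test_that("rank-sum type-I error is calibrated under an NB null", {
  set.seed(9)
  n_genes <- 2000; reps <- 20
  hits <- 0L
  for (r in seq_len(reps)) {
    counts <- matrix(rnbinom(40 * n_genes, mu = 5, size = 2), 40, n_genes,
                     dimnames = list(sprintf("c%02d", 1:40),
                                     sprintf("g%04d", seq_len(n_genes))))
    counts[, colSums(counts) == 0] <- 1L  # guard all-zero cells/genes
    nm <- normalize_expression(cell_table(counts))
    p <- statemap:::ranksum_pvalues(nm$values[1:20, , drop = FALSE],
                                    nm$values[21:40, , drop = FALSE])
    hits <- hits + sum(p < 0.01)
  }
  total <- n_genes * reps
  sd3 <- 3 * sqrt(0.01 * 0.99 / total)
  expect_lt(abs(hits / total - 0.01), sd3 + 1e-9)
})

test_that("signature scores are mean z-scores with the expected invariances", {
  X <- matrix(c(1, 2, 3,
                2, 4, 6,
                0, 1, 0,
                5, 5, 5), 3, 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  sc <- signature_scores(X, list(s1 = "a", s2 = c("a", "b")))
  z <- scale(X)
  expect_equal(sc[, "s1"], z[, "a"], ignore_attr = TRUE)
  expect_equal(sc[, "s2"], rowMeans(z[, c("a", "b")]), ignore_attr = TRUE)
  # constant gene contributes zero, not NaN
  sc_d <- signature_scores(X, list(s = c("a", "d")))
  expect_true(all(is.finite(sc_d)))
  # gene order within a set does not matter; affine rescaling of one gene
  # does not change its z-score
  sc_r <- signature_scores(X, list(s2 = c("b", "a")))
  expect_equal(sc_r[, "s2"], sc[, "s2"])
  X2 <- X; X2[, "a"] <- 10 * X2[, "a"] + 3
  expect_equal(signature_scores(X2, list(s2 = c("a", "b"))), sc[, "s2",
                                                                drop = FALSE])
  expect_error(signature_scores(X, list(bad = "zz")), "bad")
})
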