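# Metacell scATAC stack: embedding, aggregation, normalization, HVPs,
# K-S differential accessibility, pseudobulk, dynamics, intervals.

toy_pm <- function(counts, width = 501L) {
  counts <- as.matrix(counts)
  dimnames(counts) <- list(sprintf("c%03d", seq_len(nrow(counts))),
                           sprintf("p%03d", seq_len(ncol(counts))))
  start <- seq_len(ncol(counts)) * 1000L
  ps <- peak_set(tibble::tibble(chrom = "chr1", start = start,
                                end = start + width,
                                name = colnames(counts),
                                gc = seq(0.3, 0.7,
                                         length.out = ncol(counts))))
  peak_matrix(counts, ps, level = "cell")
}

test_that("TF-IDF entries match the hand formula and SVD captures rank-1 data", {
  counts <- matrix(c(1, 0, 2,
                     0, 3, 1), 2, 3, byrow = TRUE)
  pm <- toy_pm(counts)
  emb <- lsi_embed(pm, n_var = 3, n_dims = 1)
  tf <- counts / rowSums(counts)
  idf <- log(1 + 2 / (1 + colSums(counts > 0)))
  M <- sweep(tf, 2, idf, "*")
  sv <- svd(M)
  expect_equal(abs(as.numeric(emb)), abs(sv$u[, 1] * sv$d[1]),
               tolerance = 1e-10)
  expect_error(lsi_embed(pm, n_dims = 2), "n_dims")
  expect_equal(formals(lsi_embed)$n_var, 100000L)
  expect_equal(formals(lsi_embed)$n_dims, 30L)

  # rank-1 binary matrix: first singular vector explains almost everything
  set.seed(1)
  B <- outer(rep(1, 20), c(rep(1, 10), rep(0, 5)))
  pmb <- toy_pm(B)
  embB <- lsi_embed(pmb, n_var = 15, n_dims = 3)
  d <- attr(embB, "d")
  expect_gt(d[1]^2 / sum(d^2), 0.999)
})

test_that("metacell assignment respects structure and sizes", {
  set.seed(2)
  blobs <- make_blobs(25, matrix(c(0, 0, 20, 20), 2, byrow = TRUE))
  rownames(blobs$X) <- sprintf("c%03d", 1:50)
  mm <- assign_metacells(blobs$X, 2, seed = 1)
  grp <- mm$map$metacell
  expect_equal(ari(grp, blobs$labels), 1)

  mm_all <- assign_metacells(blobs$X, 50)
  expect_equal(nrow(mm_all$sizes), 50)
  expect_true(all(mm_all$sizes$n_cells == 1))
  expect_error(assign_metacells(blobs$X, 1), "at least 2")

  set.seed(3)
  U <- matrix(runif(600), 300, 2)
  rownames(U) <- sprintf("c%03d", 1:300)
  mm_u <- assign_metacells(U, 20, seed = 2)
  expect_equal(mean(mm_u$sizes$n_cells), 15)
  expect_true(all(mm_u$sizes$n_cells > 0))
})

test_that("aggregation is the exact group column sum and conserves totals", {
  counts <- matrix(c(1, 2, 3,
                     4, 5, 6,
                     7, 8, 9,
                     1, 0, 1), 4, 3, byrow = TRUE)
  pm <- toy_pm(counts)
  mm <- structure(list(map = tibble::tibble(cell = rownames(pm$counts),
                                            metacell = c("mcA", "mcA", "mcB",
                                                         "mcB")),
                       sizes = tibble::tibble(metacell = c("mcA", "mcB"),
                                              n_cells = c(2L, 2L))),
                  class = "metacell_map")
  agg <- aggregate_metacells(pm, mm)
  expect_equal(unname(agg$counts["mcA", ]), c(5, 7, 9))
  expect_equal(unname(agg$counts["mcB", ]), c(8, 8, 10))
  expect_equal(sum(agg$counts), sum(counts))

  mm$map <- mm$map[-1, ]
  expect_error(aggregate_metacells(pm, mm), "not mapped")
})

test_that("metacell normalization follows the pseudo-count-1 formula", {
  counts <- matrix(c(2, 4, 6, 8), 2, 2)
  pm <- toy_pm(counts)
  pm$level <- "metacell"
  norm <- normalize_metacells(pm)
  tot <- rowSums(counts); med <- median(tot)
  expect_equal(norm$counts,
               log(counts / tot * med + 1), ignore_attr = TRUE)
  expect_equal(formals(normalize_metacells)$pseudo, 1)
  # equal totals -> scaling factor 1 relative to raw proportions
  eq <- toy_pm(matrix(c(3, 7, 7, 3), 2, 2)); eq$level <- "metacell"
  nm2 <- normalize_metacells(eq)
  expect_equal(attr(nm2, "scale_factor"), 10)
})

test_that("highly variable peaks recover planted dispersion and skip constants", {
  hits <- 0L; total <- 0L
  for (s in 1:10) {
    set.seed(s)
    n <- 80; np <- 300
    planted <- sample(np, 15)
    mu <- runif(np, 1, 3)
    # mean-matched accessibility with ~100x dispersion on planted loci
    X <- sapply(seq_len(np), function(j) {
      rnorm(n, mu[j], sd = if (j %in% planted) 0.8 else 0.08)
    })
    sel <- highly_variable_peaks(X, min_disp = 3, min_mean = 0.0125)
    hits <- hits + length(intersect(sel, planted))
    total <- total + 15L
  }
  expect_gte(hits / total, 0.95)

  X <- cbind(rep(1, 10), rnorm(10, 10))
  expect_false(1L %in% highly_variable_peaks(X, min_disp = -10, min_mean = 0))
  expect_equal(formals(highly_variable_peaks)$min_disp, 3.0)
  expect_equal(formals(highly_variable_peaks)$min_mean, 0.0125)
})

test_that("K-S differential accessibility matches the ECDF oracle", {
  X <- matrix(c(1, 2, 3, 4, 5, 6), 6, 1)
  res <- ks_differential_peaks(X, 1:3, 4:6, alpha = 1e-4)
  expect_equal(res$D, 1)  # disjoint supports: sup ECDF difference = 1

  X2 <- matrix(rep(c(1, 2, 3), 2), 6, 1)
  res2 <- ks_differential_peaks(X2, 1:3, 4:6)
  expect_equal(res2$D, 0)
  expect_equal(res2$p, 1)
  expect_false(res2$pass)

  expect_error(ks_differential_peaks(X, 1:3, 3:6), "disjoint")
  expect_error(ks_differential_peaks(X, 1:2, 3:6), "at least 3")
  expect_equal(formals(ks_differential_peaks)$alpha, 1e-4)
})

test_that("pseudobulk means are exact and conserve the grand mean", {
  counts <- matrix(c(1, 3, 2, 6, 5, 7, 0, 4), 4, 2)
  groups <- c("g1", "g1", "g2", "g2")
  pb <- pseudobulk_groups(counts, groups)
  expect_equal(unname(pb["g1", ]), c(mean(counts[1:2, 1]), mean(counts[1:2, 2])))
  expect_equal(colMeans(pb), colMeans(counts))  # equal group sizes
  pb1 <- pseudobulk_groups(counts, rep("all", 4))
  expect_equal(unname(pb1[1, ]), colMeans(counts))
  expect_error(pseudobulk_groups(counts, factor(groups,
                                                levels = c("g1", "g2", "g3"))),
               "empty group")
})

test_that("dynamics classification follows the published class shapes", {
  pb <- rbind(g1 = c(0, 1, 0,   0, 0.5),
              g2 = c(0.25, 1, 0.2, 0, 0.5),
              g3 = c(0.5, 1, 1,  0, 0.5),
              g4 = c(0.75, 0.9, 0.2, 0.1, 0.55),
              g5 = c(1, 0, 0,   1, 0.5))
  colnames(pb) <- c("ramp", "lateclose", "transient", "lateopen", "flat")
  cls <- classify_peak_dynamics(pb, rownames(pb))
  expect_equal(cls$class[cls$peak == "ramp"], "gradual_open")
  expect_equal(cls$class[cls$peak == "lateopen"], "late_open")
  expect_equal(cls$class[cls$peak == "lateclose"], "late_close")
  expect_equal(cls$class[cls$peak == "transient"], "transient_open")
  expect_equal(cls$class[cls$peak == "flat"], "stable")
  expect_error(classify_peak_dynamics(pb[1:3, ], rownames(pb)[1:3]), "4")
  expect_error(classify_peak_dynamics(pb, c("g1", "zz", "g3", "g4", "g5")),
               "group_order")
})

test_that("planted dynamics classes are recovered from the generator", {
  pk <- simulate_peak_experiment(n_peaks = 1500, seed = 21)
  norm <- normalize_metacells(pk$counts)
  pb <- pseudobulk_groups(norm, factor(pk$counts$meta$group,
                                       levels = pk$truth$group_order))
  dyn <- classify_peak_dynamics(pb, pk$truth$group_order)
  for (cl in unique(pk$truth$peaks$class)) {
    idx <- pk$truth$peaks$class == cl
    expect_gte(mean(dyn$class[idx] == cl), 0.9)
  }
})

test_that("interval merge matches a sweep-line oracle and is idempotent", {
  ps <- peak_set(tibble::tibble(chrom = "chr1",
                                start = c(0L, 5L, 20L, 30L),
                                end = c(10L, 15L, 25L, 40L)))
  m0 <- merge_intervals(ps)
  expect_equal(m0$start, c(0L, 20L, 30L))
  expect_equal(m0$end, c(15L, 25L, 40L))

  # summits extended by +/-50 merge when within 100 bp
  summits <- peak_set(tibble::tibble(chrom = "chr1",
                                     start = c(1000L, 1080L, 1500L),
                                     end = c(1001L, 1081L, 1501L)))
  ms <- merge_intervals(summits, extend = 50L)
  expect_equal(nrow(ms), 2)
  expect_equal(ms$start[1], 1000L - 50L)
  expect_equal(ms$end[1], 1081L + 50L)

  set.seed(4)
  rnd <- peak_set(tibble::tibble(chrom = sample(c("chr1", "chr2"), 500, TRUE),
                                 start = s <- sample.int(10000, 500, TRUE),
                                 end = s + sample.int(300, 500, TRUE)))
  mr <- merge_intervals(rnd)
  for (ch in c("chr1", "chr2")) {
    sub <- rnd[rnd$chrom == ch, ]
    oracle <- sweep_merge(sub$start, sub$end)
    got <- mr[mr$chrom == ch, ]
    expect_equal(got$start, unname(oracle[, "start"]))
    expect_equal(got$end, unname(oracle[, "end"]))
  }
  expect_equal(merge_intervals(mr)[c("chrom", "start", "end")],
               mr[c("chrom", "start", "end")])
})

test_that("interval overlap respects half-open semantics and the double-loop oracle", {
  a <- peak_set(tibble::tibble(chrom = "chr1", start = c(0L, 100L),
                               end = c(10L, 200L)))
  b <- peak_set(tibble::tibble(chrom = "chr1", start = c(10L, 150L),
                               end = c(20L, 160L)))
  ov <- overlap_intervals(a, b)
  expect_equal(ov$overlaps, c(FALSE, TRUE))  # [0,10) vs [10,20): no overlap
  expect_true(all(ov$pairs == cbind(2L, 2L)))
  expect_true(overlap_intervals(a, a)$overlaps[1])

  set.seed(5)
  ra <- peak_set(tibble::tibble(chrom = "chr1",
                                start = sa <- sample.int(5000, 300, TRUE),
                                end = sa + sample.int(100, 300, TRUE)))
  rb <- peak_set(tibble::tibble(chrom = "chr1",
                                start = sb <- sample.int(5000, 300, TRUE),
                                end = sb + sample.int(100, 300, TRUE)))
  got <- overlap_intervals(ra, rb)$pairs
  oracle <- brute_overlap_pairs(ra$start, ra$end, rb$start, rb$end)
  expect_equal(nrow(got), nrow(oracle))
  expect_equal(got$a, unname(oracle[, 1]))
  expect_equal(got$b, unname(oracle[, 2]))
  # symmetry of the pair list
  rev <- overlap_intervals(rb, ra)$pairs
  expect_equal(nrow(rev), nrow(got))
  key1 <- paste(got$a, got$b); key2 <- paste(rev$b, rev$a)
  expect_setequal(key1, key2)
})
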