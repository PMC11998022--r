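# Generators: determinism, topology validation, count distributions and
# planted ground truth.

test_that("identical seeds reproduce byte-identical output, different seeds differ", {
  cfg <- sim_config(n_cells_per_timepoint = 30, n_genes = 60, seed = 42)
  a <- simulate_branching_trajectory(cfg)
  b <- simulate_branching_trajectory(cfg)
  expect_identical(a$cells$counts, b$cells$counts)
  expect_identical(a$truth$cells, b$truth$cells)
  cfg2 <- sim_config(n_cells_per_timepoint = 30, n_genes = 60, seed = 43)
  c_ <- simulate_branching_trajectory(cfg2)
  expect_false(identical(a$cells$counts, c_$cells$counts))
})

test_that("counts are non-negative integers and pseudotime lies in [0, 1]", {
  sim <- simulate_branching_trajectory(
    sim_config(n_cells_per_timepoint = 40, n_genes = 80, seed = 3))
  expect_true(all(sim$cells$counts >= 0))
  expect_true(all(sim$cells$counts == round(sim$cells$counts)))
  expect_true(all(sim$truth$cells$true_pseudotime >= 0))
  expect_true(all(sim$truth$cells$true_pseudotime <= 1))
  fate <- sim$truth$cells
  on_term <- fate$true_segment %in% c("T1", "T2", "T3")
  expect_identical(fate$true_terminal_fate[on_term],
                   fate$true_segment[on_term])
})

test_that("topology validation names the offending segment", {
  expect_error(trajectory_topology(c("a", "b"), c(NA, "zz"), c(0, 0.5),
                                   c(0.5, 1), c(FALSE, TRUE)),
               "orphan")
  expect_error(trajectory_topology(c("a", "b"), c("b", "a"), c(0, 0.5),
                                   c(0.5, 1), c(FALSE, TRUE)),
               "root")
  expect_error(trajectory_topology(c("a", "b"), c(NA, "a"), c(0, 0.6),
                                   c(0.5, 1), c(FALSE, TRUE)),
               "span|start")
  expect_error(trajectory_topology(c("a", "b"), c(NA, "a"), c(0, 0.5),
                                   c(0.5, 1), c(FALSE, FALSE)),
               "terminal")
})

test_that("near-noise-free counts track the designed mean", {
  # constant program: every gene at log-level log(5) on a single segment
  topo <- topology_linear()
  P <- matrix(log(5), 50, 1, dimnames = list(sprintf("g%02d", 1:50), "main"))
  attr(P, "baseline") <- rep(log(5), 50)
  cfg <- sim_config(n_cells_per_timepoint = 50, n_genes = 50, topology = topo,
                    programs = P, dispersion = 1e6, dropout = 0,
                    n_timepoints = 2, seed = 5)
  sim <- simulate_branching_trajectory(cfg)
  frac <- mean(abs(sim$cells$counts - 5) <= 3 * sqrt(5))
  expect_gte(frac, 0.99)
})

test_that("a single linear segment gives every cell the same fate", {
  cfg <- sim_config(n_cells_per_timepoint = 20, n_genes = 30,
                    topology = topology_linear(), n_timepoints = 2, seed = 1)
  sim <- simulate_branching_trajectory(cfg)
  expect_true(all(sim$truth$cells$true_terminal_fate == "main"))
})

test_that("generated counts match a direct negative-binomial sampler moment-wise", {
  # constant designed mean -> every gene is iid NB(mu = 4, size = 2)
  topo <- topology_linear()
  ng <- 40L
  P <- matrix(log(4), ng, 1, dimnames = list(sprintf("g%02d", 1:ng), "main"))
  attr(P, "baseline") <- rep(log(4), ng)
  cfg <- sim_config(n_cells_per_timepoint = 1500, n_genes = ng,
                    topology = topo, programs = P, dispersion = 2,
                    dropout = 0, n_timepoints = 2, seed = 7)
  sim <- simulate_branching_trajectory(cfg)
  n <- nrow(sim$cells$counts)
  set.seed(99)
  ref <- matrix(rnbinom(n * ng, mu = 4, size = 2), n, ng)
  # per-gene means and variances within 4 standard errors of the oracle's
  m_obs <- colMeans(sim$cells$counts); m_ref <- colMeans(ref)
  v_obs <- apply(sim$cells$counts, 2, var); v_ref <- apply(ref, 2, var)
  se_m <- sqrt(mean(v_ref) / n)
  expect_true(all(abs(m_obs - mean(m_ref)) < 4 * se_m + 0.2))
  expect_lt(abs(mean(v_obs) - mean(v_ref)) / mean(v_ref), 0.1)
})

test_that("marginal gene distribution passes K-S against a reference NB sampler", {
  topo <- topology_linear()
  P <- matrix(log(6), 1, 1, dimnames = list("g01", "main"))
  attr(P, "baseline") <- log(6)
  pass <- 0L
  for (s in 1:100) {
    cfg <- sim_config(n_cells_per_timepoint = 150, n_genes = 1,
                      topology = topo, programs = P, dispersion = 3,
                      dropout = 0, n_timepoints = 2, seed = s)
    sim <- simulate_branching_trajectory(cfg)
    set.seed(10000 + s)
    ref <- rnbinom(300, mu = 6, size = 3)
    p <- suppressWarnings(ks.test(as.numeric(sim$cells$counts), ref)$p.value)
    if (p > 0.01) pass <- pass + 1L
  }
  expect_gte(pass, 95L)
})

test_that("embryo reference carries five lineages and an ICM-restricted progenitor program", {
  ref <- simulate_reference_embryo(
    sim_config(topology = topology_embryo(), n_cells_per_timepoint = 80,
               n_genes = 200, seed = 11))
  expect_setequal(unique(ref$truth$cells$lineage),
                  c("ICM", "EPI", "PrE", "VE", "ParE"))
  prog <- ref$truth$genes$gene[ref$truth$genes$archetype == "progenitor"]
  expect_gt(length(prog), 0)
  icm <- ref$truth$cells$lineage == "ICM" & ref$truth$cells$true_pseudotime > 0.15
  other <- ref$truth$cells$lineage %in% c("VE", "ParE", "EPI") &
    ref$truth$cells$true_pseudotime > 0.7
  m_icm <- mean(ref$cells$counts[icm, prog])
  m_other <- mean(ref$cells$counts[other, prog])
  expect_gt(m_icm, 5 * max(m_other, 0.01))
})

test_that("progenitor genes overlapping branch programs are rejected", {
  ref <- simulate_reference_embryo(
    sim_config(topology = topology_embryo(), n_cells_per_timepoint = 20,
               n_genes = 200, seed = 2))
  P <- ref$truth$programs
  arch <- attr(P, "archetype")
  P[which(arch == "progenitor")[1L], "EPI"] <- log(8)  # contaminate
  cfg <- sim_config(topology = topology_embryo(), n_cells_per_timepoint = 20,
                    n_genes = 200, programs = P, seed = 2)
  expect_error(simulate_reference_embryo(cfg), "overlap")
})

test_that("conversions built from reference programs land next to matching reference states", {
  ref <- simulate_reference_embryo(
    sim_config(topology = topology_embryo(), n_cells_per_timepoint = 100,
               n_genes = 300, dispersion = 1e6, dropout = 0, seed = 13))
  cfgv <- conversion_from_reference(ref$truth, from = "PrE", to = "EPI",
                                    n_cells_per_timepoint = 60,
                                    dispersion = 1e6, dropout = 0,
                                    seed = 14)
  vitro <- simulate_branching_trajectory(cfgv)
  nmr <- normalize_expression(ref$cells)
  nmv <- normalize_expression(vitro$cells)
  # brute-force nearest reference neighbour in (near) noise-free space
  D <- statemap:::cross_dist(nmv$values, nmr$values)
  nn <- apply(D, 1L, which.min)
  nn_lin <- ref$truth$cells$lineage[nn]
  pt_v <- vitro$truth$cells$true_pseudotime
  matching <- ifelse(pt_v < 0.4, nn_lin %in% c("PrE", "VE", "ParE"),
                     ifelse(pt_v > 0.6, nn_lin == "EPI", TRUE))
  expect_gt(mean(matching), 0.8)
})

test_that("peak experiment plants 501-bp intervals and class dynamics", {
  pk <- simulate_peak_experiment(n_peaks = 400, seed = 5)
  expect_true(all(pk$peaks$end - pk$peaks$start == 501L))
  expect_true(all(pk$peaks$gc >= 0 & pk$peaks$gc <= 1))
  grp <- pk$counts$meta$group
  cls <- pk$truth$peaks$class
  gm <- rowsum(pk$counts$counts, grp) /
    as.vector(table(grp)[sort(unique(grp))])
  # stable peaks: group means equal within sampling error
  st <- which(cls == "stable")
  rel_spread <- apply(gm[, st, drop = FALSE], 2,
                      function(x) (max(x) - min(x)) / mean(x))
  expect_lt(median(rel_spread), 0.5)
  # late-open peaks: last group above first for nearly all peaks
  lo <- which(cls == "late_open")
  expect_gte(mean(gm[nrow(gm), lo] > gm[1L, lo]), 0.95)
  expect_error(simulate_peak_experiment(n_groups = 1), "2")
})

test_that("methylation tracks are disjoint with configurable island count", {
  mt <- simulate_methylation_tracks(n_islands = 500, seed = 3)
  expect_equal(nrow(mt), 500)
  expect_true(all(mt$signal >= 0))
  for (ch in unique(mt$chrom)) {
    sub <- mt[mt$chrom == ch, ]
    o <- order(sub$start)
    expect_true(all(sub$end[o][-nrow(sub)] <= sub$start[o][-1L]))
  }
  z <- simulate_methylation_tracks(n_islands = 100, signal_mean = 0, seed = 1)
  peaks <- peak_set(tibble::tibble(chrom = z$chrom[1:5],
                                   start = z$start[1:5], end = z$end[1:5]))
  expect_true(all(window_signal_sum(peaks, z, 1500) == 0))
  expect_equal(formals(simulate_methylation_tracks)$n_islands, 17000L)
})
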