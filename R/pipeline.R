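# End-to-end orchestration: a demo-scale run over synthetic conversions,
# the embryo-like reference, and a peak experiment, with manifests and
# deterministic outputs at a fixed seed.  The package's functions are the
# interface; run_pipeline() chains them in the canonical stage order
# (preprocess -> graphs -> diffusion -> trajectory -> comparison/trends,
# and lsi -> metacells -> HVP -> groups -> KS/pseudobulk -> regulatory).

#' Pipeline run configuration
#'
#' All stage parameters with their defaults; unknown keys are rejected.
#'
#' @param ... Overrides of the defaults listed below.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1,
    # synthetic data
    n_cells_per_timepoint = 120, n_genes = 300, n_timepoints = 5,
    dispersion = 2, dropout = 0.2,
    n_peaks = 400, n_peak_groups = 5, n_metacells_per_group = 12,
    # preprocess
    mito_fraction_max = 0.2, pseudo = 0.1, n_hvg = 150, var_frac = 0.85,
    # graphs / diffusion
    knn_k = 50, n_eigs = 20, impute_t = 3,
    # comparison
    n_bins = 20, community_k = 30, resolution = 1,
    # trends
    trend_grid = 100, trend_radius = 0.025, trend_min_size = 2,
    # atac / regulatory
    hvp_min_disp = 2.0, hvp_min_mean = 0.0125, ks_alpha = 1e-4,
    n_background = 25, enrichment_p = 1e-3, methyl_window = 1500
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad) > 0L) {
    abort(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, over)
  structure(cfg, class = "run_config")
}

stage_msg <- function(log, stage, t0, ...) {
  msg <- sprintf("[%s] %5.1fs %s", stage,
                 as.numeric(difftime(Sys.time(), t0, units = "secs")),
                 paste(sprintf(...), collapse = ""))
  message(msg)
  c(log, msg)
}

#' Run the full demo pipeline
#'
#' Simulates two conversion experiments (one branching with three terminal
#' states, one linear), an embryo-like reference and a peak experiment,
#' then runs preprocessing, trajectory inference, cross-trajectory bin
#' mapping, trend clustering, the scATAC metacell stack, and regulatory
#' scoring.  Outputs are CSV/TSV files plus a JSON manifest with the
#' effective parameters and MD5 checksums of every output; runs with the
#' same config and seed produce identical checksums.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory.
#' @param skip_existing Skip stages whose outputs already exist.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(cfg = run_config(), out_dir, skip_existing = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  log <- character()
  seed <- as.integer(cfg$seed)

  manifest_path <- file.path(out_dir, "manifest.json")
  if (skip_existing && file.exists(manifest_path)) {
    return(invisible(jsonlite::read_json(manifest_path)))
  }

  ## -- simulate ---------------------------------------------------------
  base_cfg <- function(topology, seed_off, programs = NULL) {
    sim_config(n_cells_per_timepoint = cfg$n_cells_per_timepoint,
               n_genes = cfg$n_genes, topology = topology,
               programs = programs, dispersion = cfg$dispersion,
               dropout = cfg$dropout, n_timepoints = cfg$n_timepoints,
               seed = seed + seed_off)
  }
  sim_a <- simulate_branching_trajectory(base_cfg(topology_three_terminal(), 1L))
  sim_b <- simulate_branching_trajectory(base_cfg(topology_linear(), 2L))
  ref <- simulate_reference_embryo(base_cfg(topology_embryo(), 3L))
  pk <- simulate_peak_experiment(n_peaks = cfg$n_peaks,
                                 n_groups = cfg$n_peak_groups,
                                 n_metacells_per_group = cfg$n_metacells_per_group,
                                 seed = seed + 4L)
  meth <- simulate_methylation_tracks(n_islands = 2000L, seed = seed + 5L)
  log <- stage_msg(log, "simulate", t0, "%d + %d conversion cells, %d reference cells, %d peaks",
                   nrow(sim_a$cells$counts), nrow(sim_b$cells$counts),
                   nrow(ref$cells$counts), cfg$n_peaks)

  ## -- preprocess + trajectory per conversion ---------------------------
  run_traj <- function(sim, user_terminals = NULL) {
    ct <- filter_cells(sim$cells, cfg$mito_fraction_max)
    keep <- match(ct$cell_meta$cell, sim$truth$cells$cell)
    truth <- sim$truth$cells[keep, , drop = FALSE]
    nm <- normalize_expression(ct, cfg$pseudo)
    hvg <- select_hvg(nm, min(cfg$n_hvg, ncol(nm$values)))
    pcs <- pca_retain(normalized_matrix(nm$values[, hvg, drop = FALSE],
                                        nm$scale_factor, nm$pseudo),
                      cfg$var_frac)
    start_cand <- which(truth$timepoint == "t0")[1L]
    fit <- fit_trajectory(pcs, start_candidate = start_cand, k = cfg$knn_k,
                          n_eigs = cfg$n_eigs,
                          user_terminals = user_terminals)
    list(ct = ct, nm = nm, hvg = hvg, pcs = pcs, fit = fit, truth = truth)
  }
  ra <- run_traj(sim_a)
  rb <- run_traj(sim_b)
  readr::write_csv(dplyr::bind_cols(tidy(ra$fit),
                                    ra$truth[c("true_pseudotime",
                                               "true_segment")]),
                   file.path(out_dir, "trajectory_a.csv"))
  readr::write_csv(dplyr::bind_cols(tidy(rb$fit),
                                    rb$truth[c("true_pseudotime",
                                               "true_segment")]),
                   file.path(out_dir, "trajectory_b.csv"))
  log <- stage_msg(log, "trajectory", t0, "A: %d terminals; B: %d terminals",
                   length(ra$fit$terminal_states),
                   length(rb$fit$terminal_states))

  ## -- comparison of the two conversions --------------------------------
  genes_joint <- intersect(colnames(ra$nm$values)[ra$hvg],
                           colnames(rb$nm$values)[rb$hvg])
  joint_pcs <- pca_retain(rbind(ra$nm$values[, genes_joint, drop = FALSE],
                                rb$nm$values[, genes_joint, drop = FALSE]),
                          cfg$var_frac)
  na <- nrow(ra$nm$values)
  blocks <- list(a = affinity_block(joint_pcs[seq_len(na), , drop = FALSE],
                                    k = cfg$knn_k),
                 b = affinity_block(joint_pcs[-seq_len(na), , drop = FALSE],
                                    k = cfg$knn_k))
  joint_aff <- augment_affinity(blocks, list(cross_spec("a", "b",
                                                        k = cfg$knn_k)))
  joint_ds <- diffusion_maps(markov_operator(joint_aff), n_eigs = cfg$n_eigs)
  bins_a <- pseudotime_bins(ra$fit$pseudotime, cfg$n_bins)
  bins_b <- pseudotime_bins(rb$fit$pseudotime, cfg$n_bins)
  bd <- bin_distance_matrix(joint_ds, bins_a, bins_b,
                            cells_a = seq_len(na),
                            cells_b = na + seq_len(nrow(rb$nm$values)),
                            seed = seed)
  mapping <- map_bins(bd, pt_b = rb$fit$pseudotime, pb = bins_b)
  readr::write_csv(mapping, file.path(out_dir, "bin_mapping.csv"))
  readr::write_csv(as_tibble(as.data.frame(bd$dist), rownames = "bin_a"),
                   file.path(out_dir, "bin_distances.csv"))
  log <- stage_msg(log, "comparison", t0, "%d x %d bin distances",
                   nrow(bd$dist), ncol(bd$dist))

  ## -- trends along conversion A ----------------------------------------
  T_a <- markov_operator(ra$fit$affinity)
  imputed <- impute(T_a, ra$nm$values[, ra$hvg, drop = FALSE],
                    t = cfg$impute_t)
  ts <- fit_trends(imputed, ra$fit$pseudotime,
                   grid_size = cfg$trend_grid)
  tc <- cluster_trends(ts, radius = cfg$trend_radius,
                       min_size = cfg$trend_min_size)
  readr::write_csv(tidy(tc), file.path(out_dir, "trend_clusters.csv"))
  log <- stage_msg(log, "trends", t0, "%d genes in %d clusters",
                   nrow(tc$clusters), nrow(tc$sizes))

  ## -- scATAC metacell stack --------------------------------------------
  norm <- normalize_metacells(pk$counts)
  hvp <- highly_variable_peaks(norm, cfg$hvp_min_disp, cfg$hvp_min_mean)
  groups <- pk$counts$meta$group
  g_first <- which(groups == pk$truth$group_order[1L])
  g_last <- which(groups == tail(pk$truth$group_order, 1L))
  ks <- ks_differential_peaks(norm$counts[, hvp, drop = FALSE],
                              g_first, g_last, cfg$ks_alpha)
  pb <- pseudobulk_groups(norm, factor(groups, levels = pk$truth$group_order))
  dyn <- classify_peak_dynamics(pb, pk$truth$group_order)
  readr::write_csv(dyn, file.path(out_dir, "peak_dynamics.csv"))
  readr::write_csv(ks, file.path(out_dir, "ks_differential.csv"))
  log <- stage_msg(log, "atac", t0, "%d HVPs, %d K-S hits",
                   length(hvp), sum(ks$pass))

  ## -- regulatory --------------------------------------------------------
  dev <- motif_deviation_scores(pk$counts, pk$motifs, pk$peaks,
                                n_background = cfg$n_background,
                                seed = seed + 6L)
  readr::write_csv(as_tibble(as.data.frame(dev$z), rownames = "metacell"),
                   file.path(out_dir, "motif_deviations.csv"))
  late <- peak_set(pk$peaks[dyn$class == "late_open", , drop = FALSE])
  sets <- list(planted_late = peak_set(
    pk$peaks[pk$truth$peaks$class == "late_open", , drop = FALSE]))
  enr <- regionset_enrichment(late, pk$peaks, sets, cfg$enrichment_p)
  readr::write_csv(enr, file.path(out_dir, "regionset_enrichment.csv"))
  msum <- window_signal_sum(pk$peaks, meth, cfg$methyl_window)
  readr::write_csv(tibble(peak = pk$peaks$name, cpg_signal = msum),
                   file.path(out_dir, "methylation_window_sums.csv"))
  log <- stage_msg(log, "regulatory", t0, "%d motifs scored", ncol(dev$z))

  ## -- manifest ----------------------------------------------------------
  outputs <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("statemap")),
    parameters = unclass(cfg),
    checksums = as.list(tools::md5sum(outputs)),
    log = log,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
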