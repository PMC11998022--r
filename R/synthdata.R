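# Seeded generators for every input the pipeline consumes, with ground truth
# attached.  The generators emulate the two study designs: an in-vitro
# conversion sampled at five timepoints (either linear with one terminal
# state, or branching with three terminal states), and an embryo-like
# reference with a bifurcating progenitor (ICM -> EPI / PrE, PrE -> VE /
# ParE) whose progenitor program is absent from the in-vitro simulations.

#' Describe a branching trajectory topology
#'
#' A topology is a tree of pseudotime segments.  Each segment spans an
#' interval of pseudotime; a child segment starts exactly where its parent
#' ends, and every leaf must be flagged terminal.
#'
#' @param segment Character vector of segment names (unique).
#' @param parent Parent segment name per segment; `NA` for the single root.
#' @param t_start,t_end Pseudotime span of each segment, within `[0, 1]`.
#' @param terminal Logical; `TRUE` for terminal (absorbing) segments.
#' @return A `trajectory_topology` tibble.
#' @export
trajectory_topology <- function(segment, parent, t_start, t_end, terminal) {
  topo <- tibble(segment = as.character(segment),
                 parent = as.character(parent),
                 t_start = as.numeric(t_start),
                 t_end = as.numeric(t_end),
                 terminal = as.logical(terminal))
  validate_topology(topo)
  class(topo) <- c("trajectory_topology", class(topo))
  topo
}

validate_topology <- function(topo) {
  if (anyDuplicated(topo$segment)) abort("duplicate segment names in topology")
  roots <- topo$segment[is.na(topo$parent)]
  if (length(roots) != 1L) abort("topology must have exactly one root segment")
  bad <- setdiff(topo$parent[!is.na(topo$parent)], topo$segment)
  if (length(bad) > 0L) {
    abort(sprintf("orphan segment(s): parent '%s' does not exist", bad[[1L]]))
  }
  # cycle check: every segment must reach the root
  for (s in topo$segment) {
    seen <- character()
    cur <- s
    repeat {
      if (cur %in% seen) abort(sprintf("cycle in topology at segment '%s'", s))
      seen <- c(seen, cur)
      p <- topo$parent[topo$segment == cur]
      if (is.na(p)) break
      cur <- p
    }
  }
  if (any(topo$t_end <= topo$t_start)) {
    abort(sprintf("segment '%s' has non-positive pseudotime span",
                  topo$segment[which(topo$t_end <= topo$t_start)[1L]]))
  }
  if (any(topo$t_start < 0) || any(topo$t_end > 1)) {
    abort("segment spans must lie within [0, 1]")
  }
  kids <- !is.na(topo$parent)
  if (any(kids)) {
    pe <- topo$t_end[match(topo$parent[kids], topo$segment)]
    off <- which(abs(topo$t_start[kids] - pe) > 1e-12)
    if (length(off) > 0L) {
      abort(sprintf("segment '%s' does not start where its parent ends",
                    topo$segment[kids][off[1L]]))
    }
  }
  leaves <- setdiff(topo$segment, topo$parent[!is.na(topo$parent)])
  nt <- leaves[!topo$terminal[match(leaves, topo$segment)]]
  if (length(nt) > 0L) {
    abort(sprintf("leaf segment '%s' is not flagged terminal", nt[[1L]]))
  }
  invisible(topo)
}

#' Built-in topologies
#'
#' `topology_linear()` is a single terminal segment on `[0, 1]` (one start
#' state converting into one end state).  `topology_three_terminal()` has a
#' shared early segment that splits into three terminal branches, mimicking a
#' conversion with one successful end state and two alternative dead-end
#' states.  `topology_embryo()` is the bifurcating reference tree
#' ICM -> \{EPI, PrE\}, PrE -> \{VE, ParE\}.
#'
#' @return A [trajectory_topology()].
#' @export
topology_linear <- function() {
  trajectory_topology("main", NA, 0, 1, TRUE)
}

#' @rdname topology_linear
#' @export
topology_three_terminal <- function() {
  trajectory_topology(
    segment = c("start", "T1", "T2", "T3"),
    parent = c(NA, "start", "start", "start"),
    t_start = c(0, 0.4, 0.4, 0.4),
    t_end = c(0.4, 1, 1, 1),
    terminal = c(FALSE, TRUE, TRUE, TRUE))
}

#' @rdname topology_linear
#' @export
topology_embryo <- function() {
  trajectory_topology(
    segment = c("ICM", "EPI", "PrE", "VE", "ParE"),
    parent = c(NA, "ICM", "ICM", "PrE", "PrE"),
    t_start = c(0, 0.3, 0.3, 0.6, 0.6),
    t_end = c(0.3, 1, 0.6, 1, 1),
    terminal = c(FALSE, TRUE, FALSE, TRUE, TRUE))
}

#' Simulation configuration
#'
#' Bundles every knob of the count simulators.  The defaults are the study
#' conditions exercised throughout the test-suite: five sampling timepoints,
#' negative-binomial counts with moderate overdispersion, and a modest
#' expression-independent dropout.
#'
#' @param n_cells_per_timepoint Cells sampled per timepoint.
#' @param n_genes Number of genes.
#' @param topology A [trajectory_topology()].
#' @param programs Optional genes x segments matrix of target log-expression
#'   at the *end* of each segment (column names must match segment names),
#'   with a `baseline` attribute holding the log-expression vector at the
#'   root start.  When `NULL`, [default_programs()] is used.
#' @param dispersion Negative-binomial size parameter (larger = less noise).
#' @param dropout Probability that an observed count is zeroed, in `[0, 1]`.
#' @param n_timepoints Number of sampling windows along pseudotime.
#' @param timepoint_overlap Fraction of a window's span shared with each
#'   neighbouring window (asynchronous sampling); default 0.25.
#' @param seed Integer seed; all randomness of a simulator call flows from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cells_per_timepoint = 600L,
                       n_genes = 1000L,
                       topology = topology_three_terminal(),
                       programs = NULL,
                       dispersion = 2,
                       dropout = 0.2,
                       n_timepoints = 5L,
                       timepoint_overlap = 0.25,
                       seed = 1L) {
  stopifnot_scalar_number(n_cells_per_timepoint, "n_cells_per_timepoint", 1)
  stopifnot_scalar_number(n_genes, "n_genes", 1)
  stopifnot_scalar_number(dispersion, "dispersion", 1e-8)
  stopifnot_scalar_number(dropout, "dropout", 0, 1)
  stopifnot_scalar_number(n_timepoints, "n_timepoints", 1)
  validate_topology(topology)
  structure(list(n_cells_per_timepoint = as.integer(n_cells_per_timepoint),
                 n_genes = as.integer(n_genes),
                 topology = topology,
                 programs = programs,
                 dispersion = dispersion,
                 dropout = dropout,
                 n_timepoints = as.integer(n_timepoints),
                 timepoint_overlap = timepoint_overlap,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default gene programs for a topology
#'
#' Assigns each gene an archetype: a fixed share become markers of one
#' segment (high log-expression at that segment's end, low elsewhere), a
#' share become start-state markers (high at pseudotime 0, silenced along
#' every branch), a handful are flagged mitochondrial, and the remainder are
#' housekeeping genes at the baseline level.
#'
#' @param n_genes Number of genes.
#' @param topology A [trajectory_topology()].
#' @param seed Seed for the random archetype assignment.
#' @param on_level,off_level,base_level Log-expression levels used for
#'   marker-on, marker-off and baseline states.
#' @param frac_markers Fraction of genes used as segment markers (split
#'   evenly across segments).
#' @param frac_down Fraction of genes used as start-state (silenced) markers.
#' @param n_mito Number of genes flagged mitochondrial.
#' @return Genes x segments matrix of end-of-segment log levels, with
#'   attributes `baseline` (log level at the root start), `archetype`
#'   (character per gene) and `mito` (logical per gene).
#' @export
default_programs <- function(n_genes, topology, seed = 1L,
                             on_level = log(8), off_level = log(0.05),
                             base_level = 0, frac_markers = 0.5,
                             frac_down = 0.1, n_mito = 5L) {
  with_seed(seed, {
    segs <- topology$segment
    genes <- sprintf("gene%04d", seq_len(n_genes))
    P <- matrix(base_level, n_genes, length(segs),
                dimnames = list(genes, segs))
    base <- rep(base_level, n_genes)
    archetype <- rep("housekeeping", n_genes)
    n_mark <- floor(n_genes * frac_markers)
    n_down <- floor(n_genes * frac_down)
    pool <- sample.int(n_genes, n_mark + n_down + n_mito)
    mark <- pool[seq_len(n_mark)]
    down <- pool[n_mark + seq_len(n_down)]
    mito <- pool[n_mark + n_down + seq_len(n_mito)]
    # split markers evenly across segments
    owner <- rep(seq_along(segs), length.out = n_mark)
    for (j in seq_along(segs)) {
      g <- mark[owner == j]
      P[g, ] <- off_level
      P[g, j] <- on_level
      archetype[g] <- paste0("marker_", segs[j])
    }
    base[mark] <- off_level
    # start-state markers: high baseline, silenced on every segment
    base[down] <- on_level
    P[down, ] <- off_level
    archetype[down] <- "start_marker"
    archetype[mito] <- "mito"
    names(base) <- genes
    mito_flag <- seq_len(n_genes) %in% mito
    structure(P, baseline = base, archetype = archetype, mito = mito_flag)
  })
}

# Timepoint sampling windows on [0,1]: equal widths, each extended so that
# consecutive windows share `overlap` of a window span.
timepoint_windows <- function(n_timepoints, overlap = 0.25) {
  w <- 1 / n_timepoints
  lo <- (seq_len(n_timepoints) - 1) * w - overlap * w / 2
  hi <- seq_len(n_timepoints) * w + overlap * w / 2
  cbind(lo = pmax(lo, 0), hi = pmin(hi, 1))
}

# Root-to-leaf path for each leaf of a topology.
leaf_paths <- function(topo) {
  leaves <- setdiff(topo$segment, topo$parent[!is.na(topo$parent)])
  lapply(setNames(leaves, leaves), function(lf) {
    path <- lf
    cur <- lf
    repeat {
      p <- topo$parent[topo$segment == cur]
      if (is.na(p)) break
      path <- c(p, path)
      cur <- p
    }
    path
  })
}

# Core of both count simulators: place cells on the topology, interpolate
# log-programs with cubic smoothstep along each segment, draw NB counts and
# apply Bernoulli dropout.
simulate_cells <- function(cfg) {
  topo <- cfg$topology
  P <- cfg$programs %||% default_programs(cfg$n_genes, topo, seed = cfg$seed)
  if (nrow(P) != cfg$n_genes) {
    abort("programs matrix rows must equal n_genes")
  }
  if (!all(topo$segment %in% colnames(P))) {
    abort("programs matrix must have one column per topology segment")
  }
  base <- attr(P, "baseline") %||% rep(0, nrow(P))
  genes <- rownames(P) %||% sprintf("gene%04d", seq_len(nrow(P)))

  n <- cfg$n_cells_per_timepoint * cfg$n_timepoints
  win <- timepoint_windows(cfg$n_timepoints, cfg$timepoint_overlap)
  paths <- leaf_paths(topo)

  tp <- rep(seq_len(cfg$n_timepoints), each = cfg$n_cells_per_timepoint)
  pt <- runif(n, win[tp, "lo"], win[tp, "hi"])
  leaf <- names(paths)[sample.int(length(paths), n, replace = TRUE)]

  seg <- character(n)
  for (i in seq_len(n)) {
    path <- paths[[leaf[i]]]
    k <- match(path, topo$segment)
    j <- which(topo$t_start[k] <= pt[i] & pt[i] <= topo$t_end[k])
    seg[i] <- path[j[length(j)]]
  }
  si <- match(seg, topo$segment)
  u <- (pt - topo$t_start[si]) / (topo$t_end[si] - topo$t_start[si])

  # start level of a segment = parent's end level; baseline for the root
  start_level <- function(s) {
    p <- topo$parent[topo$segment == s]
    if (is.na(p)) base else P[, p]
  }
  # per-gene activation window within a segment: genes switch sequentially
  # (smoothstep over [mid - w/2, mid + w/2] of the segment position), so the
  # expression path is a curve with non-vanishing speed and cell positions
  # stay identifiable along it.  Windows start at or after the segment
  # start (continuity with the parent program) and midpoints are biased
  # early, as lineage-defining programs engage at commitment.
  n_genes <- nrow(P)
  wid <- runif(n_genes, 0.2, 0.4)
  mid <- runif(n_genes, wid / 2, 0.7)
  # a third of the genes switch immediately at segment entry: the
  # lineage-defining part of a program engages at commitment
  immediate <- runif(n_genes) < 1 / 3
  mid[immediate] <- wid[immediate] / 2
  act_a <- mid - wid / 2
  L <- matrix(0, n, n_genes)
  for (s in unique(seg)) {
    rows <- which(seg == s)
    s0 <- start_level(s)
    s1 <- P[, s]
    ur <- u[rows]
    S <- smoothstep((matrix(ur, length(rows), n_genes) -
                       matrix(act_a, length(rows), n_genes, byrow = TRUE)) /
                      matrix(wid, length(rows), n_genes, byrow = TRUE))
    L[rows, ] <- S * matrix(s1 - s0, length(rows), n_genes, byrow = TRUE) +
      matrix(s0, length(rows), n_genes, byrow = TRUE)
  }
  mu <- exp(L)
  counts <- matrix(rnbinom(length(mu), mu = mu, size = cfg$dispersion),
                   n, nrow(P))
  if (cfg$dropout > 0) {
    keep <- matrix(runif(length(mu)) >= cfg$dropout, n, nrow(P))
    counts <- counts * keep
  }
  cells <- sprintf("cell%05d", seq_len(n))
  dimnames(counts) <- list(cells, genes)

  terminal_of <- setNames(ifelse(topo$terminal, topo$segment, NA_character_),
                          topo$segment)
  truth_cells <- tibble(cell = cells,
                        true_pseudotime = pt,
                        true_segment = seg,
                        true_terminal_fate = unname(terminal_of[seg]),
                        timepoint = sprintf("t%d", tp - 1L))
  truth_genes <- tibble(gene = genes,
                        archetype = attr(P, "archetype") %||%
                          rep(NA_character_, nrow(P)))
  list(counts = counts, truth_cells = truth_cells, truth_genes = truth_genes,
       programs = P, timepoint = sprintf("t%d", tp - 1L))
}

#' Simulate a branching single-cell conversion experiment
#'
#' Cells are placed on the topology by sampling a timepoint window (windows
#' overlap to mimic asynchronous sampling), a pseudotime within it, and a
#' root-to-leaf path.  Gene log-expression interpolates each gene's program
#' between the segment's start and end levels with a cubic smoothstep;
#' counts are negative binomial around the exponentiated level, then zeroed
#' with the dropout probability.
#'
#' @param cfg A [sim_config()].
#' @return A list with `cells` (a [cell_table()]) and `truth` (a
#'   `ground_truth` list of `cells` and `genes` tibbles; the program matrix
#'   is attached as `truth$programs`).
#' @export
simulate_branching_trajectory <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    sim <- simulate_cells(cfg)
    mito <- attr(sim$programs, "mito") %||% rep(FALSE, ncol(sim$counts))
    ct <- cell_table(sim$counts,
                     cell_meta = tibble(cell = rownames(sim$counts),
                                        timepoint = sim$timepoint,
                                        batch = "sim"),
                     gene_meta = tibble(gene = colnames(sim$counts),
                                        mito = mito))
    truth <- structure(list(cells = sim$truth_cells, genes = sim$truth_genes,
                            programs = sim$programs),
                       class = "ground_truth")
    list(cells = ct, truth = truth)
  })
}

#' Simulate the embryo-like reference trajectory
#'
#' Uses the fixed bifurcating topology ICM -> \{EPI, PrE\}, PrE -> \{VE,
#' ParE\}.  A designated progenitor program (a set of genes expressed only on
#' the ICM segment) marks the uncommitted state; conversion simulations
#' built from the same branch programs leave these genes off, which is the
#' designed ground truth for "the in-vitro path bypasses the progenitor".
#' Timepoints are labelled with embryonic stages.
#'
#' @param cfg A [sim_config()]; its topology must be [topology_embryo()].
#'   When `cfg$programs` is `NULL`, default programs are built and the first
#'   `n_progenitor` housekeeping genes are converted into the ICM-only
#'   program.
#' @param n_progenitor Number of progenitor-program genes (default 40).
#' @param stages Stage labels for the timepoint windows.
#' @return As [simulate_branching_trajectory()]; cell truth gains `lineage`
#'   and `stage` columns and gene truth marks the progenitor program.
#' @export
simulate_reference_embryo <- function(cfg = sim_config(topology = topology_embryo()),
                                      n_progenitor = 40L,
                                      stages = c("E3.5", "E4.5", "E5.5",
                                                 "E7.5", "E8.75")) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!setequal(cfg$topology$segment, topology_embryo()$segment)) {
    abort("simulate_reference_embryo() requires the fixed embryo topology")
  }
  if (length(stages) != cfg$n_timepoints) {
    abort("one stage label per timepoint is required")
  }
  with_seed(cfg$seed, {
    P <- cfg$programs
    if (is.null(P)) {
      P <- default_programs(cfg$n_genes, cfg$topology, seed = cfg$seed)
      hk <- which((attr(P, "archetype")) == "housekeeping")
      if (length(hk) < n_progenitor) {
        abort("not enough non-marker genes to host the progenitor program")
      }
      prog <- hk[seq_len(n_progenitor)]
      arch <- attr(P, "archetype")
      base <- attr(P, "baseline")
      # ICM-only: off at the root start, high at ICM's end, off on all
      # downstream segments
      off <- log(0.05)
      base[prog] <- off
      P[prog, ] <- off
      P[prog, "ICM"] <- log(8)
      arch[prog] <- "progenitor"
      attr(P, "baseline") <- base
      attr(P, "archetype") <- arch
    } else {
      arch <- attr(P, "archetype")
      prog <- which(arch == "progenitor")
      if (length(prog) == 0L) abort("programs lack a progenitor gene set")
      branch_cols <- setdiff(colnames(P), "ICM")
      if (any(P[prog, branch_cols] > attr(P, "baseline")[prog] + 1e-9)) {
        abort("progenitor gene set overlaps branch programs")
      }
    }
    cfg$programs <- P
    cfg$seed <- NULL  # already inside the seeded context
    sim <- simulate_cells(cfg)
    mito <- attr(P, "mito") %||% rep(FALSE, ncol(sim$counts))
    stage <- stages[match(sim$timepoint, sprintf("t%d", seq_along(stages) - 1L))]
    ct <- cell_table(sim$counts,
                     cell_meta = tibble(cell = rownames(sim$counts),
                                        timepoint = sim$timepoint,
                                        batch = "embryo",
                                        lineage = sim$truth_cells$true_segment,
                                        stage = stage))
    ct$gene_meta$mito <- mito
    truth_cells <- dplyr::mutate(sim$truth_cells,
                                 lineage = .data$true_segment, stage = stage)
    truth <- structure(list(cells = truth_cells, genes = sim$truth_genes,
                            programs = P),
                       class = "ground_truth")
    list(cells = ct, truth = truth)
  })
}

#' Build an in-vitro conversion configuration from reference programs
#'
#' Constructs a linear conversion whose start and end expression programs are
#' taken from two segments of a reference simulation (e.g. PrE-like start to
#' EPI-like end for a XEN-to-iPS-like conversion).  Progenitor-program genes
#' stay at their silenced baseline throughout, so the simulated conversion
#' shares the reference's endpoint programs but never expresses the
#' uncommitted progenitor state.
#'
#' @param ref_truth `truth` element returned by [simulate_reference_embryo()].
#' @param from,to Reference segment names supplying the start and end
#'   programs.
#' @param ... Passed to [sim_config()] (e.g. `n_cells_per_timepoint`, `seed`).
#' @return A [sim_config()] with a linear topology.
#' @export
conversion_from_reference <- function(ref_truth, from = "PrE", to = "EPI",
                                      ...) {
  P <- ref_truth$programs
  topo <- topology_linear()
  Q <- matrix(P[, to], nrow(P), 1L, dimnames = list(rownames(P), "main"))
  attr(Q, "baseline") <- P[, from]
  attr(Q, "archetype") <- attr(P, "archetype")
  attr(Q, "mito") <- attr(P, "mito")
  sim_config(n_genes = nrow(P), topology = topo, programs = Q, ...)
}

#' Simulate a metacell peak-accessibility experiment
#'
#' Plants peak-dynamics classes across a series of ordered cell groups:
#' stable, late-opening, gradually opening, transiently opening and
#' late-closing accessibility profiles.  Counts are negative binomial around
#' the class profile; a subset of motifs is planted to hit only peaks of one
#' class, the rest hit peaks at random.
#'
#' @param n_peaks Number of peak loci.
#' @param n_groups Number of ordered cell groups (>= 2).
#' @param n_metacells_per_group Metacells per group.
#' @param depth Mean reads per fully open peak per metacell.
#' @param floor_frac Accessibility floor as a fraction of `depth`.
#' @param dispersion Negative-binomial size.
#' @param class_fractions Named fractions over the five dynamics classes.
#' @param peak_width Width of every peak locus in bp (default 501).
#' @param n_motifs Total motifs; `n_planted` of them hit only peaks of
#'   `planted_class`.
#' @param n_planted,planted_class Planted-motif count and their target class.
#' @param motif_hit_rate Hit probability for non-planted motifs.
#' @param seed Integer seed.
#' @return List with `counts` (a metacell-level [peak_matrix()] whose
#'   metadata carries the ordered `group`), `peaks` (a [peak_set()] with GC
#'   fraction), `motifs` (a binary [motif_hits()] matrix) and `truth`
#'   (planted peak classes and motif assignments).
#' @export
simulate_peak_experiment <- function(n_peaks = 2000L,
                                     n_groups = 5L,
                                     n_metacells_per_group = 20L,
                                     depth = 20,
                                     floor_frac = 0.1,
                                     dispersion = 10,
                                     class_fractions = c(stable = 0.4,
                                                         late_open = 0.15,
                                                         gradual_open = 0.15,
                                                         transient_open = 0.15,
                                                         late_close = 0.15),
                                     peak_width = 501L,
                                     n_motifs = 20L,
                                     n_planted = 2L,
                                     planted_class = "late_open",
                                     motif_hit_rate = 0.1,
                                     seed = 1L) {
  if (n_groups < 2L) abort("at least 2 cell groups are required")
  stopifnot(abs(sum(class_fractions) - 1) < 1e-8)
  with_seed(seed, {
    classes <- sample(names(class_fractions), n_peaks, replace = TRUE,
                      prob = class_fractions)
    x <- seq(0, 1, length.out = n_groups)
    profile_of <- function(cl) {
      switch(cl,
             stable = rep(0.5, n_groups),
             late_open = pmax(0, (x - 0.75) / 0.25),
             gradual_open = x,
             transient_open = 1 - abs(2 * x - 1),
             late_close = 1 - pmax(0, (x - 0.75) / 0.25),
             abort(sprintf("unknown peak class '%s'", cl)))
    }
    prof <- vapply(classes, profile_of, numeric(n_groups))  # groups x peaks
    mu_group <- depth * (floor_frac + (1 - floor_frac) * prof)

    n_mc <- n_groups * n_metacells_per_group
    grp <- rep(seq_len(n_groups), each = n_metacells_per_group)
    mu <- mu_group[grp, , drop = FALSE]
    counts <- matrix(rnbinom(length(mu), mu = mu, size = dispersion),
                     n_mc, n_peaks)
    mcs <- sprintf("mc%04d", seq_len(n_mc))
    peaks <- sprintf("peak%05d", seq_len(n_peaks))
    dimnames(counts) <- list(mcs, peaks)

    chrom <- sample(paste0("chr", 1:5), n_peaks, replace = TRUE)
    start <- sample.int(2e8, n_peaks, replace = TRUE)
    ps <- peak_set(tibble(chrom = chrom, start = start,
                          end = start + peak_width,
                          name = peaks,
                          gc = 0.2 + 0.6 * rbeta(n_peaks, 5, 5)))

    M <- matrix(FALSE, n_peaks, n_motifs,
                dimnames = list(peaks, sprintf("motif%02d", seq_len(n_motifs))))
    planted <- seq_len(n_planted)
    target <- which(classes == planted_class)
    for (m in planted) {
      hit <- target[runif(length(target)) < 0.6]
      M[hit, m] <- TRUE
    }
    for (m in setdiff(seq_len(n_motifs), planted)) {
      M[runif(n_peaks) < motif_hit_rate, m] <- TRUE
    }

    pm <- peak_matrix(counts, ps, level = "metacell",
                      meta = tibble(metacell = mcs,
                                    group = sprintf("g%d", grp)))
    truth <- structure(
      list(peaks = tibble(peak = peaks, class = classes),
           motifs = tibble(motif = colnames(M),
                           planted = seq_len(n_motifs) %in% planted,
                           target_class = ifelse(seq_len(n_motifs) %in% planted,
                                                 planted_class, NA_character_)),
           group_order = sprintf("g%d", seq_len(n_groups))),
      class = "ground_truth")
    list(counts = pm, peaks = ps, motifs = motif_hits(M), truth = truth)
  })
}

#' Simulate CpG-island-like methylation signal tracks
#'
#' Generates non-overlapping islands across a small set of chromosomes, each
#' carrying a non-negative signal strength (emulating a genome-wide CpG
#' island annotation of configurable size).
#'
#' @param n_islands Number of islands (default 17000).
#' @param chroms Chromosome names to spread islands over.
#' @param width_range Island width range in bp.
#' @param gap_range Gap range between consecutive islands in bp.
#' @param signal_mean Mean of the exponential signal distribution; 0 gives
#'   all-zero signal.
#' @param seed Integer seed.
#' @return A [peak_set()] with a `signal` column; islands are disjoint.
#' @export
simulate_methylation_tracks <- function(n_islands = 17000L,
                                        chroms = paste0("chr", 1:5),
                                        width_range = c(300L, 2000L),
                                        gap_range = c(1000L, 20000L),
                                        signal_mean = 5,
                                        seed = 1L) {
  with_seed(seed, {
    chrom <- sort(sample(chroms, n_islands, replace = TRUE))
    out <- lapply(split(seq_len(n_islands), chrom), function(idx) {
      k <- length(idx)
      w <- sample(width_range[1]:width_range[2], k, replace = TRUE)
      g <- sample(gap_range[1]:gap_range[2], k, replace = TRUE)
      start <- cumsum(g) + c(0, cumsum(w))[seq_len(k)]
      tibble(chrom = chrom[idx], start = start, end = start + w)
    })
    tab <- dplyr::bind_rows(out)
    tab$name <- sprintf("cpg%05d", seq_len(nrow(tab)))
    tab$signal <- if (signal_mean > 0) rexp(nrow(tab), 1 / signal_mean) else
      rep(0, nrow(tab))
    peak_set(tab)
  })
}
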