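# Metacell-level scATAC processing: TF-IDF/SVD embedding, metacell
# aggregation and normalization, highly variable peaks, K-S differential
# accessibility, pseudobulk, peak-dynamics classification, and interval
# utilities (BED semantics: 0-based half-open, strand ignored).

#' TF-IDF / SVD embedding of a peak count matrix
#'
#' Selects the `n_var` peaks with the highest total counts, normalizes by
#' term frequency-inverse document frequency
#' (`tf = count / cell_total`, `idf = log(1 + n_cells / (1 + n_cells_with_peak))`)
#' and reduces by truncated SVD.
#'
#' @param pm A cell-level [peak_matrix()].
#' @param n_var Number of variable peaks to keep (default 100000).
#' @param n_dims Number of SVD dimensions (default 30).
#' @return Cells x dims coordinate matrix with attributes `d` (singular
#'   values) and `peaks_used` (column indices).
#' @export
lsi_embed <- function(pm, n_var = 100000L, n_dims = 30L) {
  stopifnot(inherits(pm, "peak_matrix"))
  X <- pm$counts
  n_var <- min(n_var, ncol(X))
  if (n_dims >= min(dim(X))) abort("n_dims must be below min(n_cells, n_peaks)")
  keep <- head(order(colSums(X), decreasing = TRUE), n_var)
  keep <- sort(keep)
  X <- X[, keep, drop = FALSE]
  tot <- rowSums(X)
  if (any(tot <= 0)) abort("cells with zero counts in the selected peaks")
  tf <- X / tot
  idf <- log(1 + nrow(X) / (1 + colSums(X > 0)))
  M <- sweep(tf, 2L, idf, "*")
  sv <- if (min(dim(M)) <= 100L) {
    s <- svd(M, nu = n_dims, nv = 0)
    list(u = s$u, d = s$d[seq_len(n_dims)])
  } else {
    s <- irlba::irlba(M, nv = n_dims)
    list(u = s$u, d = s$d)
  }
  out <- sweep(sv$u, 2L, sv$d, "*")
  rownames(out) <- rownames(X)
  attr(out, "d") <- sv$d
  attr(out, "peaks_used") <- keep
  out
}

#' Assign cells to metacells
#'
#' Seeded k-means grouping in the embedding space — a simplified metacell
#' assigner; externally computed assignments (e.g. archetype-based) can be
#' supplied anywhere a `metacell_map` is accepted.
#'
#' @param coords Cells x dims embedding (e.g. from [lsi_embed()]).
#' @param n_metacells Number of metacells (>= 2, < n_cells).
#' @param seed Seed.
#' @return A `metacell_map`: tibble `cell`, `metacell` plus a `sizes` tibble.
#' @export
assign_metacells <- function(coords, n_metacells, seed = 0L) {
  coords <- as.matrix(coords)
  if (n_metacells < 2L) abort("n_metacells must be at least 2")
  if (n_metacells > nrow(coords)) abort("n_metacells must not exceed n_cells")
  cl <- if (n_metacells == nrow(coords)) {
    seq_len(nrow(coords))
  } else {
    km <- with_seed(seed, kmeans(coords, centers = n_metacells, nstart = 5L,
                                 iter.max = 100L))
    as.integer(km$cluster)
  }
  map <- tibble(cell = rownames(coords) %||% as.character(seq_len(nrow(coords))),
                metacell = sprintf("mc%04d", cl))
  structure(list(map = map,
                 sizes = dplyr::count(map, .data$metacell, name = "n_cells")),
            class = "metacell_map")
}

#' @export
print.metacell_map <- function(x, ...) {
  cat(sprintf("<metacell_map> %d cells -> %d metacells (mean size %.1f)\n",
              nrow(x$map), nrow(x$sizes), mean(x$sizes$n_cells)))
  invisible(x)
}

#' Aggregate cell counts into metacells
#'
#' Column-aligned sums of the counts of all cells assigned to each
#' metacell; total counts are conserved exactly.
#'
#' @param pm A cell-level [peak_matrix()].
#' @param mm A [assign_metacells()] map covering every cell.
#' @return A metacell-level [peak_matrix()].
#' @export
aggregate_metacells <- function(pm, mm) {
  stopifnot(inherits(pm, "peak_matrix"), inherits(mm, "metacell_map"))
  cells <- rownames(pm$counts) %||% as.character(seq_len(nrow(pm$counts)))
  idx <- match(cells, mm$map$cell)
  if (any(is.na(idx))) {
    abort(sprintf("cell '%s' is not mapped to a metacell",
                  cells[which(is.na(idx))[1L]]))
  }
  grp <- mm$map$metacell[idx]
  agg <- rowsum(pm$counts, group = grp)
  agg <- agg[order(rownames(agg)), , drop = FALSE]
  peak_matrix(agg, pm$peaks, level = "metacell",
              meta = tibble(metacell = rownames(agg)))
}

#' Median-scaled log normalization of metacell accessibility
#'
#' `value = ln(count / total * median_total + pseudo)` with pseudo-count 1.
#'
#' @param pm A metacell-level [peak_matrix()].
#' @param pseudo Pseudo-count (default 1).
#' @return A [peak_matrix()] with `normalized = TRUE`.
#' @export
normalize_metacells <- function(pm, pseudo = 1) {
  stopifnot(inherits(pm, "peak_matrix"))
  tot <- rowSums(pm$counts)
  if (any(tot <= 0)) {
    abort(sprintf("metacell(s) with zero total counts: %s",
                  paste(head(rownames(pm$counts)[tot <= 0], 5L),
                        collapse = ", ")))
  }
  med <- median(tot)
  vals <- log(pm$counts / tot * med + pseudo)
  out <- peak_matrix(vals, pm$peaks, level = pm$level,
                     meta = pm$meta, normalized = TRUE)
  attr(out, "scale_factor") <- med
  attr(out, "pseudo") <- pseudo
  out
}

#' Highly variable peaks
#'
#' Dispersion (variance/mean) per peak, z-scored within 20 equal-occupancy
#' bins of mean accessibility; peaks pass with normalized dispersion above
#' `min_disp` and mean above `min_mean`.
#'
#' @param norm A normalized metacell [peak_matrix()] (or matrix).
#' @param min_disp Normalized-dispersion threshold (default 3.0; 2.0 gives
#'   the conventional relaxed set).
#' @param min_mean Mean-accessibility threshold (default 0.0125).
#' @return Integer vector of peak column indices.
#' @export
highly_variable_peaks <- function(norm, min_disp = 3.0, min_mean = 0.0125) {
  X <- if (inherits(norm, "peak_matrix")) norm$counts else as.matrix(norm)
  if (nrow(X) < 2L) abort("at least 2 metacells are required")
  nd <- normalized_dispersion(X, n_bins = 20L)
  which(!is.na(nd$z) & nd$z > min_disp & nd$mean > min_mean)
}

#' Kolmogorov-Smirnov differential accessibility
#'
#' Two-sided two-sample K-S test per peak between two disjoint metacell
#' groups; the exact null distribution is used when the smaller group has
#' fewer than 10 metacells, the asymptotic one otherwise.
#'
#' @param norm Normalized metacell [peak_matrix()] (or matrix).
#' @param group_a,group_b Disjoint metacell row indices (each >= 3).
#' @param alpha Significance threshold (default 1e-4).
#' @return Tibble `peak`, `D`, `p`, `pass`.
#' @export
ks_differential_peaks <- function(norm, group_a, group_b, alpha = 1e-4) {
  X <- if (inherits(norm, "peak_matrix")) norm$counts else as.matrix(norm)
  if (length(intersect(group_a, group_b)) > 0L) {
    abort("metacell groups must be disjoint")
  }
  if (length(group_a) < 3L || length(group_b) < 3L) {
    abort("each group needs at least 3 metacells")
  }
  exact <- min(length(group_a), length(group_b)) < 10L
  res <- vapply(seq_len(ncol(X)), function(j) {
    kt <- suppressWarnings(ks.test(X[group_a, j], X[group_b, j],
                                   exact = exact))
    c(unname(kt$statistic), kt$p.value)
  }, numeric(2))
  tibble(peak = colnames(X) %||% as.character(seq_len(ncol(X))),
         D = res[1L, ], p = res[2L, ], pass = res[2L, ] < alpha)
}

#' Pseudobulk accessibility per cell group
#'
#' Arithmetic mean of (normalized) accessibility per group per peak.
#'
#' @param norm Normalized metacell [peak_matrix()] (or matrix).
#' @param groups Per-metacell group labels (a partition).
#' @return Groups x peaks matrix of means (rows in group order of first
#'   appearance, or factor-level order when `groups` is a factor).
#' @export
pseudobulk_groups <- function(norm, groups) {
  X <- if (inherits(norm, "peak_matrix")) norm$counts else as.matrix(norm)
  if (length(groups) != nrow(X)) abort("groups must cover all metacells")
  lv <- if (is.factor(groups)) levels(groups) else unique(as.character(groups))
  groups <- as.character(groups)
  cnt <- table(factor(groups, levels = lv))
  if (any(cnt == 0)) {
    abort(sprintf("empty group '%s'", names(cnt)[cnt == 0][1L]))
  }
  out <- rowsum(X, group = factor(groups, levels = lv)) / as.numeric(cnt)
  out[lv, , drop = FALSE]
}

#' Classify accessibility dynamics along ordered groups
#'
#' Operates on each peak's min-max-scaled profile across `>= 4` ordered
#' groups.  Rules (thresholds exposed as arguments): profiles whose raw
#' range is under `stable_range` are `stable`; an interior maximum
#' exceeding both scaled endpoints by `transient_margin` gives
#' `transient_open`; a scaled first value <= `low` and last value >= `high`
#' give `late_open` if at least `late_frac` of the rise occurs in the final
#' third of the group order, otherwise `gradual_open` when the profile is
#' monotone (Spearman rho >= `rho_min`); `late_close` mirrors `late_open`
#' reversed.  Unmatched profiles fall back to `stable`.
#'
#' @param pb Pseudobulk matrix from [pseudobulk_groups()].
#' @param group_order Character vector giving the temporal order of the
#'   rows of `pb`.
#' @param stable_range,low,high,transient_margin,late_frac,rho_min Rule
#'   thresholds.
#' @return Tibble `peak`, `class`.
#' @export
classify_peak_dynamics <- function(pb, group_order = rownames(pb),
                                   stable_range = 0.25, low = 0.25,
                                   high = 0.75, transient_margin = 0.5,
                                   late_frac = 0.7, rho_min = 0.8) {
  if (is.null(group_order) || !all(group_order %in% rownames(pb))) {
    abort("group_order must name rows of the pseudobulk matrix")
  }
  G <- length(group_order)
  if (G < 4L) abort("at least 4 ordered groups are required")
  M <- pb[group_order, , drop = FALSE]
  x <- seq(0, 1, length.out = G)
  final_third <- which(x >= 2 / 3)[1L]
  cls <- vapply(seq_len(ncol(M)), function(j) {
    p <- M[, j]
    rng <- max(p) - min(p)
    if (rng < stable_range) return("stable")
    s <- (p - min(p)) / rng
    interior <- s[-c(1L, G)]
    if (max(interior) >= s[1L] + transient_margin &&
        max(interior) >= s[G] + transient_margin) {
      return("transient_open")
    }
    if (s[1L] <= low && s[G] >= high) {
      rise_final <- s[G] - s[final_third]
      if (rise_final >= late_frac * (s[G] - s[1L])) return("late_open")
      rho <- suppressWarnings(cor(s, seq_len(G), method = "spearman"))
      if (is.finite(rho) && rho >= rho_min) return("gradual_open")
    }
    if (s[1L] >= high && s[G] <= low) {
      fall_final <- s[final_third] - s[G]
      if (fall_final >= late_frac * (s[1L] - s[G])) return("late_close")
    }
    "stable"
  }, character(1))
  tibble(peak = colnames(M) %||% as.character(seq_len(ncol(M))), class = cls)
}

#' Extend and merge intervals
#'
#' Each interval is extended by `extend` bp on both sides (clamped at 0),
#' then overlapping or adjacent intervals are merged per chromosome.
#' Summit lists extended by 50 bp reproduce the conventional 100-bp summit
#' merge.
#'
#' @param ps A [peak_set()].
#' @param extend Bp to extend on each side (default 0).
#' @return A merged [peak_set()].
#' @export
merge_intervals <- function(ps, extend = 0L) {
  gr <- as_granges(ps)
  if (extend > 0L) {
    gr <- GenomicRanges::resize(gr, GenomicRanges::width(gr) + 2L * extend,
                                fix = "center")
    GenomicRanges::start(gr) <- pmax(GenomicRanges::start(gr), 1L)
  }
  from_granges(GenomicRanges::reduce(gr))
}

#' Interval overlap test (half-open semantics)
#'
#' @param a,b [peak_set()]s on the same genome namespace.
#' @return List with `overlaps` (logical per interval of `a`) and `pairs`
#'   (tibble of overlapping index pairs).
#' @export
overlap_intervals <- function(a, b) {
  hits <- GenomicRanges::findOverlaps(as_granges(a), as_granges(b))
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  o <- order(q, s)
  list(overlaps = seq_len(nrow(a)) %in% q,
       pairs = tibble(a = q[o], b = s[o]))
}
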