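# Cross-trajectory machinery: pseudotime binning, bin-to-bin multi-scale
# distance matrices, nearest-bin mapping, joint layout, clustering,
# differential expression and signature scoring.

#' Bin cells along pseudotime
#'
#' Partitions `[0, 1]` into equal-width intervals `[i/n, (i+1)/n)` (the last
#' interval closed).  Empty bins are dropped with a warning.  Optional
#' stratification splits every interval by a per-cell label (e.g. lineage),
#' so stratified bins never mix labels.  Equal-count quantile bins are
#' available as an alternative reading of "equal sized".
#'
#' @param pt Pseudotime vector in `[0, 1]`.
#' @param n_bins Number of intervals (default 20).
#' @param stratify_by Optional per-cell label vector.
#' @param method `"width"` (default) for equal-width intervals, `"count"`
#'   for equal-occupancy quantile bins.
#' @return A `bin_partition`: list with `cell_bins` (per-cell bin id, NA for
#'   cells in dropped bins) and `bins` (tibble of bin metadata: interval,
#'   label, n_cells).
#' @export
pseudotime_bins <- function(pt, n_bins = 20L, stratify_by = NULL,
                            method = c("width", "count")) {
  method <- match.arg(method)
  if (n_bins < 2L) abort("n_bins must be at least 2")
  if (any(pt < -1e-12) || any(pt > 1 + 1e-12)) abort("pseudotime must lie in [0, 1]")
  pt <- pmin(pmax(pt, 0), 1)
  if (method == "width") {
    interval <- pmin(floor(pt * n_bins), n_bins - 1L) + 1L
    lo <- (seq_len(n_bins) - 1L) / n_bins
    hi <- seq_len(n_bins) / n_bins
  } else {
    br <- quantile(pt, probs = seq(0, 1, length.out = n_bins + 1L))
    br[1L] <- 0; br[n_bins + 1L] <- 1
    br <- cummax(as.numeric(br))
    interval <- pmin(pmax(findInterval(pt, br, rightmost.closed = TRUE), 1L),
                     n_bins)
    lo <- br[-length(br)]
    hi <- br[-1L]
  }
  if (is.null(stratify_by)) {
    key <- sprintf("bin%02d", interval)
    label <- rep(NA_character_, length(pt))
  } else {
    if (length(stratify_by) != length(pt)) {
      abort("stratify_by must have one label per cell")
    }
    key <- sprintf("bin%02d.%s", interval, stratify_by)
    label <- as.character(stratify_by)
  }
  tab <- tibble(cell = seq_along(pt), interval = interval, bin = key,
                label = label)
  bins <- tab |>
    dplyr::count(.data$interval, .data$bin, .data$label, name = "n_cells") |>
    dplyr::arrange(.data$interval, .data$bin) |>
    dplyr::mutate(pt_lo = lo[.data$interval], pt_hi = hi[.data$interval])
  n_empty <- if (is.null(stratify_by)) n_bins - length(unique(interval)) else NA
  if (!is.na(n_empty) && n_empty > 0L) {
    warn(sprintf("%d empty pseudotime bin(s) dropped", n_empty))
  }
  structure(list(cell_bins = tab, bins = bins, n_bins = as.integer(n_bins),
                 method = method),
            class = "bin_partition")
}

#' @export
print.bin_partition <- function(x, ...) {
  cat(sprintf("<bin_partition> %d cells in %d retained bins (%s)\n",
              nrow(x$cell_bins), nrow(x$bins), x$method))
  invisible(x)
}

#' Mean multi-scale distances between bin pairs
#'
#' Entry (i, j) is the mean multi-scale distance over all pairs of cells in
#' bin i of partition A and bin j of partition B.  When a bin pair exceeds
#' `max_pairs` cell pairs, a uniform subsample of pairs is used (seeded).
#'
#' @param ds A `diffusion_space` covering the cells of both partitions.
#' @param pa,pb [pseudotime_bins()] partitions; `cells_a`/`cells_b` give the
#'   indices of the partitions' cells within `ds` (defaults assume `pa`
#'   indexes `1..n_a` and `pb` the rest is explicit).
#' @param cells_a,cells_b Index vectors mapping partition cells into `ds`.
#' @param max_pairs Cap on cell pairs per bin pair (default 250000).
#' @param seed Seed for pair subsampling.
#' @return A `bin_distance`: matrix of mean distances with bin-descriptor
#'   tibbles as attributes.
#' @export
bin_distance_matrix <- function(ds, pa, pb,
                                cells_a = seq_len(nrow(pa$cell_bins)),
                                cells_b = seq_len(nrow(pb$cell_bins)),
                                max_pairs = 250000L, seed = 0L) {
  stopifnot(inherits(pa, "bin_partition"), inherits(pb, "bin_partition"))
  bins_a <- pa$bins$bin
  bins_b <- pb$bins$bin
  M <- matrix(NA_real_, length(bins_a), length(bins_b),
              dimnames = list(bins_a, bins_b))
  ia <- split(cells_a[pa$cell_bins$cell], pa$cell_bins$bin)
  ib <- split(cells_b[pb$cell_bins$cell], pb$cell_bins$bin)
  with_seed(seed, {
    for (a in bins_a) {
      ua <- ds$u[ia[[a]], , drop = FALSE]
      for (b in bins_b) {
        ub <- ds$u[ib[[b]], , drop = FALSE]
        np <- as.double(nrow(ua)) * nrow(ub)
        if (np <= max_pairs) {
          M[a, b] <- mean(cross_dist(ua, ub))
        } else {
          pick <- sample.int(np, max_pairs)
          ra <- ((pick - 1L) %% nrow(ua)) + 1L
          rb <- ((pick - 1L) %/% nrow(ua)) + 1L
          M[a, b] <- mean(sqrt(rowSums((ua[ra, , drop = FALSE] -
                                          ub[rb, , drop = FALSE])^2)))
        }
      }
    }
  })
  structure(list(dist = M, bins_a = pa$bins, bins_b = pb$bins),
            class = "bin_distance")
}

#' @export
print.bin_distance <- function(x, ...) {
  cat(sprintf("<bin_distance> %d x %d bins\n", nrow(x$dist), ncol(x$dist)))
  invisible(x)
}

#' Plot a bin-distance matrix
#'
#' @param object A `bin_distance`.
#' @param ... Unused.
#' @return A ggplot heatmap of mean multi-scale distances.
#' @export
autoplot.bin_distance <- function(object, ...) {
  df <- as.data.frame(as.table(object$dist))
  names(df) <- c("bin_a", "bin_b", "distance")
  ggplot2::ggplot(df, ggplot2::aes(.data$bin_b, .data$bin_a,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Map each bin of one trajectory to its closest bin of another
#'
#' Row-wise argmin of the mean multi-scale distance; ties break toward the
#' lower bin index.  The representative pseudotime reported for each mapped
#' bin is the median position of the cells in the nearest target bin.
#'
#' @param bd A [bin_distance_matrix()] result.
#' @param pt_b Optional pseudotime vector of the target cells (within the
#'   target partition's own ordering) used for the representative position.
#' @param pb Optional target [pseudotime_bins()] partition (needed with
#'   `pt_b`).
#' @return Tibble with `bin_a`, `bin_b`, `distance`, `label_b` and (when
#'   available) `rep_pseudotime`.
#' @export
map_bins <- function(bd, pt_b = NULL, pb = NULL) {
  stopifnot(inherits(bd, "bin_distance"))
  if (any(!is.finite(bd$dist))) abort("bin distances must be finite")
  j <- apply(bd$dist, 1L, which.min)  # which.min takes the first (lowest) tie
  out <- tibble(bin_a = rownames(bd$dist),
                bin_b = colnames(bd$dist)[j],
                distance = bd$dist[cbind(seq_along(j), j)],
                label_b = bd$bins_b$label[j])
  if (!is.null(pt_b) && !is.null(pb)) {
    med <- vapply(out$bin_b, function(b) {
      median(pt_b[pb$cell_bins$cell[pb$cell_bins$bin == b]])
    }, numeric(1))
    out$rep_pseudotime <- unname(med)
  }
  out
}

#' Force-directed layout of an affinity graph
#'
#' Fruchterman-Reingold layout with a fixed seed for reproducibility.
#'
#' @param A An [affinity_graph()].
#' @param iterations Number of layout iterations (default 500).
#' @param seed Layout seed.
#' @return Tibble with `cell`, `x`, `y`.
#' @export
coembed_layout <- function(A, iterations = 500L, seed = 0L) {
  M <- if (inherits(A, "affinity_graph")) A$A else A
  gr <- igraph::graph_from_adjacency_matrix(M, mode = "undirected",
                                            weighted = TRUE)
  xy <- with_seed(seed,
                  igraph::layout_with_fr(gr, niter = as.integer(iterations)))
  tibble(cell = seq_len(nrow(xy)), x = xy[, 1L], y = xy[, 2L])
}

# Stress of a layout: sum of squared deviations of realized edge lengths
# from unit length (diagnostic for layout-quality tests).
layout_stress <- function(A, coords) {
  M <- if (inherits(A, "affinity_graph")) A$A else A
  tr <- Matrix::mat2triplet(M)
  up <- tr$i < tr$j
  dx <- coords$x[tr$i[up]] - coords$x[tr$j[up]]
  dy <- coords$y[tr$i[up]] - coords$y[tr$j[up]]
  len <- sqrt(dx^2 + dy^2)
  sum((len / mean(len) - 1)^2)
}

#' Cluster cells
#'
#' Community mode builds a k-NN graph (k = 30 by default), re-weights edges
#' by the Jaccard similarity of the endpoints' neighbour sets, and runs
#' modularity (Louvain) community detection.  K-means mode runs seeded
#' k-means (conventionally on diffusion components with 30 centres).
#'
#' @param X Coordinate matrix (cells x dims).
#' @param method `"community"` or `"kmeans_diffusion"`.
#' @param k Neighbourhood size for community mode (default 30).
#' @param resolution Louvain resolution (default 1; 3 reproduces the finer
#'   clustering used for transition-state analysis).
#' @param n_clusters Centres for k-means mode (default 30).
#' @param seed Seed for both modes.
#' @return Integer cluster labels (1-based).
#' @export
cluster_cells <- function(X, method = c("community", "kmeans_diffusion"),
                          k = 30L, resolution = 1, n_clusters = 30L,
                          seed = 0L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (method == "community") {
    k <- min(k, nrow(X) - 1L)
    g <- knn_graph(X, k)
    nb <- lapply(seq_len(g$n), function(i) c(i, g$index[i, ]))
    i <- rep(seq_len(g$n), g$k)
    j <- as.vector(g$index)
    jac <- vapply(seq_along(i), function(e) {
      a <- nb[[i[e]]]; b <- nb[[j[e]]]
      length(intersect(a, b)) / length(union(a, b))
    }, numeric(1))
    W <- Matrix::sparseMatrix(i = i, j = j, x = jac, dims = c(g$n, g$n))
    W <- (W + Matrix::t(W)) / 2
    gr <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                              weighted = TRUE)
    cl <- with_seed(seed,
                    igraph::cluster_louvain(gr, resolution = resolution))
    as.integer(igraph::membership(cl))
  } else {
    km <- with_seed(seed, kmeans(X, centers = min(n_clusters, nrow(X)),
                                 nstart = 10L, iter.max = 100L))
    as.integer(km$cluster)
  }
}

#' Differential expression by rank-sum test
#'
#' Two-sided Wilcoxon rank-sum test per gene between a target group and the
#' remaining cells (or a named baseline group), Benjamini-Hochberg FDR, and
#' log fold change of group means on the normalized scale.  The defaults
#' mirror terminal-state signature construction: FDR < 0.01, lfc > 2, top
#' 50 genes by FDR then |lfc|.
#'
#' @param nm A [normalized_matrix()] (or plain cells x genes matrix).
#' @param labels Per-cell group labels.
#' @param target_group Label of the group of interest.
#' @param baseline_group Optional label to compare against; default all
#'   other cells.
#' @param p_max FDR threshold (default 0.01).
#' @param lfc_min Minimum log fold change (default 2).
#' @param top_n Optional cap on the number of genes returned (default 50).
#' @return Tibble `gene`, `p`, `fdr`, `lfc`, `rank`, filtered and ranked.
#' @export
differential_genes <- function(nm, labels, target_group,
                               baseline_group = NULL, p_max = 0.01,
                               lfc_min = 2, top_n = 50L) {
  X <- if (inherits(nm, "normalized_matrix")) nm$values else as.matrix(nm)
  if (length(labels) != nrow(X)) abort("labels must cover all cells")
  a <- which(labels == target_group)
  b <- if (is.null(baseline_group)) which(labels != target_group) else
    which(labels == baseline_group)
  if (length(a) < 2L || length(b) < 2L) {
    abort("each group needs at least 2 cells")
  }
  p <- ranksum_pvalues(X[a, , drop = FALSE], X[b, , drop = FALSE])
  lfc <- colMeans(X[a, , drop = FALSE]) - colMeans(X[b, , drop = FALSE])
  tab <- tibble(gene = colnames(X) %||% as.character(seq_len(ncol(X))),
                p = p,
                fdr = p.adjust(p, "BH"),
                lfc = lfc) |>
    dplyr::filter(.data$fdr < p_max, .data$lfc > lfc_min) |>
    dplyr::arrange(.data$fdr, dplyr::desc(abs(.data$lfc)))
  if (!is.null(top_n)) tab <- head(tab, top_n)
  dplyr::mutate(tab, rank = dplyr::row_number())
}

# Two-sided Wilcoxon rank-sum p-values per column.  stats::wilcox.test
# chooses the exact null distribution for small tie-free samples and the
# tie-corrected normal approximation otherwise.
ranksum_pvalues <- function(Xa, Xb) {
  vapply(seq_len(ncol(Xa)), function(j) {
    suppressWarnings(wilcox.test(Xa[, j], Xb[, j])$p.value)
  }, numeric(1))
}

#' Signature scores
#'
#' Per-gene z-score across cells, averaged over each gene set per cell.
#'
#' @param nm A [normalized_matrix()] (or matrix).
#' @param gene_sets Named list of character vectors of gene names.
#' @return Cells x sets score matrix.
#' @export
signature_scores <- function(nm, gene_sets) {
  X <- if (inherits(nm, "normalized_matrix")) nm$values else as.matrix(nm)
  if (length(gene_sets) == 0L) abort("gene_sets must be non-empty")
  Z <- scale(X)
  Z[, attr(Z, "scaled:scale") == 0] <- 0
  out <- vapply(names(gene_sets), function(s) {
    genes <- intersect(gene_sets[[s]], colnames(X))
    if (length(genes) == 0L) {
      abort(sprintf("gene set '%s' has no genes in the matrix", s))
    }
    rowMeans(Z[, genes, drop = FALSE])
  }, numeric(nrow(X)))
  matrix(out, nrow = nrow(X),
         dimnames = list(rownames(X), names(gene_sets)))
}
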