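# Smoothed gene-expression trends along pseudotime and their clustering
# into coordinated programs.

#' Fit gene-expression trends along pseudotime
#'
#' Per gene, a penalized cubic-regression-spline smoother of expression on
#' pseudotime (a generalized additive model with GCV-selected smoothing),
#' optionally weighted by branch probabilities so that a trend follows one
#' terminal's branch.  Trends are evaluated on a regular pseudotime grid.
#'
#' @param expr Cells x genes matrix (typically imputed expression).
#' @param pt Pseudotime in `[0, 1]`.
#' @param weights Optional per-cell weights (e.g. a branch-probability
#'   column); zero-weight cells have no leverage on the fit.
#' @param grid_size Number of grid points (default 500).
#' @param k Spline basis dimension (default 8).
#' @param se Return pointwise standard errors too.
#' @return A `trend_set`: `trends` (genes x grid), `grid`, optional `se`.
#' @export
fit_trends <- function(expr, pt, weights = NULL, grid_size = 500L, k = 8L,
                       se = FALSE) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 10L) abort("at least 10 cells are required")
  if (length(pt) != nrow(expr)) abort("pt must cover all cells")
  if (!is.null(weights)) {
    if (length(weights) != nrow(expr)) abort("weights must cover all cells")
    if (any(weights < 0)) abort("weights must be non-negative")
    # zero-weight cells must have no leverage at all, including on the
    # GCV smoothing selection: drop them before fitting
    keep <- weights > 0
    expr <- expr[keep, , drop = FALSE]
    pt <- pt[keep]
    weights <- weights[keep]
  }
  grid <- seq(0, 1, length.out = grid_size)
  genes <- colnames(expr) %||% sprintf("gene%04d", seq_len(ncol(expr)))
  fit_one <- function(y) {
    if (var(y) < 1e-14) {
      m <- if (is.null(weights)) mean(y) else
        sum(y * weights) / sum(weights)
      return(list(fit = rep(m, grid_size), se = rep(0, grid_size)))
    }
    dat <- data.frame(y = y, pt = pt)
    kk <- min(k, length(unique(pt)) - 1L)
    g <- mgcv::gam(y ~ s(pt, k = kk, bs = "cr"), data = dat,
                   weights = weights, method = "GCV.Cp")
    p <- predict(g, newdata = data.frame(pt = grid), se.fit = se)
    if (se) list(fit = as.numeric(p$fit), se = as.numeric(p$se.fit))
    else list(fit = as.numeric(p), se = NULL)
  }
  res <- lapply(seq_len(ncol(expr)), function(j) fit_one(expr[, j]))
  trends <- do.call(rbind, lapply(res, `[[`, "fit"))
  rownames(trends) <- genes
  se_mat <- if (se) {
    m <- do.call(rbind, lapply(res, `[[`, "se")); rownames(m) <- genes; m
  } else NULL
  structure(list(trends = trends, grid = grid, se = se_mat,
                 weighted = !is.null(weights)),
            class = "trend_set")
}

#' @export
print.trend_set <- function(x, ...) {
  cat(sprintf("<trend_set> %d genes on a %d-point grid%s\n",
              nrow(x$trends), length(x$grid),
              if (x$weighted) " (branch-weighted)" else ""))
  invisible(x)
}

#' Plot fitted trends
#'
#' @param object A `trend_set`.
#' @param genes Optional subset of gene names to draw.
#' @param ... Unused.
#' @return A ggplot of z-scored trends along the pseudotime grid.
#' @export
autoplot.trend_set <- function(object, genes = NULL, ...) {
  M <- object$trends
  if (!is.null(genes)) M <- M[genes, , drop = FALSE]
  Z <- t(scale(t(M)))
  df <- as.data.frame(as.table(Z))
  names(df) <- c("gene", "grid_idx", "z")
  df$pt <- object$grid[as.integer(df$grid_idx)]
  ggplot2::ggplot(df, ggplot2::aes(.data$pt, .data$z, group = .data$gene)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "pseudotime", y = "z-scored trend") +
    ggplot2::theme_minimal()
}

#' Cluster gene trends into coordinated programs
#'
#' Trends are z-scored per gene; a gene-gene graph connects pairs whose
#' correlation distance `1 - cor` is within `radius`, with affinity
#' `1 - distance`; Louvain community detection with a fixed seed yields
#' clusters; clusters smaller than `min_size` are dropped and their genes
#' labelled unassigned (NA).
#'
#' @param ts A [fit_trends()] result.
#' @param radius Correlation-distance radius (default 0.025).
#' @param min_size Minimum cluster size (default 2).
#' @param seed Louvain seed.
#' @return A `trend_clusters`: tibble `gene`, `cluster` (NA = unassigned)
#'   plus a `sizes` tibble.
#' @export
cluster_trends <- function(ts, radius = 0.025, min_size = 2L, seed = 0L) {
  stopifnot(inherits(ts, "trend_set"))
  M <- ts$trends
  if (nrow(M) < 2L) abort("at least 2 genes are required")
  v <- apply(M, 1L, var)
  flat <- v < 1e-12
  if (any(flat)) {
    warn(sprintf("%d zero-variance trend(s) excluded from clustering",
                 sum(flat)))
  }
  keep <- which(!flat)
  Z <- t(scale(t(M[keep, , drop = FALSE])))
  C <- cor(t(Z))
  D <- 1 - C
  A <- 1 - D
  A[D > radius] <- 0
  diag(A) <- 0
  A <- (A + t(A)) / 2  # symmetrize the radius graph
  gr <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                            weighted = TRUE)
  cl <- with_seed(seed, igraph::cluster_louvain(gr))
  memb <- as.integer(igraph::membership(cl))
  sizes <- table(memb)
  small <- as.integer(names(sizes)[sizes < min_size])
  memb[memb %in% small] <- NA_integer_
  # renumber surviving clusters by decreasing size
  surv <- sort(table(memb), decreasing = TRUE)
  remap <- setNames(seq_along(surv), names(surv))
  memb <- unname(remap[as.character(memb)])
  cluster <- rep(NA_integer_, nrow(M))
  cluster[keep] <- memb
  out <- tibble(gene = rownames(M), cluster = as.integer(cluster))
  structure(list(clusters = out,
                 sizes = dplyr::count(dplyr::filter(out, !is.na(.data$cluster)),
                                      .data$cluster, name = "n_genes")),
            class = "trend_clusters")
}

#' @export
print.trend_clusters <- function(x, ...) {
  cat(sprintf("<trend_clusters> %d genes, %d clusters (%d unassigned)\n",
              nrow(x$clusters), nrow(x$sizes), sum(is.na(x$clusters$cluster))))
  invisible(x)
}

#' @export
tidy.trend_clusters <- function(x, ...) x$clusters
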