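# k-NN graphs, the adaptive distance-scaled affinity kernel, mutual nearest
# neighbours, and augmented affinity matrices joining datasets/timepoints.

#' Exact k-nearest-neighbour graph
#'
#' Euclidean k-NN with deterministic tie-breaking by ascending index.
#'
#' @param X Numeric coordinate matrix (cells in rows).
#' @param k Number of neighbours (default 50).
#' @return A `neighbor_graph`: list with `index` (n x k neighbour indices),
#'   `dist` (n x k distances), `k` and `n`.
#' @export
knn_graph <- function(X, k = 50L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) abort("at least 2 points are required")
  if (k >= n) abort("k must be smaller than the number of points")
  D <- cross_dist(X, X)
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    o <- order(d, seq_len(n))[seq_len(k)]  # ties broken by index
    idx[i, ] <- o
    dst[i, ] <- d[o]
  }
  structure(list(index = idx, dist = dst, k = as.integer(k), n = n),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("<neighbor_graph> %d cells, k = %d\n", x$n, x$k))
  invisible(x)
}

# Sparse distance matrix of a neighbor graph (directed: rows -> neighbours).
nn_sparse <- function(g) {
  Matrix::sparseMatrix(i = rep(seq_len(g$n), g$k),
                       j = as.vector(g$index),
                       x = as.vector(g$dist),
                       dims = c(g$n, g$n))
}

# Bandwidths: distance to the l-th neighbour; zeros replaced by the smallest
# positive bandwidth in the graph.
knn_bandwidth <- function(g, l) {
  if (l < 1L || l >= g$k + 1L && l > g$k) abort("l out of range")
  sigma <- g$dist[, l]
  if (any(sigma == 0)) {
    pos <- sigma[sigma > 0]
    if (length(pos) == 0L) abort("all bandwidths are zero (duplicate data?)")
    sigma[sigma == 0] <- min(pos)
  }
  sigma
}

#' Adaptive anisotropic affinity kernel
#'
#' Converts a k-NN distance graph into affinities with a per-cell bandwidth:
#' the distance to each cell's l-th neighbour.  The default kernel is
#' `a_ij = exp(-d_ij^2 / (sigma_i * sigma_j))` evaluated on the union of
#' neighbourhoods and symmetrized as `(A + t(A)) / 2`.  The alternative
#' `"local"` kernel uses `exp(-d_ij^2 / sigma_i^2)` before the same
#' averaging.
#'
#' @param g A [knn_graph()].
#' @param l Bandwidth neighbour rank; default `round(k / 3)` (17 for the
#'   conventional k = 50).
#' @param kernel `"geometric"` (default) or `"local"`.
#' @return An `affinity_graph`: sparse symmetric non-negative matrix with a
#'   `provenance` attribute.
#' @export
adaptive_affinity <- function(g, l = round(g$k / 3), kernel = c("geometric", "local")) {
  stopifnot(inherits(g, "neighbor_graph"))
  kernel <- match.arg(kernel)
  l <- as.integer(l)
  if (l < 1L || l >= g$k + 1L) abort("l must satisfy 1 <= l <= k")
  sigma <- knn_bandwidth(g, l)
  i <- rep(seq_len(g$n), g$k)
  j <- as.vector(g$index)
  d <- as.vector(g$dist)
  a <- if (kernel == "geometric") {
    exp(-d^2 / (sigma[i] * sigma[j]))
  } else {
    exp(-d^2 / sigma[i]^2)
  }
  A <- Matrix::sparseMatrix(i = i, j = j, x = a, dims = c(g$n, g$n))
  A <- (A + Matrix::t(A)) / 2
  Matrix::diag(A) <- 0
  A <- Matrix::drop0(A)
  affinity_graph(A, provenance = sprintf("adaptive kernel (%s), l = %d, k = %d",
                                         kernel, l, g$k))
}

#' Construct an affinity graph
#'
#' @param A Sparse symmetric non-negative matrix with zero diagonal.
#' @param provenance Character vector describing the edge sets.
#' @return An `affinity_graph` (a `dgCMatrix` with class and provenance
#'   attributes).
#' @export
affinity_graph <- function(A, provenance = character()) {
  A <- as(as(A, "CsparseMatrix"), "generalMatrix")
  if (max(abs(A - Matrix::t(A))) > 1e-12) abort("affinity matrix must be symmetric")
  if (any(A@x < 0)) abort("affinities must be non-negative")
  attr(A, "provenance") <- provenance
  class(A) <- c(class(A))
  structure(list(A = A, provenance = provenance), class = "affinity_graph")
}

#' @export
print.affinity_graph <- function(x, ...) {
  cat(sprintf("<affinity_graph> %d cells, %d edges\n  provenance: %s\n",
              nrow(x$A), length(x$A@x) / 2,
              paste(x$provenance, collapse = "; ")))
  invisible(x)
}

#' Mutual nearest neighbours between two datasets
#'
#' An edge (a, b) is retained iff b is among a's k nearest neighbours in B
#' and a is among b's k nearest neighbours in A.
#'
#' @param Xa,Xb Coordinate matrices (same dimensionality).
#' @param k Neighbourhood size (default 50, capped at the dataset size).
#' @return Tibble with columns `a`, `b`, `dist`.
#' @export
mutual_nn <- function(Xa, Xb, k = 50L) {
  Xa <- as.matrix(Xa); Xb <- as.matrix(Xb)
  if (nrow(Xa) == 0L || nrow(Xb) == 0L) abort("both datasets must be non-empty")
  k_ab <- min(k, nrow(Xb))
  k_ba <- min(k, nrow(Xa))
  D <- cross_dist(Xa, Xb)
  nn_ab <- t(apply(D, 1L, function(d) order(d, seq_along(d))[seq_len(k_ab)]))
  nn_ba <- t(apply(D, 2L, function(d) order(d, seq_along(d))[seq_len(k_ba)]))
  if (k_ab == 1L) nn_ab <- matrix(nn_ab, ncol = 1L)
  if (k_ba == 1L) nn_ba <- matrix(nn_ba, ncol = 1L)
  ii <- rep(seq_len(nrow(Xa)), k_ab)
  jj <- as.vector(nn_ab)
  mutual <- vapply(seq_along(ii), function(e) {
    ii[e] %in% nn_ba[jj[e], ]
  }, logical(1))
  tibble(a = ii[mutual], b = jj[mutual],
         dist = D[cbind(ii[mutual], jj[mutual])]) |>
    dplyr::arrange(.data$a, .data$b)
}

#' Per-group building block for graph augmentation
#'
#' Packages a group's coordinates with its within-group k-NN graph and
#' adaptive affinity, ready for [augment_affinity()].
#'
#' @param X Coordinates of the group's cells.
#' @param k,l Kernel parameters as in [adaptive_affinity()].
#' @param kernel Kernel flavour.
#' @return List with `coords`, `knn`, `affinity`, `sigma`.
#' @export
affinity_block <- function(X, k = 50L, l = round(k / 3),
                           kernel = c("geometric", "local")) {
  kernel <- match.arg(kernel)
  k <- min(k, nrow(X) - 1L)
  l <- min(max(1L, as.integer(l)), k)
  g <- knn_graph(X, k)
  list(coords = as.matrix(X), knn = g,
       affinity = adaptive_affinity(g, l, kernel),
       sigma = knn_bandwidth(g, l))
}

#' Cross-edge specification for augmentation
#'
#' @param a,b Group names to join by mutual nearest neighbours.
#' @param subset_a,subset_b Optional logical/integer subsets restricting the
#'   cells considered on each side (e.g. a shared lineage present at two
#'   stages).
#' @param k MNN neighbourhood size.
#' @param label Optional human-readable description recorded in provenance.
#' @return A `cross_spec` list.
#' @export
cross_spec <- function(a, b, subset_a = NULL, subset_b = NULL, k = 50L,
                       label = NULL) {
  structure(list(a = a, b = b, subset_a = subset_a, subset_b = subset_b,
                 k = as.integer(k),
                 label = label %||% sprintf("MNN(%s, %s)", a, b)),
            class = "cross_spec")
}

#' Augmented affinity matrix across cell groups
#'
#' Joins per-group affinity graphs block-diagonally and adds adaptive-kernel
#' affinities on every mutual-nearest-neighbour cross edge requested.  Cross
#' edge bandwidths use each endpoint's within-group l-th-neighbour distance.
#' Every cross specification is recorded verbatim in the result's
#' provenance.
#'
#' @param blocks Named list of [affinity_block()]s (groups must be
#'   disjoint cell sets; names are the group identifiers).
#' @param cross_specs List of [cross_spec()]s.
#' @return An [affinity_graph()] over the concatenated cells, with a
#'   `groups` attribute mapping rows to group names.
#' @export
augment_affinity <- function(blocks, cross_specs = list()) {
  if (is.null(names(blocks)) || any(names(blocks) == "")) {
    abort("blocks must be a named list")
  }
  sizes <- vapply(blocks, function(b) nrow(b$coords), integer(1))
  offset <- c(0L, cumsum(sizes))[seq_along(sizes)]
  names(offset) <- names(blocks)
  n <- sum(sizes)

  tri <- list()
  for (g in names(blocks)) {
    A <- blocks[[g]]$affinity$A
    T3 <- Matrix::mat2triplet(A)
    tri[[g]] <- tibble(i = T3$i + offset[[g]], j = T3$j + offset[[g]],
                       x = T3$x)
  }
  prov <- unlist(lapply(names(blocks), function(g) {
    sprintf("within-group: %s (%s)", g,
            paste(blocks[[g]]$affinity$provenance, collapse = "; "))
  }))

  for (cs in cross_specs) {
    if (!cs$a %in% names(blocks)) abort(sprintf("unknown group '%s'", cs$a))
    if (!cs$b %in% names(blocks)) abort(sprintf("unknown group '%s'", cs$b))
    ba <- blocks[[cs$a]]; bb <- blocks[[cs$b]]
    ia <- seq_len(nrow(ba$coords))
    ib <- seq_len(nrow(bb$coords))
    if (!is.null(cs$subset_a)) ia <- ia[cs$subset_a]
    if (!is.null(cs$subset_b)) ib <- ib[cs$subset_b]
    if (length(ia) == 0L || length(ib) == 0L) next
    mnn <- mutual_nn(ba$coords[ia, , drop = FALSE],
                     bb$coords[ib, , drop = FALSE],
                     k = cs$k)
    if (nrow(mnn) > 0L) {
      ga <- ia[mnn$a]; gb <- ib[mnn$b]
      aff <- exp(-mnn$dist^2 / (ba$sigma[ga] * bb$sigma[gb]))
      gi <- ga + offset[[cs$a]]
      gj <- gb + offset[[cs$b]]
      tri[[length(tri) + 1L]] <- tibble(i = c(gi, gj), j = c(gj, gi),
                                        x = rep(aff, 2L))
    }
    prov <- c(prov, sprintf("cross: %s [k = %d, %d edges]", cs$label, cs$k,
                            nrow(mnn)))
  }

  tt <- dplyr::bind_rows(tri)
  A <- Matrix::sparseMatrix(i = tt$i, j = tt$j, x = tt$x, dims = c(n, n),
                            use.last.ij = FALSE)
  A <- (A + Matrix::t(A)) / 2  # idempotent for already-symmetric input
  Matrix::diag(A) <- 0
  out <- affinity_graph(Matrix::drop0(A), provenance = prov)
  attr(out, "groups") <- rep(names(blocks), sizes)
  out
}
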