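# Diffusion operator, eigendecomposition with eigengap selection,
# multi-scale coordinates/distances, and diffusion-based imputation.

#' Row-stochastic Markov operator from an affinity graph
#'
#' @param A An [affinity_graph()] or sparse symmetric matrix.
#' @return Sparse row-stochastic operator `T = D^-1 A`.
#' @export
markov_operator <- function(A) {
  M <- if (inherits(A, "affinity_graph")) A$A else A
  T_ <- as(row_stochastic(M), "CsparseMatrix")
  attr(T_, "degree") <- as.numeric(Matrix::rowSums(M))
  T_
}

#' Diffusion maps of a Markov operator
#'
#' Eigendecomposes the diffusion operator through its degree-symmetrized
#' form `D^{1/2} T D^{-1/2}` (numerically stable; shares T's spectrum) and
#' maps eigenvectors back.  The number of informative components is chosen
#' by the largest consecutive eigenvalue drop among the non-trivial
#' eigenvalues (eigengap), or fixed by the caller.  Multi-scale coordinates
#' re-weight each selected eigenvector by `lambda / (1 - lambda)`.
#'
#' @param T_ Row-stochastic sparse operator from [markov_operator()].
#' @param n_eigs Number of eigenpairs to compute (default 20).
#' @param select `"eigengap"` (default) or `"fixed"`.
#' @param n_fixed Number of components when `select = "fixed"` (e.g. 14 for
#'   a joint two-trajectory operator).
#' @return A `diffusion_space`: eigenvalues (descending, leading value 1 on
#'   a connected graph), eigenvectors `psi` (cells x n_eigs), `n_selected`,
#'   and multi-scale coordinates `u` (cells x n_selected).
#' @export
diffusion_maps <- function(T_, n_eigs = 20L, select = c("eigengap", "fixed"),
                           n_fixed = NULL) {
  select <- match.arg(select)
  n <- nrow(T_)
  n_eigs <- min(as.integer(n_eigs), n - 1L)
  rs <- Matrix::rowSums(T_)
  if (max(abs(rs - 1)) > 1e-8) abort("operator is not row-stochastic")

  # reconstruct degrees from the operator is not possible; symmetrize using
  # the stationary scaling: for T = D^-1 A with symmetric A, pi ~ d, and
  # S = D^{1/2} T D^{-1/2} is symmetric.  We recover d from the attribute
  # set by markov_operator when available, else by solving for the
  # stationary distribution.
  d <- attr(T_, "degree")
  if (is.null(d)) {
    d <- stationary_distribution(T_)
  }
  sq <- sqrt(d)
  S <- Matrix::Diagonal(x = sq) %*% T_ %*% Matrix::Diagonal(x = 1 / sq)
  S <- (S + Matrix::t(S)) / 2

  if (n < 200L) {
    e <- eigen(as.matrix(S), symmetric = TRUE)
    vals <- e$values[seq_len(n_eigs)]
    vecs <- e$vectors[, seq_len(n_eigs), drop = FALSE]
  } else {
    e <- tryCatch(
      RSpectra::eigs_sym(S, k = n_eigs, which = "LA"),
      error = function(err) abort(sprintf("eigensolver failed: %s",
                                          conditionMessage(err))))
    if (length(e$values) < n_eigs) {
      abort(sprintf("eigensolver converged for only %d of %d eigenpairs",
                    length(e$values), n_eigs))
    }
    o <- order(e$values, decreasing = TRUE)
    vals <- e$values[o]
    vecs <- e$vectors[, o, drop = FALSE]
  }
  # map back to right eigenvectors of T and normalize
  psi <- vecs / sq
  psi <- sweep(psi, 2L, sqrt(colSums(psi^2)), "/")
  # canonical sign: largest-magnitude loading positive
  for (j in seq_len(ncol(psi))) {
    m <- which.max(abs(psi[, j]))
    if (psi[m, j] < 0) psi[, j] <- -psi[, j]
  }

  if (select == "fixed") {
    if (is.null(n_fixed)) abort("n_fixed must be given when select = 'fixed'")
    n_selected <- as.integer(n_fixed)
  } else {
    # largest consecutive drop among the non-trivial eigenvalues; at least 2
    # components (a single component cannot support multi-scale distances)
    gaps <- vals[-length(vals)] - vals[-1L]
    gaps <- gaps[-1L]  # exclude the trivial lambda_0 drop
    n_selected <- max(2L, which.max(gaps))
  }
  n_selected <- min(n_selected, n_eigs - 1L)

  lam <- vals[1L + seq_len(n_selected)]
  lam_c <- pmin(lam, 1 - 1e-10)
  u <- sweep(psi[, 1L + seq_len(n_selected), drop = FALSE], 2L,
             lam_c / (1 - lam_c), "*")

  structure(list(eigenvalues = vals, psi = psi, n_selected = n_selected,
                 u = u),
            class = "diffusion_space")
}

#' @export
print.diffusion_space <- function(x, ...) {
  cat(sprintf("<diffusion_space> %d cells, %d eigenpairs, %d selected\n",
              nrow(x$psi), length(x$eigenvalues), x$n_selected))
  invisible(x)
}

# Stationary distribution of a row-stochastic operator via power iteration
# (for symmetric-affinity operators this is proportional to the degrees).
stationary_distribution <- function(T_, tol = 1e-12, max_iter = 10000L) {
  n <- nrow(T_)
  p <- rep(1 / n, n)
  Tt <- Matrix::t(T_)
  for (i in seq_len(max_iter)) {
    q <- as.numeric(Tt %*% p)
    q <- q / sum(q)
    if (max(abs(q - p)) < tol) return(q)
    p <- q
  }
  p
}

#' Multi-scale distances between cell sets
#'
#' Euclidean distance in the multi-scale diffusion coordinates `u`.
#'
#' @param ds A `diffusion_space`.
#' @param idx_a,idx_b Cell index vectors.
#' @return Dense `|a| x |b|` distance matrix.
#' @export
multiscale_distance <- function(ds, idx_a, idx_b) {
  stopifnot(inherits(ds, "diffusion_space"))
  cross_dist(ds$u[idx_a, , drop = FALSE], ds$u[idx_b, , drop = FALSE])
}

#' Diffusion-based imputation
#'
#' Smooths expression over the cell graph by applying the diffusion
#' operator `t` times: `T^t X`.
#'
#' @param T_ Row-stochastic operator.
#' @param X Cells x genes matrix of (normalized) values.
#' @param t Number of diffusion steps (default 3).
#' @return Imputed dense matrix of the same shape.
#' @export
impute <- function(T_, X, t = 3L) {
  if (t < 0) abort("t must be non-negative")
  X <- as.matrix(X)
  if (nrow(X) != nrow(T_)) abort("shapes are not conformable")
  out <- X
  for (s in seq_len(t)) out <- as.matrix(T_ %*% out)
  dimnames(out) <- dimnames(X)
  out
}
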