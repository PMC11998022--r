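# Count-matrix QC, normalization, variable-gene selection and PCA — the
# steps applied upstream of all trajectory analysis.

#' Remove cells with excessive mitochondrial content
#'
#' Cells whose fraction of molecules assigned to mitochondrial genes exceeds
#' the threshold are treated as apoptotic and removed.
#'
#' @param ct A [cell_table()] whose `gene_meta` has a logical `mito` column.
#' @param mito_fraction_max Maximum tolerated mitochondrial fraction
#'   (default 0.20).
#' @return The filtered [cell_table()].
#' @export
filter_cells <- function(ct, mito_fraction_max = 0.20) {
  stopifnot(inherits(ct, "cell_table"))
  if (!"mito" %in% names(ct$gene_meta)) {
    abort("gene_meta lacks a `mito` flag; cannot compute mitochondrial fractions")
  }
  tot <- rowSums(ct$counts)
  mt <- rowSums(ct$counts[, ct$gene_meta$mito, drop = FALSE])
  frac <- ifelse(tot > 0, mt / tot, 0)
  keep <- frac <= mito_fraction_max
  cell_table(ct$counts[keep, , drop = FALSE],
             cell_meta = ct$cell_meta[keep, , drop = FALSE],
             gene_meta = ct$gene_meta)
}

#' Median-scaled log normalization
#'
#' Each cell's counts are divided by the cell total, multiplied by the
#' median total across cells, and log-transformed with a pseudo-count:
#' `value = ln(count / total * median_total + pseudo)`.
#'
#' @param ct A [cell_table()].
#' @param pseudo Pseudo-count (default 0.1).
#' @return A [normalized_matrix()].
#' @export
normalize_expression <- function(ct, pseudo = 0.1) {
  stopifnot(inherits(ct, "cell_table"))
  tot <- rowSums(ct$counts)
  if (any(tot <= 0)) {
    abort(sprintf("cell(s) with zero total counts: %s",
                  paste(head(rownames(ct$counts)[tot <= 0], 5L),
                        collapse = ", ")))
  }
  med <- median(tot)
  vals <- log(ct$counts / tot * med + pseudo)
  normalized_matrix(vals, scale_factor = med, pseudo = pseudo)
}

#' Select highly variable genes
#'
#' Ranks genes by normalized dispersion: variance/mean of the linear
#' (back-transformed) normalized values, z-scored within 20 equal-occupancy
#' bins of gene mean.  Constant genes are never selected while variable
#' genes remain; ties are broken by gene name for determinism.
#'
#' @param nm A [normalized_matrix()].
#' @param n Number of genes to keep (default 1500; pooled cross-timepoint
#'   analyses conventionally use 2500).
#' @return Integer vector of selected gene column indices, ordered by
#'   decreasing normalized dispersion.
#' @export
select_hvg <- function(nm, n = 1500L) {
  stopifnot(inherits(nm, "normalized_matrix"))
  if (n > ncol(nm$values)) abort("n exceeds the number of genes")
  lin <- pmax(exp(nm$values) - nm$pseudo, 0)
  nd <- normalized_dispersion(lin, n_bins = 20L)
  score <- nd$z
  names(score) <- colnames(nm$values) %||% as.character(seq_along(score))
  ord <- order(-score, names(score), na.last = TRUE)
  head(ord, n)
}

#' PCA retaining a variance fraction
#'
#' Centred principal components; the smallest number of components whose
#' cumulative explained variance reaches `var_frac` is retained.
#'
#' @param nm A [normalized_matrix()] or a plain matrix.
#' @param var_frac Fraction of variance to retain, in `(0, 1]` (default
#'   0.85).
#' @return Cells x components coordinate matrix with attributes `sdev`
#'   (all singular values / sqrt(n-1)) and `var_explained`.
#' @export
pca_retain <- function(nm, var_frac = 0.85) {
  X <- if (inherits(nm, "normalized_matrix")) nm$values else as.matrix(nm)
  if (nrow(X) < 2L) abort("PCA needs at least 2 cells")
  if (!is.numeric(var_frac) || var_frac <= 0 || var_frac > 1) {
    abort("var_frac must lie in (0, 1]")
  }
  p <- prcomp(X, center = TRUE, scale. = FALSE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  ncomp <- which(cumsum(ve) >= var_frac - 1e-12)[1L]
  out <- p$x[, seq_len(ncomp), drop = FALSE]
  attr(out, "sdev") <- p$sdev
  attr(out, "var_explained") <- ve
  out
}
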