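# Light S3 containers.  Matrices stay matrices (cells x genes, metacells x
# peaks); metadata and all derived results are tibbles so downstream calls
# chain naturally.

#' Cells-by-genes count container
#'
#' @param counts Non-negative integer matrix, cells in rows, genes in
#'   columns, with dimnames.
#' @param cell_meta Tibble with one row per cell; must contain a `cell`
#'   column matching `rownames(counts)`.  Typically carries `timepoint`,
#'   `batch` and (for references) `lineage`/`stage`.
#' @param gene_meta Tibble with one row per gene (`gene` column matching
#'   `colnames(counts)`); an optional logical `mito` column flags
#'   mitochondrial genes.
#' @return A `cell_table`.
#' @export
cell_table <- function(counts,
                       cell_meta = tibble(cell = rownames(counts)),
                       gene_meta = tibble(gene = colnames(counts))) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("counts must have cell rownames and gene colnames")
  }
  if (anyDuplicated(colnames(counts))) abort("duplicate gene names")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    abort("counts must be finite and non-negative")
  }
  if (!identical(cell_meta$cell, rownames(counts))) {
    abort("cell_meta rows must align 1:1 with counts rows")
  }
  if (!identical(gene_meta$gene, colnames(counts))) {
    abort("gene_meta rows must align 1:1 with counts columns")
  }
  structure(list(counts = counts, cell_meta = cell_meta,
                 gene_meta = gene_meta),
            class = "cell_table")
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("<cell_table> %d cells x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' @export
dim.cell_table <- function(x) dim(x$counts)

#' Genomic interval set (BED semantics)
#'
#' Intervals are 0-based, half-open `[start, end)`.  Extra columns (e.g.
#' `gc`, `signal`) travel with the intervals.
#'
#' @param tab Tibble/data.frame with `chrom`, `start`, `end` and optional
#'   `name`, `gc`, `signal` columns.
#' @return A `peak_set` tibble.
#' @export
peak_set <- function(tab) {
  tab <- as_tibble(tab)
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(tab))) abort("peak_set needs chrom, start, end")
  if (any(tab$start >= tab$end)) {
    abort(sprintf("interval %d has start >= end",
                  which(tab$start >= tab$end)[1L]))
  }
  if (any(tab$start < 0)) abort("starts must be >= 0 (0-based half-open)")
  if ("gc" %in% names(tab) && (any(tab$gc < 0) || any(tab$gc > 1))) {
    abort("gc fraction must lie in [0, 1]")
  }
  if (!"name" %in% names(tab)) tab$name <- sprintf("peak%05d", seq_len(nrow(tab)))
  class(tab) <- c("peak_set", class(tab))
  tab
}

# GRanges bridge (0-based half-open -> 1-based closed).
as_granges <- function(ps) {
  GenomicRanges::GRanges(ps$chrom,
                         IRanges::IRanges(start = ps$start + 1L, end = ps$end))
}

from_granges <- function(gr, template = NULL) {
  tab <- tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                start = GenomicRanges::start(gr) - 1L,
                end = GenomicRanges::end(gr))
  peak_set(tab)
}

#' (Meta)cell-by-peak count container
#'
#' @param counts Non-negative matrix, (meta)cells in rows, peaks in columns.
#' @param peaks A [peak_set()] aligned to the columns.
#' @param level `"cell"` or `"metacell"`.
#' @param meta Tibble with one row per matrix row.
#' @param normalized Logical; whether `counts` holds normalized values.
#' @return A `peak_matrix`.
#' @export
peak_matrix <- function(counts, peaks, level = c("cell", "metacell"),
                        meta = NULL, normalized = FALSE) {
  level <- match.arg(level)
  counts <- as.matrix(counts)
  if (nrow(peaks) != ncol(counts)) {
    abort("peaks must align with count-matrix columns")
  }
  if (!normalized && any(counts < 0)) abort("counts must be non-negative")
  if (is.null(meta)) {
    meta <- tibble(id = rownames(counts) %||%
                     sprintf("%s%04d", substr(level, 1, 2), seq_len(nrow(counts))))
  }
  structure(list(counts = counts, peaks = peaks, level = level, meta = meta,
                 normalized = normalized),
            class = "peak_matrix")
}

#' @export
print.peak_matrix <- function(x, ...) {
  cat(sprintf("<peak_matrix> %d %ss x %d peaks%s\n", nrow(x$counts), x$level,
              ncol(x$counts), if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' Binary peak-by-motif hit matrix
#'
#' @param hits Logical (or 0/1) matrix, peaks in rows, motifs in columns,
#'   with dimnames.
#' @return A `motif_hits` object.
#' @export
motif_hits <- function(hits) {
  hits <- as.matrix(hits)
  if (!all(hits %in% c(0, 1, TRUE, FALSE))) abort("hits must be binary")
  storage.mode(hits) <- "logical"
  structure(list(hits = hits, motifs = colnames(hits)),
            class = "motif_hits")
}

#' Normalized expression container
#'
#' @param values Cells x genes matrix of log-normalized values.
#' @param scale_factor Median of per-cell totals used for scaling.
#' @param pseudo Pseudo-count added before the log.
#' @return A `normalized_matrix`.
#' @export
normalized_matrix <- function(values, scale_factor, pseudo) {
  structure(list(values = values, scale_factor = scale_factor,
                 pseudo = pseudo),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("<normalized_matrix> %d cells x %d genes (scale %.1f, pseudo %g)\n",
              nrow(x$values), ncol(x$values), x$scale_factor, x$pseudo))
  invisible(x)
}
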