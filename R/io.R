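# File formats: Matrix Market count matrices with TSV sidecars, BED
# interval sets, flat key-value configs.

#' Write / read a count matrix with metadata sidecars
#'
#' Counts go to Matrix Market (`matrix.mtx`), row metadata to `cells.tsv`
#' and column metadata to `features.tsv` inside `dir`.  Round-tripping is
#' the identity on counts and metadata.
#'
#' @param obj A [cell_table()] or [peak_matrix()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_matrix <- function(obj, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(obj, "cell_table")) {
    counts <- obj$counts
    rows <- obj$cell_meta
    cols <- obj$gene_meta
    kind <- "cell_table"
  } else if (inherits(obj, "peak_matrix")) {
    counts <- obj$counts
    rows <- obj$meta
    cols <- as_tibble(obj$peaks)
    kind <- paste0("peak_matrix/", obj$level)
  } else {
    abort("write_matrix handles cell_table and peak_matrix objects")
  }
  Matrix::writeMM(as(as(counts, "CsparseMatrix"), "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  readr::write_tsv(rows, file.path(dir, "cells.tsv"))
  readr::write_tsv(cols, file.path(dir, "features.tsv"))
  jsonlite::write_json(list(kind = kind, n_rows = nrow(counts),
                            n_cols = ncol(counts)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_matrix
#' @param dir Directory written by [write_matrix()].
#' @export
read_matrix <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  cells_f <- file.path(dir, "cells.tsv")
  feats_f <- file.path(dir, "features.tsv")
  for (f in c(mtx, cells_f, feats_f)) {
    if (!file.exists(f)) abort(sprintf("missing sidecar or matrix file: %s", f))
  }
  counts <- as.matrix(Matrix::readMM(mtx))
  rows <- readr::read_tsv(cells_f, show_col_types = FALSE)
  cols <- readr::read_tsv(feats_f, show_col_types = FALSE)
  if (nrow(rows) != nrow(counts) || nrow(cols) != ncol(counts)) {
    abort("sidecar shapes do not match the matrix")
  }
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  if (identical(man$kind, "cell_table")) {
    dimnames(counts) <- list(rows$cell, cols$gene)
    cell_table(counts, cell_meta = rows, gene_meta = cols)
  } else {
    level <- sub("^peak_matrix/", "", man$kind)
    dimnames(counts) <- list(rows[[1L]], cols$name)
    peak_matrix(counts, peak_set(cols), level = level, meta = rows)
  }
}

#' Write / read interval sets as BED
#'
#' BED6 with 0-based half-open coordinates; an optional 7th column carries
#' the GC fraction and an optional 8th a signal value.
#'
#' @param ps A [peak_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(ps, path) {
  tab <- tibble(chrom = ps$chrom, start = ps$start, end = ps$end,
                name = ps$name %||% sprintf("region%05d", seq_len(nrow(ps))),
                score = 0L, strand = ".")
  if ("gc" %in% names(ps)) tab$gc <- ps$gc
  if ("signal" %in% names(ps)) tab$signal <- ps$signal
  readr::write_tsv(tab, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @param path BED3/BED6(+gc+signal) file to read.
#' @export
read_bed <- function(path) {
  tab <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE)
  if (ncol(tab) < 3L) abort("BED needs at least chrom, start, end")
  names(tab)[1:3] <- c("chrom", "start", "end")
  if (ncol(tab) >= 4L) names(tab)[4L] <- "name"
  if (ncol(tab) >= 5L) names(tab)[5L] <- "score"
  if (ncol(tab) >= 6L) names(tab)[6L] <- "strand"
  if (ncol(tab) >= 7L) names(tab)[7L] <- "gc"
  if (ncol(tab) >= 8L) names(tab)[8L] <- "signal"
  bad <- which(tab$start >= tab$end)
  if (length(bad) > 0L) {
    abort(sprintf("malformed BED record at line %d: start >= end", bad[1L]))
  }
  keep <- intersect(c("chrom", "start", "end", "name", "gc", "signal"),
                    names(tab))
  peak_set(tab[keep])
}

#' Read / write a flat key-value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment.  Values are
#' parsed as numbers when possible, otherwise kept as strings.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readr::read_lines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) abort(sprintf("malformed config line: '%s'", ln))
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' @rdname read_config
#' @param cfg Named list of scalar values.
#' @export
write_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(k) {
    sprintf("%s = %s", k, format(cfg[[k]], scientific = FALSE))
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}
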