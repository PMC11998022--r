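# Motif-deviation scoring with matched backgrounds, region-set enrichment
# against an atlas, and signal-window integration.

#' Bias-corrected motif deviation scores
#'
#' For each motif and metacell: observed counts O = sum over the motif's
#' hit peaks; expected counts E = metacell total x the fraction of the
#' dataset's count mass falling in the hit peaks; raw deviation
#' `(O - E) / E`.  The raw deviation is z-scored against `n_background`
#' background peak sets matched on GC content and mean accessibility via a
#' fixed 10x10 quantile grid (sampling without replacement within a bin,
#' with replacement once a bin is exhausted).
#'
#' @param pm A metacell-level [peak_matrix()] of raw counts.
#' @param mh A [motif_hits()] matrix aligned to the peaks.
#' @param ps The aligned [peak_set()] with a `gc` column.
#' @param n_background Number of background draws (default 50).
#' @param seed Seed for background sampling.
#' @return A `deviation_scores`: `z` (metacells x motifs; NA for motifs
#'   with zero hit peaks, flagged in `skipped`), `raw`, `n_background`.
#' @export
motif_deviation_scores <- function(pm, mh, ps, n_background = 50L, seed = 0L) {
  stopifnot(inherits(pm, "peak_matrix"), inherits(mh, "motif_hits"))
  X <- pm$counts
  H <- mh$hits
  if (ncol(X) != nrow(H) || ncol(X) != nrow(ps)) {
    abort("peak matrix, motif hits and peak set must be aligned")
  }
  if (!"gc" %in% names(ps)) abort("peak set lacks a gc column")
  n_mc <- nrow(X); n_pk <- ncol(X); n_mot <- ncol(H)
  tot_cell <- rowSums(X)
  mass <- colSums(X)
  frac <- mass / sum(mass)
  mean_acc <- colMeans(X)

  # fixed 10x10 background grid on (GC, mean accessibility) quantiles
  gbin <- function(v) {
    br <- unique(quantile(v, probs = seq(0, 1, 0.1)))
    pmin(pmax(findInterval(v, br, rightmost.closed = TRUE), 1L),
         length(br) - 1L)
  }
  bin <- paste(gbin(ps$gc), gbin(mean_acc), sep = "_")
  bin_members <- split(seq_len(n_pk), bin)

  dev_for <- function(peaks) {
    O <- rowSums(X[, peaks, drop = FALSE])
    E <- tot_cell * sum(frac[peaks])
    (O - E) / E
  }

  z <- raw <- matrix(NA_real_, n_mc, n_mot,
                     dimnames = list(rownames(X), colnames(H)))
  skipped <- logical(n_mot)
  with_seed(seed, {
    for (m in seq_len(n_mot)) {
      hit <- which(H[, m])
      if (length(hit) == 0L) { skipped[m] <- TRUE; next }
      r <- dev_for(hit)
      raw[, m] <- r
      bg <- matrix(0, n_background, n_mc)
      hit_bins <- bin[hit]
      for (b in seq_len(n_background)) {
        draw <- integer(length(hit))
        for (bn in unique(hit_bins)) {
          need <- which(hit_bins == bn)
          pool <- bin_members[[bn]]
          if (length(pool) >= length(need)) {
            draw[need] <- pool[sample.int(length(pool), length(need))]
          } else {
            draw[need] <- pool[sample.int(length(pool), length(need),
                                          replace = TRUE)]
          }
        }
        bg[b, ] <- dev_for(draw)
      }
      mu <- colMeans(bg)
      sdv <- apply(bg, 2L, sd)
      sdv[sdv == 0] <- NA_real_
      z[, m] <- (r - mu) / sdv
    }
  })
  structure(list(z = z, raw = raw, n_background = as.integer(n_background),
                 skipped = skipped),
            class = "deviation_scores")
}

#' @export
print.deviation_scores <- function(x, ...) {
  cat(sprintf("<deviation_scores> %d metacells x %d motifs (%d skipped), %d backgrounds\n",
              nrow(x$z), ncol(x$z), sum(x$skipped), x$n_background))
  invisible(x)
}

#' Region-set enrichment against an atlas
#'
#' For each named region set, builds the 2x2 table of query/universe
#' intervals overlapping/not overlapping the set and computes a one-sided
#' Fisher exact p-value (enrichment; the hypergeometric upper tail) and
#' odds ratio.
#'
#' @param query A [peak_set()] of selected regions (a subset of the
#'   universe by overlap).
#' @param universe The atlas [peak_set()].
#' @param sets Named list of [peak_set()]s.
#' @param p_max Significance threshold (default 1e-3).
#' @return Tibble `set`, `n_overlap`, `odds_ratio`, `p`, `q`, `significant`.
#' @export
regionset_enrichment <- function(query, universe, sets, p_max = 1e-3) {
  if (nrow(universe) == 0L) abort("universe must be non-empty")
  uni_gr <- as_granges(universe)
  qry_in_uni <- overlap_intervals(universe, query)$overlaps
  n_uni <- nrow(universe)
  n_qry <- sum(qry_in_uni)
  rows <- lapply(names(sets), function(s) {
    in_set <- overlap_intervals(universe, sets[[s]])$overlaps
    a <- sum(qry_in_uni & in_set)        # query and set
    b <- sum(qry_in_uni & !in_set)       # query only
    c_ <- sum(!qry_in_uni & in_set)      # rest of universe in set
    d <- sum(!qry_in_uni & !in_set)
    orat <- if (b == 0 || c_ == 0) Inf else (a * d) / (b * c_)
    if (a == 0 && (b == 0 || c_ == 0)) orat <- NaN
    p <- phyper(a - 1L, a + c_, b + d, a + b, lower.tail = FALSE)
    tibble(set = s, n_overlap = a, odds_ratio = orat, p = p)
  })
  out <- dplyr::bind_rows(rows)
  out$q <- p.adjust(out$p, "BH")
  out$significant <- out$p < p_max
  dplyr::arrange(out, .data$p)
}

#' Sum feature signal within a window of each peak
#'
#' Adds up the `signal` of every feature whose interval lies within
#' `window` bp of the peak interval (inter-interval gap <= window).
#'
#' @param peaks A [peak_set()].
#' @param features A [peak_set()] with a `signal` column.
#' @param window Window in bp (default 1500).
#' @return Numeric vector of summed signal per peak.
#' @export
window_signal_sum <- function(peaks, features, window = 1500L) {
  if (!"signal" %in% names(features)) abort("features lack a signal column")
  if (any(features$signal < 0)) abort("signals must be non-negative")
  # window 0 degenerates to plain interval overlap (half-open semantics)
  mg <- if (window == 0L) -1L else as.integer(window)
  hits <- GenomicRanges::findOverlaps(as_granges(peaks), as_granges(features),
                                      maxgap = mg)
  out <- rep(0, nrow(peaks))
  if (length(hits) > 0L) {
    agg <- rowsum(features$signal[S4Vectors::subjectHits(hits)],
                  group = S4Vectors::queryHits(hits))
    out[as.integer(rownames(agg))] <- agg[, 1L]
  }
  out
}

#' Count targets within a window of each query interval
#'
#' @param query,targets [peak_set()]s.
#' @param window Window in bp; 0 reduces to plain interval overlap.
#' @return Tibble `any` (logical) and `count` per query interval.
#' @export
window_overlap_count <- function(query, targets, window) {
  mg <- if (window == 0L) -1L else as.integer(window)
  cnt <- GenomicRanges::countOverlaps(as_granges(query), as_granges(targets),
                                      maxgap = mg)
  tibble(any = cnt > 0L, count = as.integer(cnt))
}
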