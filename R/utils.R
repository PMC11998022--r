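# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.  All exported stochastic operations funnel their
# randomness through this single mechanism.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Cubic smoothstep on [0,1]; clamps outside.
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

# Pairwise Euclidean distances between rows of a and rows of b, computed in
# chunks so the peak allocation stays modest.  Returns |a| x |b| dense matrix.
cross_dist <- function(a, b, chunk = 512L) {
  a <- as.matrix(a); b <- as.matrix(b)
  bb <- rowSums(b^2)
  out <- matrix(0, nrow(a), ncol = nrow(b))
  idx <- split(seq_len(nrow(a)), ceiling(seq_len(nrow(a)) / chunk))
  for (ii in idx) {
    aa <- rowSums(a[ii, , drop = FALSE]^2)
    g <- a[ii, , drop = FALSE] %*% t(b)
    d2 <- outer(aa, bb, "+") - 2 * g
    d2[d2 < 0] <- 0
    out[ii, ] <- sqrt(d2)
  }
  out
}

# Dispersion (variance / mean) per column, z-scored within `n_bins`
# equal-occupancy bins of the column means.  Shared by the highly-variable
# gene and highly-variable peak selectors.  Columns with zero mean get NA.
normalized_dispersion <- function(mat, n_bins = 20L) {
  mu <- colMeans(mat)
  v <- apply(mat, 2L, var)
  disp <- ifelse(mu > 0 & v > 0, v / mu, NA_real_)
  ok <- which(is.finite(disp))
  z <- rep(NA_real_, length(disp))
  if (length(ok) == 0L) {
    return(list(mean = mu, dispersion = disp, z = z))
  }
  n_bins <- max(1L, min(n_bins, length(ok)))
  # equal-occupancy bins over the ranked means; robust centring/scaling
  # within each bin so a handful of genuinely dispersed features cannot
  # mask themselves by inflating the bin's scale
  r <- rank(mu[ok], ties.method = "first")
  bin <- ceiling(r / (length(ok) / n_bins))
  for (b in unique(bin)) {
    j <- ok[bin == b]
    m <- median(disp[j])
    s <- stats::mad(disp[j])
    if (!is.finite(s) || s == 0) s <- sd(disp[j])
    if (!is.finite(s) || s == 0) s <- 1
    z[j] <- (disp[j] - m) / s
  }
  list(mean = mu, dispersion = disp, z = z)
}

# Deterministic column scaling of a sparse or dense matrix by row totals.
row_stochastic <- function(A) {
  rs <- Matrix::rowSums(A)
  if (any(rs <= 0)) {
    abort(sprintf("isolated vertices (zero row sum) at indices: %s",
                  paste(head(which(rs <= 0), 10L), collapse = ", ")))
  }
  Matrix::Diagonal(x = 1 / rs) %*% A
}
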