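# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths.

# Adjusted Rand index between two labelings.
ari <- function(a, b) {
  t <- table(a, b)
  s <- function(x) sum(choose(x, 2))
  exp_idx <- s(rowSums(t)) * s(colSums(t)) / choose(length(a), 2)
  (s(t) - exp_idx) / ((s(rowSums(t)) + s(colSums(t))) / 2 - exp_idx)
}

# Brute-force single-source shortest paths (Dijkstra over a dense weighted
# adjacency matrix; Inf = no edge).
brute_dijkstra <- function(W, start) {
  n <- nrow(W)
  dist <- rep(Inf, n)
  dist[start] <- 0
  visited <- rep(FALSE, n)
  for (it in seq_len(n)) {
    u <- which(!visited & dist == min(dist[!visited]))[1L]
    if (!is.finite(dist[u])) break
    visited[u] <- TRUE
    for (v in which(is.finite(W[u, ]))) {
      if (dist[u] + W[u, v] < dist[v]) dist[v] <- dist[u] + W[u, v]
    }
  }
  dist
}

# Brute-force interval merge by sort-and-sweep on 0-based half-open
# intervals of one chromosome.
sweep_merge <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1L]; me <- end[1L]
  out_s <- c(); out_e <- c()
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

# Brute-force overlap test between two half-open interval sets on one
# chromosome: a overlaps b iff a.start < b.end && b.start < a.end.
brute_overlap_pairs <- function(sa, ea, sb, eb) {
  out <- matrix(0L, 0L, 2L)
  for (i in seq_along(sa)) {
    hit <- which(sa[i] < eb & sb < ea[i])
    if (length(hit) > 0L) out <- rbind(out, cbind(i, hit))
  }
  out
}

# Exact permutation null for the two-sample rank-sum statistic (small n).
perm_ranksum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  obs <- sum(rank(pooled)[seq_len(nx)])
  combs <- utils::combn(nx + ny, nx)
  r <- rank(pooled)
  stats <- apply(combs, 2L, function(idx) sum(r[idx]))
  mu <- nx * (nx + ny + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# One-sided hypergeometric upper-tail probability by explicit summation of
# binomial-coefficient terms (oracle for Fisher enrichment p-values).
hyper_tail_sum <- function(q, K, N, n) {
  jmax <- min(K, n)
  j <- q:jmax
  if (length(j) == 0L || q > jmax) return(0)
  terms <- exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n))
  sum(terms)
}

# Simulate absorption probabilities by explicit random walks (all walkers
# advanced in parallel; terminals are absorbing).
walk_absorption <- function(P, start, terminals, n_walks, max_steps = 5000L) {
  s <- rep(start, n_walks)
  for (step in seq_len(max_steps)) {
    active <- which(!(s %in% terminals))
    if (length(active) == 0L) break
    for (st in unique(s[active])) {
      idx <- active[s[active] == st]
      s[idx] <- sample.int(ncol(P), length(idx), replace = TRUE,
                           prob = P[st, ])
    }
  }
  vapply(terminals, function(t) mean(s == t), numeric(1))
}

# Small Gaussian-blob dataset with known labels.
make_blobs <- function(n_per, centers, sd = 0.5) {
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    sweep(matrix(stats::rnorm(n_per * ncol(centers), sd = sd), n_per),
          2L, centers[i, ], "+")
  }))
  list(X = X, labels = rep(seq_len(nrow(centers)), each = n_per))
}
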