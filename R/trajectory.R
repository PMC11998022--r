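# Trajectory inference: start-cell anchoring, shortest-path pseudotime,
# directed Markov chain, terminal-state detection, absorption (branch)
# probabilities and differentiation potential.

#' Anchor the start cell at a diffusion-component extremum
#'
#' Differentiation trajectories start at boundaries of the phenotypic
#' manifold.  Given a candidate start (e.g. a random cell from the first
#' timepoint), this returns the cell at the extremum of the multi-scale
#' component on which the candidate loads most strongly, choosing the
#' extremum nearer the candidate.
#'
#' @param ds A `diffusion_space`.
#' @param candidate Candidate cell index.
#' @return Adjusted start cell index.
#' @export
anchor_start_cell <- function(ds, candidate) {
  stopifnot(inherits(ds, "diffusion_space"))
  u <- ds$u
  if (candidate < 1L || candidate > nrow(u)) abort("invalid candidate index")
  j <- which.max(abs(u[candidate, ]))
  hi <- which.max(u[, j])
  lo <- which.min(u[, j])
  if (abs(u[candidate, j] - u[hi, j]) <= abs(u[candidate, j] - u[lo, j])) hi else lo
}

# igraph over the union of k-NN edges, weighted by distance.
nn_igraph <- function(g) {
  el <- cbind(rep(seq_len(g$n), g$k), as.vector(g$index))
  w <- as.vector(g$dist)
  # undirected union; igraph keeps multi-edges, collapse to min weight
  gr <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(gr)$weight <- w
  igraph::simplify(gr, edge.attr.comb = list(weight = "min"))
}

#' Shortest-path pseudotime
#'
#' Single-source shortest-path distances from a designated start cell over
#' the k-NN graph (edge weights = Euclidean distances), min-max normalized
#' to `[0, 1]`.  Optional waypoint refinement iteratively averages
#' waypoint-centred orderings weighted by proximity.
#'
#' @param g A [knn_graph()].
#' @param start Start cell index.
#' @param n_waypoints Number of refinement waypoints; 0 (default) disables
#'   refinement.
#' @param tol Convergence tolerance for the refinement (max change < tol).
#' @param seed Seed for waypoint sampling.
#' @return Numeric pseudotime vector in `[0, 1]`.
#' @export
compute_pseudotime <- function(g, start, n_waypoints = 0L, tol = 1e-3,
                               seed = 0L) {
  stopifnot(inherits(g, "neighbor_graph"))
  gr <- nn_igraph(g)
  d0 <- as.numeric(igraph::distances(gr, v = start)[1L, ])
  unreachable <- !is.finite(d0)
  if (any(unreachable)) {
    abort(sprintf("%d cells unreachable from the start cell",
                  sum(unreachable)))
  }
  pt <- d0
  if (n_waypoints > 0L) {
    wps <- with_seed(seed, maxmin_sample(gr, start, n_waypoints))
    D <- igraph::distances(gr, v = wps)
    # proximity weights per waypoint, softmax over waypoint distances
    sds <- pmax(apply(D, 1L, sd), 1e-12)
    W <- exp(-(D / sds)^2)
    W <- rbind(W, exp(-(d0 / max(sd(d0), 1e-12))^2))
    W <- sweep(W, 2L, colSums(W), "/")
    repeat {
      # orient each waypoint's distances by the current ordering
      P <- matrix(0, length(wps) + 1L, g$n)
      for (w in seq_along(wps)) {
        base <- pt[wps[w]]
        P[w, ] <- ifelse(pt < base, base - D[w, ], base + D[w, ])
      }
      P[length(wps) + 1L, ] <- d0
      new_pt <- colSums(P * W)
      new_pt <- new_pt - min(new_pt)
      if (max(new_pt) > 0) new_pt <- new_pt / max(new_pt) * max(pt)
      if (max(abs(new_pt - pt)) < tol) { pt <- new_pt; break }
      pt <- new_pt
    }
  }
  pt <- pt - min(pt)
  if (max(pt) > 0) pt <- pt / max(pt)
  pt
}

# Greedy max-min landmark sampling over graph distances.
maxmin_sample <- function(gr, start, n) {
  picked <- start
  d <- as.numeric(igraph::distances(gr, v = start)[1L, ])
  for (i in seq_len(n - 1L)) {
    nxt <- which.max(d)
    picked <- c(picked, nxt)
    d2 <- as.numeric(igraph::distances(gr, v = nxt)[1L, ])
    d <- pmin(d, d2)
  }
  setdiff(picked, start)
}

#' Direct an affinity graph along pseudotime
#'
#' Turns the symmetric affinity graph into a directed Markov chain: the
#' transition i -> j is retained iff `pt_j >= pt_i - w_i`, where `w_i` is
#' the standard deviation of pseudotime among i's neighbours (a per-cell
#' adaptive window), then rows are renormalized.  Rows left with no edges
#' become self-absorbing.
#'
#' @param A An [affinity_graph()].
#' @param pt Pseudotime vector.
#' @param window Optional fixed window overriding the adaptive one; `Inf`
#'   reproduces the undirected normalization.
#' @return Sparse row-stochastic directed chain.
#' @export
directed_markov_chain <- function(A, pt, window = NULL) {
  M <- if (inherits(A, "affinity_graph")) A$A else A
  # symmetric sparse classes store one triangle only; expand before use
  M <- as(as(M, "CsparseMatrix"), "generalMatrix")
  n <- nrow(M)
  if (length(pt) != n) abort("pseudotime must cover all cells")
  tr <- Matrix::mat2triplet(M)
  if (is.null(window)) {
    nb <- split(pt[tr$j], factor(tr$i, levels = seq_len(n)))
    w <- vapply(nb, function(p) if (length(p) < 2L) 0 else sd(p), numeric(1))
  } else {
    w <- rep(window, n)
  }
  keep <- pt[tr$j] >= pt[tr$i] - w[tr$i]
  P <- Matrix::sparseMatrix(i = tr$i[keep], j = tr$j[keep], x = tr$x[keep],
                            dims = c(n, n))
  rs <- Matrix::rowSums(P)
  dead <- which(rs == 0)
  if (length(dead) > 0L) {
    P <- P + Matrix::sparseMatrix(i = dead, j = dead, x = rep(1, length(dead)),
                                  dims = c(n, n))
    rs[dead] <- 1
  }
  as(Matrix::Diagonal(x = 1 / rs) %*% P, "CsparseMatrix")
}

#' Detect terminal states of a directed chain
#'
#' Candidates are the extremum cells of each multi-scale diffusion
#' component; a candidate is retained iff its outgoing transition mass
#' toward higher-pseudotime cells is below `eps` (boundary-absorbing).
#' Candidates within each other's neighbourhoods are merged, keeping the
#' highest-pseudotime representative.  A user-supplied list short-circuits
#' detection (used when end points are known).
#'
#' @param chain Directed chain from [directed_markov_chain()].
#' @param ds A `diffusion_space`.
#' @param pt Pseudotime vector.
#' @param user_terminals Optional explicit terminal cell indices, returned
#'   verbatim.
#' @param eps Outgoing-mass threshold (default 1e-3).
#' @param dedup_margin Pseudotime margin used when merging candidates on
#'   the same branch end (default 0.05).
#' @return Integer vector of terminal cell indices.
#' @export
detect_terminal_states <- function(chain, ds, pt, user_terminals = NULL,
                                   eps = 1e-3, dedup_margin = 0.05) {
  if (!is.null(user_terminals)) return(as.integer(user_terminals))
  u <- ds$u
  cand <- unique(c(apply(u, 2L, which.max), apply(u, 2L, which.min)))
  tr <- Matrix::mat2triplet(chain)
  out_nb <- split(tr$j, factor(tr$i, levels = seq_len(nrow(chain))))
  # refine each extremum candidate to its local pseudotime maximum along the
  # chain (the boundary cell of its branch); only that cell can be
  # boundary-absorbing
  climb <- function(i) {
    for (step in seq_len(nrow(chain))) {
      nb <- out_nb[[i]]
      if (length(nb) == 0L) return(i)
      best <- nb[which.max(pt[nb])]
      if (pt[best] <= pt[i]) return(i)
      i <- best
    }
    i
  }
  cand <- unique(vapply(cand, climb, integer(1)))
  # boundary absorption: the candidate itself sends no mass forward, and
  # its neighbourhood does not leak walkers to higher-pseudotime cells
  # outside itself.  A true branch end satisfies both; a mid-branch pocket
  # fails the second (the trajectory continues past it).
  keep <- vapply(cand, function(i) {
    fwd <- tr$i == i & pt[tr$j] > pt[i]
    if (sum(tr$x[fwd]) >= eps) return(FALSE)
    nb <- unique(c(i, out_nb[[i]]))
    leak <- tr$i %in% nb & !(tr$j %in% nb) & pt[tr$j] > pt[i]
    sum(tr$x[leak]) / length(nb) < 0.05
  }, logical(1))
  cand <- cand[keep]
  if (length(cand) == 0L) {
    abort("no terminal states detected; supply user_terminals")
  }
  # deduplicate: two candidates lie on the same branch end iff they are
  # connected through high-pseudotime cells alone; distinct branches only
  # connect through the (much earlier) branch point.  Keep the
  # highest-pseudotime representative per group.
  if (length(cand) > 1L) {
    n <- nrow(chain)
    adj <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = 1, dims = c(n, n))
    adj <- (adj + Matrix::t(adj)) > 0
    same_branch <- function(a, b) {
      tau <- min(pt[a], pt[b]) - dedup_margin
      region <- which(pt >= tau)
      gr <- igraph::graph_from_adjacency_matrix(
        adj[region, region, drop = FALSE], mode = "undirected")
      comp <- igraph::components(gr)$membership
      comp[match(a, region)] == comp[match(b, region)]
    }
    parent <- seq_along(cand)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (a in seq_along(cand)) {
      for (b in seq_along(cand)) {
        if (a < b && same_branch(cand[a], cand[b])) {
          parent[find(b)] <- find(a)
        }
      }
    }
    groups <- vapply(seq_along(cand), find, integer(1))
    cand <- vapply(split(cand, groups), function(grp) grp[which.max(pt[grp])],
                   integer(1))
  }
  sort(unname(cand))
}

#' Absorption (branch) probabilities
#'
#' Makes the terminal cells absorbing and computes, for every cell, the
#' probability that the chain's random walk is absorbed at each terminal
#' via the fundamental matrix: `B = (I - Q)^{-1} R` on the transient
#' states.
#'
#' @param chain Directed row-stochastic chain.
#' @param terminals Terminal cell indices.
#' @return Cells x terminals matrix; rows sum to 1.  Terminal rows are
#'   indicators of their own state.
#' @export
branch_probabilities <- function(chain, terminals) {
  terminals <- as.integer(terminals)
  if (length(terminals) == 0L) abort("terminals must be non-empty")
  n <- nrow(chain)
  trans <- setdiff(seq_len(n), terminals)
  B <- matrix(0, n, length(terminals))
  B[cbind(terminals, seq_along(terminals))] <- 1
  if (length(trans) > 0L) {
    Q <- chain[trans, trans, drop = FALSE]
    R <- chain[trans, terminals, drop = FALSE]
    IQ <- Matrix::Diagonal(length(trans)) - Q
    sol <- tryCatch({
      if (length(trans) < 500L) {
        solve(as.matrix(IQ), as.matrix(R))
      } else {
        as.matrix(Matrix::solve(IQ, R, sparse = TRUE))
      }
    }, error = function(e) {
      abort(paste0("(I - Q) is singular: the chain has a recurrent ",
                   "non-terminal class (", conditionMessage(e), ")"))
    })
    rs <- rowSums(sol)
    if (any(!is.finite(rs)) || max(abs(rs - 1)) > 1e-6) {
      abort("absorption probabilities do not sum to 1; chain has leaks")
    }
    sol <- sol / rs
    B[trans, ] <- sol
  }
  colnames(B) <- paste0("terminal_", terminals)
  B
}

#' Differentiation potential (fate entropy)
#'
#' Shannon entropy (natural log) of each cell's branch-probability row;
#' `0 * log 0` is taken as 0.  Committed cells score 0, maximally
#' uncommitted cells `ln K`.
#'
#' @param branch_probs Cells x terminals probability matrix.
#' @return Numeric entropy vector.
#' @export
differentiation_potential <- function(branch_probs) {
  P <- as.matrix(branch_probs)
  if (any(P < -1e-12)) abort("branch probabilities must be non-negative")
  P[P < 0] <- 0
  H <- -rowSums(ifelse(P > 0, P * log(P), 0))
  pmax(H, 0)
}

#' Fit a full trajectory model
#'
#' Convenience wrapper chaining start-cell anchoring, shortest-path
#' pseudotime, chain direction, terminal-state detection and branch
#' probabilities into a single fitted object.
#'
#' @param X Coordinate matrix (e.g. retained principal components).
#' @param start_candidate Candidate start cell index.
#' @param k,l Graph/kernel parameters.
#' @param n_eigs Eigenpairs for the diffusion map.
#' @param user_terminals Optional known terminal cells.
#' @param eps Terminal-detection threshold.
#' @return A `trajectory_fit` with pseudotime, terminal states, branch
#'   probabilities, differentiation potential and the underlying graph and
#'   diffusion space.
#' @export
fit_trajectory <- function(X, start_candidate = 1L, k = 50L, l = round(k / 3),
                           n_eigs = 20L, user_terminals = NULL, eps = 1e-3) {
  k <- min(k, nrow(X) - 1L)
  g <- knn_graph(X, k)
  A <- adaptive_affinity(g, l = min(max(1L, round(k / 3)), k))
  T_ <- markov_operator(A)
  ds <- diffusion_maps(T_, n_eigs = n_eigs)
  start <- anchor_start_cell(ds, start_candidate)
  # pseudotime and the directed chain operate in the multi-scale diffusion
  # space, where noise directions are contracted and branches separate;
  # if the neighbourhood graph fragments there, widen k until it connects
  k2 <- k
  repeat {
    g2 <- knn_graph(ds$u, k2)
    if (igraph::is_connected(nn_igraph(g2)) || k2 >= nrow(ds$u) - 1L) break
    k2 <- min(2L * k2, nrow(ds$u) - 1L)
  }
  A2 <- adaptive_affinity(g2, l = min(max(1L, round(k2 / 3)), k2))
  pt <- compute_pseudotime(g2, start)
  chain <- directed_markov_chain(A2, pt)
  terms <- detect_terminal_states(chain, ds, pt, user_terminals, eps)
  # self-absorbing cells outside the detected set are absorbing states of
  # the chain (isolated dead ends); include them so absorption is well posed
  dead <- setdiff(which(Matrix::diag(chain) > 1 - 1e-9), terms)
  B <- branch_probabilities(chain, c(terms, dead))
  structure(list(pseudotime = pt, start = start, terminal_states = terms,
                 dead_ends = dead,
                 branch_probs = B,
                 diff_potential = differentiation_potential(B),
                 graph = g, affinity = A, diffusion = ds, chain = chain),
            class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("<trajectory_fit> %d cells, start %d, %d terminal state(s)\n",
              length(x$pseudotime), x$start, length(x$terminal_states)))
  invisible(x)
}

#' Tidy a trajectory fit into a per-cell tibble
#'
#' @param x A `trajectory_fit`.
#' @param ... Unused.
#' @return Tibble with `cell`, `pseudotime`, `diff_potential` and one
#'   branch-probability column per terminal state.
#' @export
tidy.trajectory_fit <- function(x, ...) {
  out <- tibble(cell = seq_along(x$pseudotime),
                pseudotime = x$pseudotime,
                diff_potential = x$diff_potential)
  dplyr::bind_cols(out, as_tibble(as.data.frame(x$branch_probs)))
}

#' One-row summary of a trajectory fit
#'
#' @param x A `trajectory_fit`.
#' @param ... Unused.
#' @return Tibble with cell count, terminal count, selected components and
#'   mean differentiation potential.
#' @export
glance.trajectory_fit <- function(x, ...) {
  tibble(n_cells = length(x$pseudotime),
         n_terminal = length(x$terminal_states),
         n_components = x$diffusion$n_selected,
         mean_diff_potential = mean(x$diff_potential))
}

#' Plot a trajectory fit
#'
#' Scatter of the first two multi-scale diffusion components coloured by
#' pseudotime, with terminal states marked.
#'
#' @param object A `trajectory_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trajectory_fit <- function(object, ...) {
  u <- object$diffusion$u
  df <- tibble(dc1 = u[, 1L],
               dc2 = if (ncol(u) > 1L) u[, 2L] else 0,
               pseudotime = object$pseudotime)
  terms <- df[object$terminal_states, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$dc1, .data$dc2,
                                   colour = .data$pseudotime)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_point(data = terms, colour = "red", shape = 8, size = 3) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = "multi-scale DC1", y = "multi-scale DC2",
                  colour = "pseudotime") +
    ggplot2::theme_minimal()
}
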