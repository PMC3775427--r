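#' Binary undirected graph at a fixed sparsity
#'
#' Internal representation used by all graph metrics: a 0/1 adjacency matrix
#' with node labels, no self-loops and no duplicate edges. Graphs are usually
#' produced by [threshold_sparsity()] rather than constructed directly.
#'
#' @param adj Square 0/1 (or logical) adjacency matrix, symmetric, zero
#'   diagonal.
#' @param labels Node labels; default taken from dimnames.
#' @return An object of class `binary_graph` with elements `adj` (integer
#'   matrix), `labels`, `n_nodes`, `n_edges` and `sparsity` (the achieved
#'   fraction of possible edges, exactly `n_edges / (n * (n - 1) / 2)`).
#' @export
binary_graph <- function(adj, labels = NULL) {
  adj <- as.matrix(adj)
  storage.mode(adj) <- "integer"
  n <- nrow(adj)
  if (ncol(adj) != n) abort("Adjacency matrix must be square.")
  if (!all(adj %in% c(0L, 1L))) abort("Adjacency matrix must be 0/1.")
  if (any(diag(adj) != 0L)) abort("Self-loops are not allowed.")
  if (!identical(adj, t(adj))) abort("Adjacency matrix must be symmetric.")
  labels <- labels %||% rownames(adj) %||% paste0("roi_", seq_len(n))
  dimnames(adj) <- list(labels, labels)
  m <- sum(adj) / 2L
  structure(
    list(
      adj = adj, labels = labels, n_nodes = n, n_edges = as.integer(m),
      sparsity = m / (n * (n - 1) / 2)
    ),
    class = "binary_graph"
  )
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf(
    "<binary_graph> %d nodes, %d edges (sparsity %.4f)\n",
    x$n_nodes, x$n_edges, x$sparsity
  ))
  invisible(x)
}

#' @export
format.binary_graph <- function(x, ...) {
  sprintf("<binary_graph: %d nodes, %d edges>", x$n_nodes, x$n_edges)
}

# Upper-triangle pair table in lexicographic (i, j) order; the canonical
# edge ordering used for deterministic tie-breaking.
pair_table <- function(n) {
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2L:n)
  cbind(i = i, j = j)
}

# Edge ids are row indices into pair_table(n).
edge_ids <- function(g) {
  pt <- pair_table(g$n_nodes)
  which(g$adj[pt] == 1L)
}

graph_from_edge_ids <- function(ids, n, labels = NULL) {
  pt <- pair_table(n)
  adj <- matrix(0L, n, n)
  if (length(ids)) {
    adj[pt[ids, , drop = FALSE]] <- 1L
    adj[pt[ids, c(2, 1), drop = FALSE]] <- 1L
  }
  binary_graph(adj, labels = labels)
}

#' List the edges of a binary graph
#'
#' @param g A [binary_graph()].
#' @return A tibble with columns `i`, `j` (node indices, `i < j`), `label_i`,
#'   `label_j`.
#' @export
graph_edges <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  pt <- pair_table(g$n_nodes)
  keep <- g$adj[pt] == 1L
  tibble::tibble(
    i = pt[keep, "i"], j = pt[keep, "j"],
    label_i = g$labels[pt[keep, "i"]], label_j = g$labels[pt[keep, "j"]]
  )
}

#' Binarize a weighted connectivity matrix at a target sparsity
#'
#' Retains exactly `round(s * n(n-1)/2)` strongest edges (rounding half away
#' from zero), so that two matrices thresholded at the same sparsity always
#' carry the same number of edges — the matched-sparsity contract that makes
#' binary metrics of the two networks comparable. Weight ties at the
#' threshold boundary are broken by lexicographic (i, j) pair order, making
#' the edge set deterministic and seed-free. The diagonal is ignored.
#'
#' @param w Symmetric labeled connectivity matrix.
#' @param s Target sparsity, the fraction of all `n(n-1)/2` node pairs to
#'   keep as edges; strictly between 0 and 1.
#' @return A [binary_graph()] carrying the labels of `w`.
#' @export
#' @examples
#' w <- connectivity_matrix(matrix(c(1, .9, .1, .9, 1, .5, .1, .5, 1), 3))
#' threshold_sparsity(w, 2 / 3)$n_edges
threshold_sparsity <- function(w, s) {
  w <- connectivity_matrix(w)
  n <- nrow(w)
  if (!is.numeric(s) || length(s) != 1L || s <= 0 || s >= 1) {
    abort("`s` must be a single sparsity in (0, 1).")
  }
  n_pairs <- n * (n - 1) / 2
  m <- floor(s * n_pairs + 0.5) # round half away from zero (weights of pairs)
  if (m < 1) abort("Sparsity too low: no edges would be retained.")
  if (m >= n_pairs) abort("Sparsity too high: all pairs would be edges.")
  pt <- pair_table(n)
  wts <- w[pt]
  keep <- order(-wts, pt[, "i"], pt[, "j"])[seq_len(m)]
  graph_from_edge_ids(sort(keep), n, labels = rownames(w))
}

#' Node degrees of a binary graph
#'
#' @param g A [binary_graph()].
#' @return Named integer vector: the number of edges incident to each node.
#' @export
node_degree <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  setNames(as.integer(rowSums(g$adj)), g$labels)
}

#' Global efficiency of a binary graph
#'
#' Mean of inverse shortest-path lengths over all ordered node pairs, with
#' disconnected pairs contributing 0. Equals 1 for the complete graph and 0
#' for the edgeless graph; summarizes how efficiently the network integrates
#' information globally. Path lengths come from breadth-first search.
#'
#' @param g A [binary_graph()].
#' @return A number in `[0, 1]`.
#' @export
global_efficiency <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  n <- g$n_nodes
  if (n < 2) abort("Global efficiency needs at least 2 nodes.")
  d <- bfs_distance_matrix(g$adj)
  inv <- 1 / d
  inv[is.na(d)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Clustering coefficients of a binary graph
#'
#' Per node, the fraction of pairs of neighbors that are themselves
#' connected: `C_i = 2 t_i / (k_i (k_i - 1))` with `t_i` the number of
#' triangles through node i; nodes of degree < 2 get 0. [mean_clustering()]
#' averages over all nodes.
#'
#' @param g A [binary_graph()].
#' @return Named numeric vector of per-node coefficients.
#' @export
clustering_coef <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  a <- g$adj
  k <- rowSums(a)
  # triangles through i: (A^3)_ii / 2 = sum_j A_ij (A^2)_ij / 2
  a2 <- a %*% a
  tri <- rowSums(a * a2) / 2
  ci <- ifelse(k >= 2, 2 * tri / (k * (k - 1)), 0)
  setNames(as.numeric(ci), g$labels)
}

#' @rdname clustering_coef
#' @export
mean_clustering <- function(g) mean(clustering_coef(g))

#' Newman's modularity Q of a partition
#'
#' `Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) * delta(c_i, c_j)` over ordered
#' pairs, where `m` is the edge count. Q is 0 for the single-module
#' partition and at most 1; disconnected graphs are scored on the full
#' graph, per the formula.
#'
#' @param g A [binary_graph()] with at least one edge.
#' @param membership Integer module id per node (any labeling), or a
#'   `partition` object from [louvain()].
#' @return Modularity of the partition.
#' @export
modularity_q <- function(g, membership) {
  stopifnot(inherits(g, "binary_graph"))
  if (inherits(membership, "partition")) membership <- membership$membership
  if (length(membership) != g$n_nodes) {
    abort("`membership` must assign a module to every node.")
  }
  m <- g$n_edges
  if (m < 1) abort("Modularity is undefined for an empty graph.")
  k <- rowSums(g$adj)
  q <- 0
  for (c in unique(membership)) {
    idx <- which(membership == c)
    l_c <- sum(g$adj[idx, idx, drop = FALSE]) / 2
    d_c <- sum(k[idx])
    q <- q + l_c / m - (d_c / (2 * m))^2
  }
  q
}

# One full Louvain run: local moves + aggregation until no improvement.
# W convention: symmetric weight matrix whose diagonal holds twice the
# self-loop weight, so k = rowSums(W) and 2m = sum(W) throughout.
louvain_one_run <- function(adj, node_order) {
  n0 <- nrow(adj)
  membership <- seq_len(n0) # original node -> current community
  w <- adj * 1.0
  ord <- node_order
  repeat {
    n <- nrow(w)
    m2 <- sum(w)
    k <- rowSums(w)
    comm <- seq_len(n)
    ktot <- k # community degree totals
    improved <- TRUE
    any_move <- FALSE
    while (improved) {
      improved <- FALSE
      for (i in ord) {
        ci <- comm[i]
        wi <- w[i, ]
        wi[i] <- 0
        nz <- which(wi > 0)
        if (!length(nz)) next
        wic <- rowsum(wi[nz], comm[nz], reorder = FALSE)
        cand <- as.integer(rownames(wic))
        wic <- wic[, 1L]
        ktot[ci] <- ktot[ci] - k[i] # take i out of its community
        w_stay <- if (ci %in% cand) wic[match(ci, cand)] else 0
        gain_stay <- 2 * w_stay / m2 - 2 * k[i] * ktot[ci] / m2^2
        gain <- 2 * wic / m2 - 2 * k[i] * ktot[cand] / m2^2
        best <- which.max(gain) # first max; cand order is deterministic
        if (gain[best] > gain_stay + 1e-12) {
          comm[i] <- cand[best]
          improved <- TRUE
          any_move <- TRUE
        }
        ktot[comm[i]] <- ktot[comm[i]] + k[i]
      }
    }
    comm <- match(comm, unique(comm)) # contiguous ids
    membership <- comm[membership]
    if (!any_move || max(comm) == n) break
    # aggregate communities into supernodes
    w <- rowsum(t(rowsum(w, comm, reorder = TRUE)), comm, reorder = TRUE)
    ord <- seq_len(nrow(w))
  }
  membership
}

#' Louvain community detection
#'
#' Greedy multi-level modularity optimization: repeated local node moves
#' followed by graph aggregation, iterated until no move improves Q. The Q
#' landscape is degenerate, so the optimizer is restarted with shuffled
#' node-visit orders and the best partition kept; the returned `q` is
#' recomputed on the original graph with [modularity_q()], so it is exact
#' for the returned assignment.
#'
#' @param g A [binary_graph()] with at least one edge.
#' @param seed Integer seed for the restart shuffles (default 1; the result
#'   is a pure function of `g`, `seed`, `restarts`).
#' @param restarts Number of randomized restarts.
#' @return An object of class `partition`: list with `membership` (named
#'   integer vector, module ids contiguous from 1), `q`, `n_modules`.
#' @export
louvain <- function(g, seed = 1L, restarts = 10L) {
  stopifnot(inherits(g, "binary_graph"))
  if (g$n_edges < 1) abort("Community detection needs at least one edge.")
  best <- NULL
  best_q <- -Inf
  for (r in seq_len(restarts)) {
    ord <- with_seed_maybe(child_seed(seed, r), sample.int(g$n_nodes))
    mem <- louvain_one_run(g$adj, ord)
    q <- modularity_q(g, mem)
    if (q > best_q + 1e-15) {
      best_q <- q
      best <- mem
    }
  }
  structure(
    list(
      membership = setNames(match(best, unique(best)), g$labels),
      q = best_q, n_modules = length(unique(best))
    ),
    class = "partition"
  )
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d modules, Q = %.4f\n", x$n_modules, x$q))
  invisible(x)
}

#' Random-network reference values for the three binary metrics
#'
#' Draws `reps` random graphs with the same node and edge count as the
#' network under study and averages global efficiency, mean clustering and
#' Louvain modularity over the draws. The default model is uniform G(n, m);
#' degree-preserving Maslov-Sneppen rewiring of a base graph is available
#' because "random network" is ambiguous between the two conventions.
#'
#' @param n,m Node and edge counts (ignored for `model = "rewire"` except
#'   for validation against `base_graph`).
#' @param reps Number of random graphs.
#' @param seed Integer root seed.
#' @param model `"gnm"` (uniform given n, m) or `"rewire"`
#'   (degree-preserving edge swaps of `base_graph`, 10 swaps per edge).
#' @param base_graph A [binary_graph()], required for `model = "rewire"`.
#' @param louvain_restarts Restarts per rep for the modularity value.
#' @return A tibble with one row: mean `efficiency`, `clustering`,
#'   `modularity` over the `reps` draws.
#' @export
random_reference <- function(n, m, reps = 1000L, seed = 1L,
                             model = c("gnm", "rewire"), base_graph = NULL,
                             louvain_restarts = 1L) {
  model <- match.arg(model)
  if (model == "rewire") {
    if (is.null(base_graph)) abort("`base_graph` is required for model = \"rewire\".")
    n <- base_graph$n_nodes
    m <- base_graph$n_edges
  }
  n_pairs <- n * (n - 1) / 2
  if (m < 1 || m > n_pairs) abort("Edge count `m` is infeasible for `n` nodes.")
  vals <- matrix(NA_real_, reps, 3)
  for (r in seq_len(reps)) {
    s_r <- child_seed(seed, r)
    g <- if (model == "gnm") {
      ids <- with_seed_maybe(s_r, sort(sample.int(n_pairs, m)))
      graph_from_edge_ids(ids, n)
    } else {
      rewire_graph(base_graph, seed = s_r)
    }
    vals[r, 1] <- global_efficiency(g)
    vals[r, 2] <- mean_clustering(g)
    vals[r, 3] <- louvain(g, seed = child_seed(s_r, 1L),
                          restarts = louvain_restarts)$q
  }
  tibble::tibble(
    efficiency = mean(vals[, 1]),
    clustering = mean(vals[, 2]),
    modularity = mean(vals[, 3]),
    reps = as.integer(reps), model = model
  )
}

# Degree-preserving rewiring (Maslov-Sneppen): random double edge swaps,
# rejected when they would create a self-loop or duplicate edge.
rewire_graph <- function(g, seed = NULL, swaps_per_edge = 10L) {
  stopifnot(inherits(g, "binary_graph"))
  ed <- as.matrix(graph_edges(g)[, c("i", "j")])
  m <- nrow(ed)
  if (m < 2) return(g)
  adj <- g$adj
  with_seed_maybe(seed, {
    n_attempts <- swaps_per_edge * m
    picks <- matrix(sample.int(m, 2L * n_attempts, replace = TRUE), ncol = 2)
    flips <- runif(n_attempts) < 0.5
    for (t in seq_len(n_attempts)) {
      e1 <- picks[t, 1]
      e2 <- picks[t, 2]
      if (e1 == e2) next
      a <- ed[e1, 1]; b <- ed[e1, 2]
      c <- ed[e2, 1]; d <- ed[e2, 2]
      if (flips[t]) { tmp <- c; c <- d; d <- tmp } # choose swap orientation
      # propose (a,d) and (c,b)
      if (a == d || c == b) next
      if (adj[a, d] == 1L || adj[c, b] == 1L) next
      adj[a, b] <- adj[b, a] <- 0L
      adj[c, d] <- adj[d, c] <- 0L
      adj[a, d] <- adj[d, a] <- 1L
      adj[c, b] <- adj[b, c] <- 1L
      ed[e1, ] <- c(min(a, d), max(a, d))
      ed[e2, ] <- c(min(c, b), max(c, b))
    }
  })
  binary_graph(adj, labels = g$labels)
}

metric_registry <- function(louvain_restarts = 10L, seed = 1L) {
  list(
    efficiency = function(g, metric_seed = seed) global_efficiency(g),
    clustering = function(g, metric_seed = seed) mean_clustering(g),
    modularity = function(g, metric_seed = seed) {
      louvain(g, seed = metric_seed, restarts = louvain_restarts)$q
    }
  )
}

check_metrics <- function(metrics) {
  known <- c("efficiency", "clustering", "modularity")
  bad <- setdiff(metrics, known)
  if (length(bad)) {
    abort(paste0("Unknown metric(s): ", paste(bad, collapse = ", "),
                 ". Available: ", paste(known, collapse = ", "), "."))
  }
  metrics
}

#' Sweep binary graph metrics across a sparsity grid
#'
#' Thresholds each network at every sparsity in `grid` and evaluates the
#' requested metrics, optionally appending random-reference values (G(n, m)
#' averages at the matching edge count). This reproduces the
#' metric-versus-sparsity curves used to compare the task coactivation and
#' resting-state networks.
#'
#' @param w A connectivity matrix, or a named list of them (the names become
#'   the `network` column).
#' @param metrics Character subset of `c("efficiency", "clustering",
#'   "modularity")`.
#' @param grid Increasing sparsity grid; default 0.06 to 0.40 in steps of
#'   0.01 (35 points), the range in which large-scale brain networks behave
#'   as small-world networks.
#' @param random_reps If > 0, also compute the random-network reference with
#'   this many draws per sparsity (rows with `network = "random"`).
#' @param seed Root seed for modularity restarts and random references.
#' @param louvain_restarts Restarts for the modularity metric.
#' @return A tibble of class `sparsity_curve` with columns `network`,
#'   `sparsity`, `metric`, `value`.
#' @export
sparsity_sweep <- function(w, metrics = c("efficiency", "clustering", "modularity"),
                           grid = seq(0.06, 0.40, by = 0.01),
                           random_reps = 0L, seed = 1L, louvain_restarts = 10L) {
  metrics <- check_metrics(metrics)
  if (is.matrix(w)) w <- list(network = w)
  if (is.null(names(w)) || anyDuplicated(names(w))) {
    abort("`w` must be a matrix or a uniquely named list of matrices.")
  }
  if (any(diff(grid) <= 0) || any(grid <= 0) || any(grid >= 1)) {
    abort("`grid` must be strictly increasing within (0, 1).")
  }
  reg <- metric_registry(louvain_restarts = louvain_restarts)
  rows <- purrr::imap(w, function(mat, nm) {
    purrr::map(seq_along(grid), function(gi) {
      g <- threshold_sparsity(mat, grid[gi])
      tibble::tibble(
        network = nm, sparsity = grid[gi], metric = metrics,
        value = purrr::map_dbl(
          metrics, ~ reg[[.x]](g, metric_seed = child_seed(seed, gi))
        )
      )
    })
  })
  out <- dplyr::bind_rows(rows)
  if (random_reps > 0) {
    n <- nrow(w[[1]])
    rand <- purrr::map(seq_along(grid), function(gi) {
      m <- floor(grid[gi] * n * (n - 1) / 2 + 0.5)
      ref <- random_reference(n, m, reps = random_reps,
                              seed = child_seed(seed, 1000L + gi),
                              louvain_restarts = 1L)
      tibble::tibble(
        network = "random", sparsity = grid[gi], metric = metrics,
        value = unlist(ref[1, metrics], use.names = FALSE)
      )
    })
    out <- dplyr::bind_rows(out, dplyr::bind_rows(rand))
  }
  class(out) <- c("sparsity_curve", class(out))
  out
}
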