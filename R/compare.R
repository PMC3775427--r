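#' Edge-exchange scramble of two matched-sparsity graphs
#'
#' The permutation null for comparing two binary networks with equal edge
#' counts: identify the edges present in only one of the two graphs, pick a
#' random half (by default) of each side's private edges, and swap the two
#' selections. Shared edges are untouched and both edge counts are
#' preserved, as are the union and intersection of the edge sets. With the
#' two graphs' private edges exchangeable under the null of "no
#' configuration difference", metric differences between scrambled pairs
#' form the reference distribution.
#'
#' @param g1,g2 [binary_graph()]s on the same node set with equal edge
#'   counts.
#' @param frac Fraction of each private edge set to exchange (default 0.5);
#'   the selected count is `round(frac * |D|)` with half rounded up.
#' @param seed Integer seed (NULL uses the current RNG stream).
#' @return List with `g1`, `g2` (the mixed graphs) and `unchanged` (TRUE
#'   with a warning when the graphs were identical, so nothing could be
#'   exchanged).
#' @export
edge_exchange <- function(g1, g2, frac = 0.5, seed = NULL) {
  stopifnot(inherits(g1, "binary_graph"), inherits(g2, "binary_graph"))
  if (!identical(g1$labels, g2$labels)) {
    abort("The two graphs must share the same node set.")
  }
  if (g1$n_edges != g2$n_edges) {
    abort("Edge counts must match (threshold both at the same sparsity).")
  }
  e1 <- edge_ids(g1)
  e2 <- edge_ids(g2)
  d1 <- setdiff(e1, e2)
  d2 <- setdiff(e2, e1)
  if (!length(d1)) {
    warn("Graphs are identical; nothing to exchange.")
    return(list(g1 = g1, g2 = g2, unchanged = TRUE))
  }
  k <- floor(frac * length(d1) + 0.5) # round half up
  sel <- with_seed_maybe(seed, list(
    s1 = d1[sample.int(length(d1), k)], s2 = d2[sample.int(length(d2), k)]
  ))
  n <- g1$n_nodes
  new1 <- sort(c(setdiff(e1, sel$s1), sel$s2))
  new2 <- sort(c(setdiff(e2, sel$s2), sel$s1))
  list(
    g1 = graph_from_edge_ids(new1, n, labels = g1$labels),
    g2 = graph_from_edge_ids(new2, n, labels = g2$labels),
    unchanged = FALSE
  )
}

#' Permutation test for a between-network metric difference
#'
#' Thresholds both weighted matrices at the same sparsity, computes the
#' observed metric difference (first network minus second), and builds the
#' null distribution from `n_perm` independent [edge_exchange()] scrambles
#' of the two binary graphs. The p-value is the add-one permutation
#' estimator `p = (1 + #{|null| >= |obs|}) / (1 + n_perm)` (two-sided by
#' default), so p is never exactly 0 at finite `n_perm`.
#'
#' For the modularity metric, Q is the Louvain-optimized value with a fixed
#' number of restarts; each permutation gets its own child seed so the whole
#' test is a pure function of `seed`.
#'
#' @param w1,w2 Connectivity matrices with identical labels.
#' @param s Sparsity for thresholding.
#' @param metric One of `"efficiency"`, `"clustering"`, `"modularity"`.
#' @param n_perm Number of permutations (1000 in the reference analysis).
#' @param seed Integer root seed.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param louvain_restarts Restarts used for every modularity evaluation.
#' @return Object of class `perm_test`: observed difference, null sample,
#'   p-value and metadata. Use [tidy()] / [glance()] for tibble output.
#' @export
metric_difference_test <- function(w1, w2, s, metric = "efficiency",
                                   n_perm = 1000L, seed = 1L,
                                   alternative = c("two.sided", "greater", "less"),
                                   louvain_restarts = 5L) {
  alternative <- match.arg(alternative)
  check_same_labels(w1, w2)
  g1 <- threshold_sparsity(w1, s)
  g2 <- threshold_sparsity(w2, s)
  perm_test_graphs(g1, g2, metric = metric, n_perm = n_perm, seed = seed,
                   alternative = alternative, louvain_restarts = louvain_restarts,
                   sparsity = s)
}

#' @rdname metric_difference_test
#' @param g1,g2 Already-thresholded [binary_graph()]s with equal edge
#'   counts; `perm_test_graphs()` is the graph-level core of
#'   [metric_difference_test()].
#' @param sparsity Sparsity recorded in the result (defaults to the graphs').
#' @export
perm_test_graphs <- function(g1, g2, metric = "efficiency", n_perm = 1000L,
                             seed = 1L,
                             alternative = c("two.sided", "greater", "less"),
                             louvain_restarts = 5L, sparsity = g1$sparsity) {
  alternative <- match.arg(alternative)
  metric <- check_metrics(metric)[1]
  reg <- metric_registry(louvain_restarts = louvain_restarts)
  f <- reg[[metric]]
  observed <- f(g1, metric_seed = child_seed(seed, 0L)) -
    f(g2, metric_seed = child_seed(seed, 0L))
  identical_graphs <- identical(g1$adj, g2$adj)
  if (identical_graphs) {
    warn("Thresholded graphs are identical; the test is degenerate (p = 1).")
    nulls <- rep(0, n_perm)
  } else {
    nulls <- vapply(seq_len(n_perm), function(b) {
      sb <- child_seed(seed, b)
      mixed <- edge_exchange(g1, g2, frac = 0.5, seed = sb)
      f(mixed$g1, metric_seed = child_seed(sb, 1L)) -
        f(mixed$g2, metric_seed = child_seed(sb, 2L))
    }, numeric(1))
  }
  p <- switch(alternative,
    two.sided = (1 + sum(abs(nulls) >= abs(observed))) / (1 + n_perm),
    greater = (1 + sum(nulls >= observed)) / (1 + n_perm),
    less = (1 + sum(nulls <= observed)) / (1 + n_perm)
  )
  if (identical_graphs) p <- 1
  structure(
    list(
      metric = metric, sparsity = sparsity, observed_diff = observed,
      null_diffs = nulls, p_value = p, n_perm = as.integer(n_perm),
      alternative = alternative, seed = as.integer(seed),
      degenerate = identical_graphs
    ),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "<perm_test> %s difference at sparsity %.2f: observed %.5f, p = %.4g (%d permutations)\n",
    x$metric, x$sparsity, x$observed_diff, x$p_value, x$n_perm
  ))
  invisible(x)
}

#' @rdname metric_difference_test
#' @param x A `perm_test` object.
#' @param ... Unused.
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(
    metric = x$metric, sparsity = x$sparsity,
    observed_diff = x$observed_diff, p_value = x$p_value,
    null_mean = mean(x$null_diffs), null_sd = sd(x$null_diffs),
    n_perm = x$n_perm
  )
}

#' @rdname metric_difference_test
#' @export
glance.perm_test <- function(x, ...) {
  tibble::tibble(
    metric = x$metric, sparsity = x$sparsity, p_value = x$p_value,
    n_perm = x$n_perm, alternative = x$alternative, seed = x$seed,
    degenerate = x$degenerate
  )
}

#' Permutation tests across a sparsity grid
#'
#' Runs [metric_difference_test()] for every (sparsity, metric) pair, with
#' per-cell child seeds derived from the root seed by counter, so the sweep
#' is reproducible and each cell matches the corresponding standalone call.
#'
#' @param w1,w2 Connectivity matrices with identical labels.
#' @param grid Sparsity grid.
#' @param metrics Metrics to test.
#' @param n_perm Permutations per cell.
#' @param alpha Significance level for the `significant` flag (0.001 in the
#'   reference analysis).
#' @param seed Root seed.
#' @param louvain_restarts Restarts per modularity evaluation.
#' @return Tibble of class `perm_sweep`: one row per (sparsity, metric) with
#'   `observed_diff`, `p_value`, `significant`.
#' @export
sweep_tests <- function(w1, w2, grid = seq(0.06, 0.40, by = 0.01),
                        metrics = c("efficiency", "clustering", "modularity"),
                        n_perm = 1000L, alpha = 0.001, seed = 1L,
                        louvain_restarts = 5L) {
  metrics <- check_metrics(metrics)
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  cells <- tidyr::expand_grid(sparsity = grid, metric = metrics)
  rows <- purrr::pmap(cells, function(sparsity, metric) {
    cell_id <- which(cells$sparsity == sparsity & cells$metric == metric)
    res <- suppressWarnings(metric_difference_test(
      w1, w2, s = sparsity, metric = metric, n_perm = n_perm,
      seed = child_seed(seed, cell_id), louvain_restarts = louvain_restarts
    ))
    tibble::tibble(
      sparsity = sparsity, metric = metric,
      observed_diff = res$observed_diff, p_value = res$p_value,
      n_perm = res$n_perm
    )
  })
  out <- dplyr::mutate(dplyr::bind_rows(rows),
    significant = .data$p_value < alpha
  )
  attr(out, "alpha") <- alpha
  attr(out, "seed") <- seed
  class(out) <- c("perm_sweep", class(out))
  out
}
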