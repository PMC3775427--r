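#' Correlation of node degrees between two networks
#'
#' Thresholds both matrices at the same sparsity and correlates the two
#' degree vectors. High edge-weight similarity between two networks does not
#' imply similar hub placement: degree correlations can be low while weight
#' correlations stay high, which is the dissociation this function
#' quantifies across sparsity.
#'
#' @param w1,w2 Connectivity matrices with identical labels.
#' @param s Sparsity.
#' @param method `"pearson"` (default; degree scatter plots are summarized
#'   with linear fits) or `"spearman"`.
#' @return Correlation coefficient, or `NA` (with a warning) when either
#'   degree vector is constant.
#' @export
degree_correlation <- function(w1, w2, s, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  check_same_labels(w1, w2)
  k1 <- node_degree(threshold_sparsity(w1, s))
  k2 <- node_degree(threshold_sparsity(w2, s))
  if (var(k1) == 0 || var(k2) == 0) {
    warn("A degree vector is constant; the degree correlation is undefined.")
    return(NA_real_)
  }
  cor(k1, k2, method = method)
}

#' Per-node degree differences between two networks
#'
#' At matched sparsity, subtracts node degrees of the second network from
#' the first (`diff = degree_a - degree_b`) and sorts descending (ties by
#' label order). Because the two graphs carry the same number of edges, the
#' differences always sum to zero.
#'
#' @param w1,w2 Connectivity matrices with identical labels.
#' @param s Sparsity.
#' @return Tibble of class `degree_diff_table`: `label`, `degree_a`,
#'   `degree_b`, `diff`, `rank` (1 = largest difference).
#' @export
degree_difference_table <- function(w1, w2, s) {
  check_same_labels(w1, w2)
  k1 <- node_degree(threshold_sparsity(w1, s))
  k2 <- node_degree(threshold_sparsity(w2, s))
  out <- tibble::tibble(
    label = names(k1), degree_a = as.integer(k1), degree_b = as.integer(k2),
    diff = as.integer(k1 - k2)
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$diff), .data$label)
  out$rank <- seq_len(nrow(out))
  attr(out, "sparsity") <- s
  class(out) <- c("degree_diff_table", class(out))
  out
}

#' Null envelope for the sorted degree-difference curve
#'
#' Each permutation scrambles the two binary graphs with [edge_exchange()]
#' and records the sorted degree-difference curve; the envelope is the
#' per-rank min/max (and the two-sided 0.1% percentile band) over `n_perm`
#' curves. Rank positions where the observed sorted curve lies outside the
#' min/max band are flagged — evidence that the hub shift at that rank is
#' not explained by random reassignment of the networks' private edges.
#' Exceedance is assessed per rank position (the curves are sorted), not
#' per node identity.
#'
#' @param w1,w2 Connectivity matrices with identical labels.
#' @param s Sparsity.
#' @param n_perm Number of permutations.
#' @param seed Root seed.
#' @return Tibble of class `degree_envelope`: per rank the observed sorted
#'   difference, null min/max, percentile band (`lo`, `hi`), and `exceeds`.
#' @export
degree_envelope <- function(w1, w2, s, n_perm = 1000L, seed = 1L) {
  check_same_labels(w1, w2)
  g1 <- threshold_sparsity(w1, s)
  g2 <- threshold_sparsity(w2, s)
  n <- g1$n_nodes
  observed <- sort(node_degree(g1) - node_degree(g2), decreasing = TRUE)
  curves <- matrix(NA_real_, n_perm, n)
  if (identical(g1$adj, g2$adj)) {
    warn("Thresholded graphs are identical; the null envelope is degenerate.")
    curves[] <- 0
  } else {
    for (b in seq_len(n_perm)) {
      mixed <- edge_exchange(g1, g2, frac = 0.5, seed = child_seed(seed, b))
      curves[b, ] <- sort(node_degree(mixed$g1) - node_degree(mixed$g2),
                          decreasing = TRUE)
    }
  }
  lo_hi <- apply(curves, 2, quantile, probs = c(0.0005, 0.9995), names = FALSE)
  out <- tibble::tibble(
    rank = seq_len(n),
    observed = as.numeric(observed),
    null_min = apply(curves, 2, min),
    null_max = apply(curves, 2, max),
    lo = lo_hi[1, ], hi = lo_hi[2, ]
  )
  out$exceeds <- out$observed > out$null_max | out$observed < out$null_min
  attr(out, "sparsity") <- s
  attr(out, "n_perm") <- n_perm
  class(out) <- c("degree_envelope", class(out))
  out
}

#' Top and bottom hub-shift tables
#'
#' The k nodes with the largest (most positive) and least (most negative)
#' degree differences, with MNI coordinates when an ROI table is supplied —
#' the layout of a hub-shift summary table (x, y, z, label, degree
#' difference).
#'
#' @param table A [degree_difference_table()].
#' @param k Number of nodes per direction (default 5).
#' @param rois Optional ROI table with `label`, `x`, `y`, `z` to join
#'   coordinates.
#' @return List with tibbles `top` (diff descending) and `bottom` (diff
#'   ascending).
#' @export
top_bottom_k <- function(table, k = 5L, rois = NULL) {
  stopifnot(inherits(table, "degree_diff_table"))
  n <- nrow(table)
  if (k > n) abort("`k` cannot exceed the number of nodes.")
  fmt <- function(tb) {
    if (!is.null(rois)) {
      tb <- dplyr::left_join(tb, rois[, c("label", "x", "y", "z")], by = "label")
      tb <- dplyr::select(tb, "x", "y", "z", "label", "diff")
    } else {
      tb <- dplyr::select(tb, "label", "diff")
    }
    tb
  }
  list(
    top = fmt(utils::head(table, k)),
    bottom = fmt(utils::head(dplyr::arrange(table, .data$diff, .data$label), k))
  )
}

#' Full hub-shift analysis at selected sparsity levels
#'
#' For each sparsity: the degree correlation, the degree-difference table,
#' the top/bottom-k hub tables, and the permutation envelope of the sorted
#' difference curve.
#'
#' @param w1,w2 Connectivity matrices with identical labels.
#' @param sparsities Sparsity levels to analyze (default 0.10, 0.20, 0.30).
#' @param k Hubs per direction.
#' @param n_perm Permutations for the envelope.
#' @param seed Root seed.
#' @param rois Optional ROI table for coordinates.
#' @return List (per sparsity) of `degree_correlation`, `table`, `hubs`,
#'   `envelope`.
#' @export
hub_analysis <- function(w1, w2, sparsities = c(0.10, 0.20, 0.30), k = 5L,
                         n_perm = 1000L, seed = 1L, rois = NULL) {
  res <- purrr::map(seq_along(sparsities), function(i) {
    s <- sparsities[i]
    tab <- degree_difference_table(w1, w2, s)
    list(
      sparsity = s,
      degree_correlation = degree_correlation(w1, w2, s),
      table = tab,
      hubs = top_bottom_k(tab, k = k, rois = rois),
      envelope = degree_envelope(w1, w2, s, n_perm = n_perm,
                                 seed = child_seed(seed, i))
    )
  })
  names(res) <- paste0("s", format(sparsities))
  res
}
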