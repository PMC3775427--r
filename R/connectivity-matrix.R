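#' Construct and validate a labeled connectivity matrix
#'
#' A connectivity matrix is the common currency of the pipeline: a symmetric,
#' finite, numeric matrix whose rows and columns are labeled by region of
#' interest (ROI). Both the meta-analytic coactivation matrix and the group
#' resting-state correlation matrix take this form.
#'
#' @param m Square numeric matrix.
#' @param labels Character vector of unique node labels. Defaults to existing
#'   dimnames, or `"roi_1"`, `"roi_2"`, ... when none are present.
#' @param tol Symmetry tolerance: the maximum absolute difference between
#'   `m` and `t(m)` allowed before the matrix is rejected.
#'
#' @return A labeled symmetric numeric matrix.
#' @export
#' @examples
#' connectivity_matrix(diag(3))
connectivity_matrix <- function(m, labels = NULL, tol = 1e-10) {
  if (!is.matrix(m) || !is.numeric(m)) {
    abort("`m` must be a numeric matrix.")
  }
  if (nrow(m) != ncol(m)) {
    abort("`m` must be square.")
  }
  if (any(!is.finite(m))) {
    abort("`m` must contain only finite values.")
  }
  if (max(abs(m - t(m))) > tol) {
    abort("`m` is not symmetric within tolerance; symmetrize() it first.")
  }
  m <- (m + t(m)) / 2
  if (is.null(labels)) {
    labels <- rownames(m) %||% paste0("roi_", seq_len(nrow(m)))
  }
  stopifnot(length(labels) == nrow(m))
  if (anyDuplicated(labels)) {
    abort("Node labels must be unique.")
  }
  dimnames(m) <- list(labels, labels)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_same_labels <- function(w1, w2) {
  if (!identical(rownames(w1), rownames(w2))) {
    abort("The two matrices must share the same node labels in the same order.")
  }
  invisible(TRUE)
}

#' Derive a child seed from a root seed and a counter
#'
#' Child seeds let every subject, permutation or restart own a reproducible
#' RNG stream while the whole analysis is a pure function of one root seed.
#' Kept below 2^31 so the result is always a valid R integer seed.
#'
#' @param seed Integer root seed.
#' @param counter Non-negative integer counter.
#' @return An integer seed.
#' @export
child_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + as.double(counter) * 16807) %% 2147483629)
}

# Run `expr` under `seed` when given, without touching the caller's RNG state;
# with seed = NULL the current RNG stream is used (and advanced).
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
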