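#' Read and write labeled connectivity matrices as TSV
#'
#' Matrices are stored as tab-separated text with matching row and column
#' label headers, at full floating precision, so `read_matrix(write_matrix(m))`
#' round-trips bitwise. On read, asymmetry beyond `tol` triggers a warning
#' and the matrix is symmetrized.
#'
#' @param path File path.
#' @param m A [connectivity_matrix()].
#' @param tol Symmetry tolerance on read.
#' @return `read_matrix()`: a [connectivity_matrix()]. `write_matrix()`:
#'   `path`, invisibly.
#' @export
read_matrix <- function(path, tol = 1e-10) {
  df <- read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(!vapply(df, is.numeric, logical(1)))[1]
    abort(sprintf("Non-numeric values in column '%s' of %s.", names(df)[bad], path))
  }
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m))) {
    abort(sprintf("Row and column labels of %s do not match.", path))
  }
  asym <- max(abs(m - t(m)))
  if (asym > tol) {
    warn(sprintf("Matrix in %s asymmetric (max dev %.3g); symmetrizing.", path, asym))
    m <- symmetrize(m)
  }
  connectivity_matrix(m, tol = Inf)
}

#' @rdname read_matrix
#' @export
write_matrix <- function(m, path) {
  m <- connectivity_matrix(m)
  df <- data.frame(label = rownames(m), m, check.names = FALSE)
  names(df)[1] <- ""
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
    path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read an ROI table
#'
#' Expects tab-separated columns `label`, `x`, `y`, `z` (MNI mm),
#' `radius_mm`, `network`. An optional logical column `in_mask` marks ROIs
#' that fall outside the analysis mask; those rows are dropped (and
#' counted), mirroring the bookkeeping by which a published ROI inventory is
#' reduced to the analyzed set.
#'
#' @param path File path, or a data frame already in the required layout.
#' @return A tibble of class `roi_set`, with attribute `n_dropped`.
#' @export
read_roiset <- function(path) {
  df <- if (is.data.frame(path)) path else read.delim(path, check.names = TRUE)
  need <- c("label", "x", "y", "z", "radius_mm", "network")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(paste0("ROI table is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  n_dropped <- 0L
  if ("in_mask" %in% names(df)) {
    n_dropped <- sum(!df$in_mask)
    df <- df[as.logical(df$in_mask), , drop = FALSE]
  }
  if (anyDuplicated(df$label)) {
    dup <- df$label[duplicated(df$label)][1]
    abort(sprintf("Duplicate ROI label '%s'.", dup))
  }
  if (nrow(df) < 2) abort("An ROI set needs at least 2 ROIs.")
  if (any(df$radius_mm <= 0)) abort("ROI radii must be positive.")
  out <- tibble::as_tibble(df[, union(need, setdiff(names(df), "in_mask"))])
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("roi_set", class(out))
  out
}

#' Write a binary graph as an edge-list TSV
#'
#' Columns: `i`, `j` (1-based node indices, i < j), `label_i`, `label_j`.
#'
#' @param g A [binary_graph()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(g, path) {
  write.table(graph_edges(g), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a synthetic ROI table
#'
#' Random MNI-plausible coordinates with the requested sphere radius and a
#' round-robin network affiliation; labels are `roi_001`, ... . A synthetic
#' stand-in for a published ROI inventory, for tests and demonstrations.
#'
#' @param n Number of ROIs (the reference analysis uses 140).
#' @param radius_mm Sphere radius (10 mm in the reference analysis).
#' @param n_networks Number of network affiliations to cycle through.
#' @param seed Integer seed.
#' @return An `roi_set` tibble.
#' @export
gen_roiset <- function(n = 140L, radius_mm = 10, n_networks = 6L, seed = 1L) {
  with_seed_maybe(seed, {
    tb <- tibble::tibble(
      label = sprintf("roi_%03d", seq_len(n)),
      x = round(runif(n, -70, 70)),
      y = round(runif(n, -100, 70)),
      z = round(runif(n, -45, 75)),
      radius_mm = radius_mm,
      network = paste0("net_", ((seq_len(n) - 1L) %% n_networks) + 1L)
    )
    read_roiset(tb)
  })
}
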