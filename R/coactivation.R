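#' Extract per-ROI values from a volumetric map
#'
#' For each spherical ROI, averages the values of all voxels whose world-space
#' (MNI mm) center lies within `radius_mm` of the ROI center (closed ball).
#' This is how one seed's whole-brain coactivation map is reduced to one value
#' per target ROI.
#'
#' @param map A volume as returned by [gen_volume_with_spheres()]: a list with
#'   `data` (3-D array) and `affine` (4x4 voxel-to-world transform, 1-based
#'   voxel indices). A file path to a NIfTI volume is also accepted (read via
#'   the RNifti package, whose affine maps 0-based indices).
#' @param rois ROI table as returned by [read_roiset()]: columns `label`,
#'   `x`, `y`, `z`, `radius_mm`.
#' @param statistic Summary over in-sphere voxels: `"mean"` (default),
#'   `"max"`, or `"center"` (value of the voxel nearest the ROI center).
#' @return Named numeric vector, one value per ROI in table order.
#' @export
extract_roi_values <- function(map, rois, statistic = c("mean", "max", "center")) {
  statistic <- match.arg(statistic)
  map <- as_volume(map)
  if (abs(det(map$affine)) < 1e-12) abort("Volume affine must be invertible.")
  dims <- dim(map$data)
  # world coordinates of every voxel center
  idx <- as.matrix(expand.grid(
    i = seq_len(dims[1]), j = seq_len(dims[2]), k = seq_len(dims[3])
  ))
  world <- cbind(idx, 1) %*% t(map$affine)
  vals <- as.vector(map$data)
  out <- numeric(nrow(rois))
  for (r in seq_len(nrow(rois))) {
    ctr <- c(rois$x[r], rois$y[r], rois$z[r])
    d2 <- (world[, 1] - ctr[1])^2 + (world[, 2] - ctr[2])^2 + (world[, 3] - ctr[3])^2
    inside <- d2 <= rois$radius_mm[r]^2
    if (!any(inside)) {
      abort(sprintf("ROI '%s': sphere contains no voxel centers.", rois$label[r]))
    }
    out[r] <- switch(statistic,
      mean = mean(vals[inside]),
      max = max(vals[inside]),
      center = vals[which.min(d2)]
    )
  }
  setNames(out, rois$label)
}

as_volume <- function(map) {
  if (is.character(map)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      abort("Reading NIfTI files requires the RNifti package.")
    }
    img <- RNifti::readNifti(map)
    aff <- structure(RNifti::xform(img), class = NULL)
    # RNifti xform maps 0-based voxel indices; shift to 1-based
    aff[, 4] <- aff %*% c(-1, -1, -1, 1)
    return(list(data = as.array(img), affine = aff))
  }
  if (!is.list(map) || is.null(map$data) || is.null(map$affine)) {
    abort("`map` must be a list(data, affine) volume or a NIfTI file path.")
  }
  map
}

#' Normalize a raw seed-by-target matrix by its diagonal
#'
#' Each row of the raw coactivation matrix comes from a different seed
#' inquiry, and inquiries return different numbers of studies, so rows are
#' on different scales. Dividing row i by its diagonal entry (the seed's
#' coactivation with itself) removes the per-seed scale, making the diagonal
#' exactly 1.
#'
#' @param raw Square numeric matrix with finite, nonnegative entries and a
#'   strictly positive diagonal.
#' @return Matrix with `out[i, j] = raw[i, j] / raw[i, i]`.
#' @export
#' @examples
#' normalize_by_diagonal(matrix(c(2, 1, 4, 5), 2))
normalize_by_diagonal <- function(raw) {
  raw <- check_raw_matrix(raw)
  raw / diag(raw)
}

check_raw_matrix <- function(raw) {
  if (!is.matrix(raw) || !is.numeric(raw) || nrow(raw) != ncol(raw)) {
    abort("`raw` must be a square numeric matrix.")
  }
  if (any(!is.finite(raw)) || any(raw < 0)) {
    abort("`raw` must be finite and nonnegative.")
  }
  bad <- which(diag(raw) <= 0)
  if (length(bad)) {
    lab <- (rownames(raw) %||% as.character(seq_len(nrow(raw))))[bad[1]]
    abort(sprintf(
      "Seed ROI '%s' has a nonpositive diagonal value; cannot normalize.", lab
    ))
  }
  raw
}

#' Log-transform a nonnegative matrix
#'
#' `ln(1 + x)` elementwise. Coactivation values are strongly right-skewed;
#' adding one and taking the natural log pulls the distribution toward
#' normal while mapping 0 to 0. The transform is strictly monotone, so edge
#' rankings — and therefore every thresholded binary graph — are unchanged
#' by the choice of log base.
#'
#' @param m Numeric matrix with entries `>= 0`.
#' @return `log1p(m)`.
#' @export
log_transform <- function(m) {
  if (any(m < 0)) abort("`m` must be nonnegative.")
  log1p(m)
}

#' Symmetrize a square matrix
#'
#' Averages the matrix with its transpose: the coactivation of A with B and
#' of B with A are similar but not identical, and their mean defines the
#' undirected edge weight. The diagonal is unchanged and the operation is
#' idempotent.
#'
#' @param m Square numeric matrix.
#' @return `(m + t(m)) / 2`.
#' @export
symmetrize <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) abort("`m` must be square.")
  (m + t(m)) / 2
}

#' Build the symmetric coactivation connectivity matrix
#'
#' Applies the full recipe to a raw seed-by-target value matrix: normalize
#' each row by its diagonal, add one and log-transform, then symmetrize.
#' Every diagonal entry of the result is `ln 2` (the diagonal is 1 after
#' normalization, then `ln(1 + 1)`), and the result is invariant to
#' rescaling any raw row by a positive constant.
#'
#' @param raw Square nonnegative matrix, rows indexed by seed ROI, columns
#'   by target ROI, positive diagonal.
#' @param labels Optional ROI labels (defaults to `rownames(raw)`).
#' @return A [connectivity_matrix()] with diagonal `log(2)`.
#' @export
#' @examples
#' raw <- matrix(c(2, 1, 4, 5), 2, dimnames = list(c("a", "b"), c("a", "b")))
#' build_coactivation_matrix(raw)
build_coactivation_matrix <- function(raw, labels = NULL) {
  raw <- check_raw_matrix(raw)
  labels <- labels %||% rownames(raw)
  out <- symmetrize(log_transform(normalize_by_diagonal(raw)))
  connectivity_matrix(out, labels = labels)
}

#' Assemble a raw coactivation matrix from per-seed volumetric maps
#'
#' Extracts one row per seed ROI from that seed's whole-brain coactivation
#' map, yielding the raw seed-by-target matrix consumed by
#' [build_coactivation_matrix()].
#'
#' @param maps List of volumes (or NIfTI paths), one per ROI, in ROI order.
#' @param rois ROI table (see [read_roiset()]).
#' @param statistic Passed to [extract_roi_values()].
#' @return Raw matrix with rows/columns labeled by ROI.
#' @export
raw_matrix_from_maps <- function(maps, rois, statistic = "mean") {
  if (length(maps) != nrow(rois)) {
    abort("Need exactly one map per ROI, in ROI order.")
  }
  rows <- purrr::map(maps, extract_roi_values, rois = rois, statistic = statistic)
  raw <- do.call(rbind, rows)
  dimnames(raw) <- list(rois$label, rois$label)
  raw
}
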