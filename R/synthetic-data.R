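#' Specification for a planted modular weight matrix
#'
#' Describes the block structure of a synthetic connectivity matrix:
#' within-module weights are drawn around `mu_in`, between-module weights
#' around `mu_out` (with `mu_in > mu_out >= 0`), with Gaussian noise of
#' standard deviation `sigma` clipped at zero so weights stay nonnegative.
#'
#' @param n_nodes Total number of nodes.
#' @param module_sizes Integer sizes summing to `n_nodes`.
#' @param mu_in,mu_out Mean within- and between-module weight.
#' @param sigma Weight noise SD (>= 0).
#' @param seed Integer RNG seed.
#' @return A `modular_spec` list.
#' @export
modular_spec <- function(n_nodes, module_sizes, mu_in, mu_out, sigma, seed = 1L) {
  if (sum(module_sizes) != n_nodes) {
    abort("`module_sizes` must sum to `n_nodes`.")
  }
  if (!(mu_in > mu_out && mu_out >= 0)) abort("Need mu_in > mu_out >= 0.")
  if (sigma < 0) abort("`sigma` must be >= 0.")
  structure(
    list(
      n_nodes = as.integer(n_nodes), module_sizes = as.integer(module_sizes),
      mu_in = mu_in, mu_out = mu_out, sigma = sigma, seed = as.integer(seed)
    ),
    class = "modular_spec"
  )
}

#' Generate a symmetric modular weight matrix
#'
#' Off-diagonal weights are Gaussian draws centered at `mu_in` inside the
#' planted modules and `mu_out` between them, clipped at 0; the diagonal is
#' set to 1. The planted module assignment is attached as attribute
#' `"modules"` so recovery tests can compare detected communities against
#' the ground truth.
#'
#' @param spec A [modular_spec()].
#' @return A [connectivity_matrix()] with attribute `modules` (integer
#'   module id per node).
#' @export
gen_modular_matrix <- function(spec) {
  stopifnot(inherits(spec, "modular_spec"))
  n <- spec$n_nodes
  modules <- rep(seq_along(spec$module_sizes), spec$module_sizes)
  mu <- matrix(spec$mu_out, n, n)
  same <- outer(modules, modules, `==`)
  mu[same] <- spec$mu_in
  w <- with_seed_maybe(spec$seed, {
    noise <- matrix(rnorm(n * n, 0, spec$sigma), n, n)
    noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
    pmax(mu + noise, 0)
  })
  diag(w) <- 1
  out <- connectivity_matrix(w)
  attr(out, "modules") <- modules
  out
}

#' Generate a raw seed-by-target count matrix with per-seed scale biases
#'
#' Emulates the fact that each seed inquiry of a coactivation database
#' returns a different number of studies: row i of the output is row i of
#' `base` multiplied by `per_seed_scale[i]`, plus nonnegative half-normal
#' noise. The output is asymmetric in general; diagonal-normalization in the
#' coactivation builder removes the planted scales exactly when `noise_sd = 0`.
#'
#' @param base Symmetric base connectivity matrix with positive diagonal.
#' @param per_seed_scale Positive scale per seed row (length = nodes).
#' @param noise_sd SD of the half-normal noise added to every entry.
#' @param seed Integer RNG seed.
#' @return Raw nonnegative matrix with strictly positive diagonal.
#' @export
gen_seed_count_matrix <- function(base, per_seed_scale, noise_sd = 0, seed = 1L) {
  base <- connectivity_matrix(base)
  n <- nrow(base)
  if (length(per_seed_scale) != n) {
    abort("`per_seed_scale` must have one entry per node.")
  }
  if (any(per_seed_scale <= 0)) abort("Per-seed scales must be positive.")
  if (any(diag(base) <= 0)) abort("`base` must have a positive diagonal.")
  raw <- base * per_seed_scale # recycles down columns: row i scaled
  if (noise_sd > 0) {
    noise <- with_seed_maybe(seed, matrix(abs(rnorm(n * n, 0, noise_sd)), n, n))
    diag(noise) <- 0 # keep the diagonal's planted scale exact
    raw <- raw + noise
  }
  raw
}

#' Generate a multi-subject ROI time-series panel
#'
#' Draws each subject's T x N series from a multivariate normal with the
#' given population covariance (repaired to positive semidefinite by
#' clipping negative eigenvalues at 1e-10, with a warning, since modular
#' templates can be slightly indefinite), adds independent Gaussian noise,
#' and attaches synthetic motion traces (random walks) and smooth WM/CSF
#' eigenvector regressors. One subject can be planted as a motion violator
#' whose peak absolute translation is scaled to a chosen value, to exercise
#' the motion screen.
#'
#' @param cov Symmetric population covariance (a [connectivity_matrix()]).
#' @param n_subjects Number of subjects (>= 1).
#' @param t_len Time points per subject (>= 10; 240 frames at TR 1.8 s
#'   matches a typical resting-state acquisition after dummy-scan removal).
#' @param tr_seconds Repetition time in seconds.
#' @param noise_sd SD of i.i.d. measurement noise added to the series.
#' @param motion_spec List: `step_sd` (random-walk step SD, mm),
#'   `violator_subject` (index or NULL), `violator_peak_mm` (peak |translation|
#'   given to the violator).
#' @param seed Root seed; per-subject streams are derived with
#'   [child_seed()], so subject k's data does not change when `n_subjects`
#'   grows.
#' @return A panel: list with `series`, `motion`, `wm_eigs`, `csf_eigs`
#'   (per-subject lists) and `tr_seconds`.
#' @export
gen_subject_panel <- function(cov, n_subjects, t_len = 240L, tr_seconds = 1.8,
                              noise_sd = 0.5,
                              motion_spec = list(step_sd = 0.02,
                                                 violator_subject = NULL,
                                                 violator_peak_mm = 3.5),
                              seed = 1L) {
  cov <- connectivity_matrix(cov)
  if (n_subjects < 1) abort("Need at least one subject.")
  if (t_len < 10) abort("Need at least 10 time points.")
  n <- nrow(cov)
  labels <- rownames(cov)
  cov <- psd_repair(cov)
  eig <- eigen(cov, symmetric = TRUE)
  sqrt_cov <- eig$vectors %*% (t(eig$vectors) * sqrt(pmax(eig$values, 0)))
  step_sd <- motion_spec$step_sd %||% 0.02
  subj <- purrr::map(seq_len(n_subjects), function(s) {
    with_seed_maybe(child_seed(seed, s), {
      z <- matrix(rnorm(t_len * n), t_len, n)
      x <- z %*% sqrt_cov
      if (noise_sd > 0) x <- x + matrix(rnorm(t_len * n, 0, noise_sd), t_len, n)
      colnames(x) <- labels
      motion <- apply(matrix(rnorm(t_len * 6, 0, step_sd), t_len, 6), 2, cumsum)
      if (identical(s, as.integer(motion_spec$violator_subject)) ||
          isTRUE(s == motion_spec$violator_subject)) {
        peak <- motion_spec$violator_peak_mm %||% 3.5
        cur <- max(abs(motion[, 1:3]))
        motion[, 1:3] <- motion[, 1:3] * (peak / cur)
      }
      list(
        series = x, motion = motion,
        wm = smooth_regressors(t_len, 5), csf = smooth_regressors(t_len, 5)
      )
    })
  })
  list(
    series = purrr::map(subj, "series"),
    motion = purrr::map(subj, "motion"),
    wm_eigs = purrr::map(subj, "wm"),
    csf_eigs = purrr::map(subj, "csf"),
    tr_seconds = tr_seconds
  )
}

# Clip negative eigenvalues at 1e-10 so slightly indefinite modular
# templates become usable covariances; warns when a repair happened.
psd_repair <- function(cov) {
  eig <- eigen(cov, symmetric = TRUE)
  if (min(eig$values) >= 0) return(cov)
  warn(sprintf(
    "Covariance repaired: %d negative eigenvalue(s) clipped at 1e-10.",
    sum(eig$values < 0)
  ))
  out <- eig$vectors %*% (t(eig$vectors) * pmax(eig$values, 1e-10))
  dimnames(out) <- dimnames(cov)
  (out + t(out)) / 2
}

# Smooth random series: white noise passed through a moving-average window,
# then scaled to unit SD. Emulates slow physiological eigenvariates.
smooth_regressors <- function(t_len, k, window = 9L) {
  x <- matrix(rnorm(t_len * k), t_len, k)
  kern <- rep(1 / window, window)
  sm <- apply(x, 2, function(col) {
    as.numeric(stats::filter(col, kern, sides = 2, circular = TRUE))
  })
  scale(sm, center = TRUE, scale = apply(sm, 2, sd))[, , drop = FALSE]
}

#' Increase all weights incident to one node
#'
#' Adds `boost` to every off-diagonal weight in the chosen node's row and
#' column, preserving symmetry. Used to plant a hub whose degree after
#' thresholding exceeds every other node's — the ground truth for hub-shift
#' recovery tests.
#'
#' @param w A [connectivity_matrix()].
#' @param node_index Node to boost (integer index or label).
#' @param boost Positive weight increment.
#' @return The boosted [connectivity_matrix()] (planted `modules` attribute,
#'   if any, is preserved).
#' @export
plant_hub <- function(w, node_index, boost) {
  w <- connectivity_matrix(w)
  if (is.character(node_index)) node_index <- match(node_index, rownames(w))
  n <- nrow(w)
  if (is.na(node_index) || node_index < 1 || node_index > n) {
    abort("`node_index` is out of range.")
  }
  if (!is.numeric(boost) || boost <= 0) abort("`boost` must be positive.")
  mods <- attr(w, "modules")
  d <- diag(w)
  w[node_index, ] <- w[node_index, ] + boost
  w[, node_index] <- w[, node_index] + boost
  diag(w) <- d
  out <- connectivity_matrix(w)
  attr(out, "modules") <- mods
  out
}

#' Boost all between-module weights
#'
#' Adds `boost` to every off-diagonal weight whose endpoints lie in
#' different planted modules. Starting from a resting-like modular matrix,
#' this manufactures a task-like matrix with stronger between-system
#' coupling: higher global efficiency and lower modularity at matched
#' sparsity.
#'
#' @param w A [connectivity_matrix()] carrying a `modules` attribute (from
#'   [gen_modular_matrix()]), or supply `modules` explicitly.
#' @param boost Positive weight increment.
#' @param modules Optional integer module id per node.
#' @return The boosted [connectivity_matrix()].
#' @export
boost_between_modules <- function(w, boost, modules = attr(w, "modules")) {
  w <- connectivity_matrix(w)
  if (is.null(modules)) abort("No module assignment available.")
  if (boost <= 0) abort("`boost` must be positive.")
  between <- outer(modules, modules, `!=`)
  diag(between) <- FALSE
  out <- w + boost * between
  out <- connectivity_matrix(out)
  attr(out, "modules") <- modules
  out
}

#' Paint ROI spheres into a volume
#'
#' Builds a 3-D volume in which voxels whose world-space centers fall within
#' each ROI sphere carry that ROI's value (later ROIs win on overlap; the
#' overlap voxel count is attached as attribute `overlap_voxels`), with 0
#' background. Used as a fixture for sphere extraction.
#'
#' @param grid_shape Integer 3-vector of voxel dimensions.
#' @param affine 4x4 voxel-to-world transform (1-based voxel indices).
#' @param rois ROI table (`label`, `x`, `y`, `z`, `radius_mm`).
#' @param values One value per ROI.
#' @return A volume `list(data, affine)` with attribute `overlap_voxels`.
#' @export
gen_volume_with_spheres <- function(grid_shape, affine, rois, values) {
  if (length(values) != nrow(rois)) abort("Need one value per ROI.")
  if (abs(det(affine)) < 1e-12) abort("`affine` must be invertible.")
  dims <- as.integer(grid_shape)
  data <- array(0, dim = dims)
  painted <- array(FALSE, dim = dims)
  idx <- as.matrix(expand.grid(
    i = seq_len(dims[1]), j = seq_len(dims[2]), k = seq_len(dims[3])
  ))
  world <- cbind(idx, 1) %*% t(affine)
  overlap <- 0L
  for (r in seq_len(nrow(rois))) {
    d2 <- (world[, 1] - rois$x[r])^2 + (world[, 2] - rois$y[r])^2 +
      (world[, 3] - rois$z[r])^2
    inside <- d2 <= rois$radius_mm[r]^2
    if (!any(inside)) {
      abort(sprintf("ROI '%s': sphere lies entirely outside the grid.", rois$label[r]))
    }
    overlap <- overlap + sum(painted[inside])
    data[inside] <- values[r]
    painted[inside] <- TRUE
  }
  structure(list(data = data, affine = affine), overlap_voxels = overlap)
}
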