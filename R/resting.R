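#' Screen subjects for excessive head motion
#'
#' A subject is excluded if and only if the maximum absolute value over its
#' translation parameters exceeds `threshold_mm` (strictly greater; a peak of
#' exactly the threshold is kept). Rotations are reported in the log but not
#' thresholded, since the criterion is in millimetres.
#'
#' @param panel A subject panel (see [gen_subject_panel()]): must carry a
#'   `motion` list of per-subject T x 6 matrices, columns 1-3 translations
#'   (mm), columns 4-6 rotations.
#' @param threshold_mm Exclusion threshold in mm (default 3).
#' @return List with `kept` (integer indices of retained subjects) and `log`
#'   (tibble: subject, peak translation mm, peak rotation, excluded flag).
#' @export
motion_screen <- function(panel, threshold_mm = 3) {
  check_panel(panel)
  peaks <- purrr::map_dbl(panel$motion, ~ max(abs(.x[, 1:3])))
  rot_peaks <- purrr::map_dbl(panel$motion, ~ max(abs(.x[, 4:6])))
  excluded <- peaks > threshold_mm
  list(
    kept = which(!excluded),
    log = tibble::tibble(
      subject = seq_along(panel$motion),
      peak_translation_mm = peaks,
      peak_rotation = rot_peaks,
      excluded = excluded
    )
  )
}

check_panel <- function(panel) {
  need <- c("series", "motion", "wm_eigs", "csf_eigs", "tr_seconds")
  if (!is.list(panel) || !all(need %in% names(panel))) {
    abort("`panel` must carry series, motion, wm_eigs, csf_eigs, tr_seconds.")
  }
  ns <- length(panel$series)
  if (length(panel$motion) != ns) abort("Missing motion trace for some subject.")
  invisible(panel)
}

#' Build the nuisance design matrix
#'
#' Columns: the six head motion parameters, their first-order backward
#' differences (first row 0), the first five WM eigenvector time series, the
#' first five CSF eigenvector time series, and an intercept — 23 columns.
#' Any constant offset in a derivative convention is absorbed by the
#' intercept.
#'
#' @param motion T x 6 motion-parameter matrix.
#' @param wm_eigs,csf_eigs T x 5 eigenvector time-series matrices.
#' @return T x 23 matrix with column roles as names
#'   (`motion1..6, dmotion1..6, wm1..5, csf1..5, intercept`).
#' @export
build_nuisance <- function(motion, wm_eigs, csf_eigs) {
  motion <- as.matrix(motion)
  wm_eigs <- as.matrix(wm_eigs)
  csf_eigs <- as.matrix(csf_eigs)
  tt <- nrow(motion)
  if (nrow(wm_eigs) != tt || nrow(csf_eigs) != tt) {
    abort("motion, wm_eigs and csf_eigs must have the same number of time points.")
  }
  if (ncol(motion) != 6 || ncol(wm_eigs) != 5 || ncol(csf_eigs) != 5) {
    abort("Expected 6 motion, 5 WM and 5 CSF columns.")
  }
  dmotion <- rbind(0, diff(motion))
  out <- cbind(motion, dmotion, wm_eigs, csf_eigs, 1)
  colnames(out) <- c(
    paste0("motion", 1:6), paste0("dmotion", 1:6),
    paste0("wm", 1:5), paste0("csf", 1:5), "intercept"
  )
  out
}

#' Regress nuisance signals out of ROI time series
#'
#' Ordinary least-squares residuals of each ROI column on the nuisance
#' design. Residuals are orthogonal to every nuisance column. A
#' rank-deficient design is handled by the pseudoinverse (with a warning).
#'
#' @param series T x N matrix of ROI time series.
#' @param nuisance T x K nuisance design (see [build_nuisance()]).
#' @return T x N residual matrix.
#' @export
regress_nuisance <- function(series, nuisance) {
  series <- as.matrix(series)
  nuisance <- as.matrix(nuisance)
  tt <- nrow(series)
  k <- ncol(nuisance)
  if (nrow(nuisance) != tt) abort("series and nuisance must share T.")
  if (tt <= k) abort("Need more time points than nuisance columns (T > K).")
  qrx <- qr(nuisance)
  if (qrx$rank < k) {
    warn("Nuisance design is rank deficient; using the pseudoinverse.")
    beta <- MASS_ginv(nuisance) %*% series
    return(series - nuisance %*% beta)
  }
  qr.resid(qrx, series)
}

# Moore-Penrose pseudoinverse via SVD (small matrices only).
MASS_ginv <- function(x, tol = sqrt(.Machine$double.eps)) {
  s <- svd(x)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Band-pass filter ROI time series
#'
#' Default is an ideal FFT-domain filter: frequency bins with
#' `low_hz <= f <= high_hz` (inclusive edges) are kept, all others —
#' including the DC mean — are zeroed. A 4th-order zero-phase Butterworth
#' (via \pkg{signal}) is available as an alternative with smoother roll-off.
#'
#' @param series T x N matrix.
#' @param low_hz,high_hz Pass-band edges in Hz (defaults 0.01 and 0.1, the
#'   conventional resting-state fluctuation band).
#' @param tr_seconds Sampling interval (repetition time), seconds.
#' @param method `"ideal"` (FFT mask) or `"butterworth"`.
#' @return Filtered T x N matrix (real).
#' @export
bandpass_filter <- function(series, low_hz = 0.01, high_hz = 0.1,
                            tr_seconds = 1.8, method = c("ideal", "butterworth")) {
  method <- match.arg(method)
  series <- as.matrix(series)
  tt <- nrow(series)
  if (tt < 32) abort("Band-pass filtering needs at least 32 time points.")
  nyquist <- 1 / (2 * tr_seconds)
  if (!(0 < low_hz && low_hz < high_hz && high_hz < nyquist)) {
    abort(sprintf(
      "Band edges must satisfy 0 < low < high < Nyquist (%.4f Hz).", nyquist
    ))
  }
  if (method == "butterworth") {
    if (!requireNamespace("signal", quietly = TRUE)) {
      abort("method = \"butterworth\" requires the signal package.")
    }
    bf <- signal::butter(4, c(low_hz, high_hz) / nyquist, type = "pass")
    return(apply(series, 2, function(x) signal::filtfilt(bf, x)))
  }
  freqs <- (seq_len(tt) - 1) / (tt * tr_seconds)
  freqs <- pmin(freqs, 1 / tr_seconds - freqs) # fold to [0, Nyquist]
  keep <- freqs >= low_hz & freqs <= high_hz
  ft <- mvfft(series)
  ft[!keep, ] <- 0
  Re(mvfft(ft, inverse = TRUE)) / tt
}

#' Kendall rank correlation matrix of ROI time series
#'
#' Pairwise Kendall tau-b (tie-corrected) between all ROI columns; the rank
#' statistic damps the influence of noise spikes relative to Pearson
#' correlation. Constant columns have no rank ordering and are rejected by
#' name.
#'
#' @param series T x N matrix, T >= 3, labeled columns.
#' @return Symmetric N x N matrix, unit diagonal, entries in `[-1, 1]`.
#' @export
kendall_matrix <- function(series) {
  series <- as.matrix(series)
  if (nrow(series) < 3) abort("Kendall correlation needs at least 3 time points.")
  rng <- apply(series, 2, function(x) diff(range(x)))
  if (any(rng == 0)) {
    lab <- (colnames(series) %||% as.character(seq_len(ncol(series))))[which(rng == 0)[1]]
    abort(sprintf("ROI '%s' has a constant time series; tau is undefined.", lab))
  }
  tau <- cor(series, method = "kendall")
  diag(tau) <- 1
  (tau + t(tau)) / 2
}

#' Fisher's z transform and its inverse
#'
#' `fisher_z()` is `atanh(r)`; correlations with `|r| = 1` are clipped to
#' `1 - 1e-7` (with a warning) so group averaging never propagates
#' infinities. `fisher_inv()` is `tanh(z)`.
#'
#' @param r Correlation value(s), `|r| <= 1`.
#' @param z Fisher z value(s).
#' @return Transformed numeric vector/matrix.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1)) abort("|r| must be <= 1.")
  if (any(abs(r) == 1)) {
    warn("Correlations of |r| = 1 clipped to 1 - 1e-7 before atanh.")
    r <- sign(r) * pmin(abs(r), 1 - 1e-7)
  }
  atanh(r)
}

#' @rdname fisher_z
#' @export
fisher_inv <- function(z) tanh(z)

#' Average per-subject correlation matrices through Fisher's z
#'
#' Off-diagonal entries are transformed with [fisher_z()], averaged across
#' subjects, and back-transformed; the diagonal is set to 1 without
#' transformation (atanh(1) is infinite).
#'
#' @param matrices Non-empty list of equally sized correlation matrices.
#' @return A [connectivity_matrix()] with unit diagonal.
#' @export
group_average <- function(matrices) {
  if (!length(matrices)) abort("Need at least one matrix.")
  dims <- purrr::map(matrices, dim)
  if (length(unique(dims)) != 1) abort("All matrices must have the same shape.")
  zs <- purrr::map(matrices, function(m) {
    diag(m) <- 0 # excluded from the transform; reset below
    fisher_z(m)
  })
  mean_z <- Reduce(`+`, zs) / length(zs)
  out <- fisher_inv(mean_z)
  diag(out) <- 1
  connectivity_matrix(symmetrize(out), labels = rownames(matrices[[1]]))
}

#' Build the group resting-state connectivity matrix from a subject panel
#'
#' The full resting-state chain: screen out high-motion subjects, then per
#' subject regress out the nuisance design (6 motion parameters, their
#' derivatives, 5 WM and 5 CSF eigenvectors, intercept), band-pass filter,
#' and compute the Kendall tau matrix; finally Fisher-z average across the
#' retained subjects.
#'
#' @param panel Subject panel (see [gen_subject_panel()]).
#' @param low_hz,high_hz,filter_method Passed to [bandpass_filter()].
#' @param motion_threshold_mm Passed to [motion_screen()].
#' @param filter_first If `TRUE`, filter before nuisance regression; the
#'   default regresses first (the conventional listing order).
#' @return List with `matrix` (the group [connectivity_matrix()]),
#'   `motion_log`, `n_subjects_used`.
#' @export
build_resting_matrix <- function(panel, low_hz = 0.01, high_hz = 0.1,
                                 motion_threshold_mm = 3,
                                 filter_method = "ideal",
                                 filter_first = FALSE) {
  check_panel(panel)
  screen <- motion_screen(panel, threshold_mm = motion_threshold_mm)
  if (!length(screen$kept)) abort("All subjects excluded by the motion screen.")
  taus <- purrr::map(screen$kept, function(s) {
    x <- as.matrix(panel$series[[s]])
    nuis <- build_nuisance(panel$motion[[s]], panel$wm_eigs[[s]], panel$csf_eigs[[s]])
    if (filter_first) {
      x <- bandpass_filter(x, low_hz, high_hz, panel$tr_seconds, filter_method)
      x <- regress_nuisance(x, nuis)
    } else {
      x <- regress_nuisance(x, nuis)
      x <- bandpass_filter(x, low_hz, high_hz, panel$tr_seconds, filter_method)
    }
    kendall_matrix(x)
  })
  list(
    matrix = group_average(taus),
    motion_log = screen$log,
    n_subjects_used = length(screen$kept)
  )
}
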