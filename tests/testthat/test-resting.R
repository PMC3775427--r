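make_panel <- function(n_subjects = 3, t_len = 60, n = 6, seed = 2,
                       noise_sd = 0.3, motion_spec = list(step_sd = 0.02)) {
  w <- gen_modular_matrix(modular_spec(n, c(ceiling(n / 2), floor(n / 2)),
                                       0.6, 0.2, 0.05, seed = seed))
  gen_subject_panel(w, n_subjects, t_len = t_len, noise_sd = noise_sd,
                    motion_spec = motion_spec, seed = seed)
}

test_that("motion screen excludes only peaks strictly above the threshold", {
  panel <- make_panel(4, t_len = 40)
  screen <- motion_screen(panel)
  expect_identical(screen$kept, 1:4) # random-walk traces stay near 0

  # a planted 3.5 mm violator among many is the only exclusion
  pv <- make_panel(10, t_len = 40,
                   motion_spec = list(step_sd = 0.02, violator_subject = 3,
                                      violator_peak_mm = 3.5))
  sc <- motion_screen(pv)
  expect_identical(sc$kept, setdiff(1:10, 3L))
  expect_identical(sum(sc$log$excluded), 1L)

  # boundary: a peak of exactly 3.0 mm is kept ("greater than" is strict)
  pb <- make_panel(2, t_len = 40,
                   motion_spec = list(step_sd = 0.02, violator_subject = 1,
                                      violator_peak_mm = 3.0))
  expect_identical(motion_screen(pb)$kept, 1:2)

  bad <- panel
  bad$motion <- bad$motion[1:2]
  expect_error(motion_screen(bad), "Missing motion")
})

test_that("the nuisance design has 23 labeled columns with backward-difference derivatives", {
  t_len <- 30
  motion <- matrix(seq_len(t_len) * 0.01, t_len, 6) # linear ramps, slope 0.01
  wm <- matrix(rnorm(t_len * 5), t_len, 5)
  csf <- matrix(rnorm(t_len * 5), t_len, 5)
  nd <- build_nuisance(motion, wm, csf)
  expect_identical(ncol(nd), 23L)
  expect_identical(
    colnames(nd),
    c(paste0("motion", 1:6), paste0("dmotion", 1:6),
      paste0("wm", 1:5), paste0("csf", 1:5), "intercept")
  )
  expect_identical(unname(nd[1, paste0("dmotion", 1:6)]), rep(0, 6))
  expect_equal(unname(nd[-1, "dmotion1"]), rep(0.01, t_len - 1))
  # constant motion: derivatives vanish
  nd0 <- build_nuisance(matrix(1, t_len, 6), wm, csf)
  expect_identical(unname(nd0[, "dmotion3"]), rep(0, t_len))
  expect_error(build_nuisance(motion[1:10, ], wm, csf), "same number")
})

test_that("nuisance regression returns OLS residuals orthogonal to the design", {
  t_len <- 80
  nd <- withr::with_seed(5, build_nuisance(
    matrix(rnorm(t_len * 6, 0, 0.1), t_len, 6),
    matrix(rnorm(t_len * 5), t_len, 5), matrix(rnorm(t_len * 5), t_len, 5)
  ))
  # a series equal to a nuisance column is annihilated
  res <- regress_nuisance(cbind(nd[, "wm2"]), nd)
  expect_lt(max(abs(res)), 1e-10)

  # a series orthogonal to the design passes through unchanged
  y <- withr::with_seed(6, rnorm(t_len))
  y_perp <- qr.resid(qr(nd), y)
  expect_equal(regress_nuisance(cbind(y_perp), nd)[, 1], y_perp)

  # explicit normal-equations oracle and orthogonality
  series <- withr::with_seed(7, matrix(rnorm(t_len * 4), t_len, 4))
  res4 <- regress_nuisance(series, nd)
  beta <- solve(crossprod(nd), crossprod(nd, series))
  expect_equal(res4, series - nd %*% beta, ignore_attr = TRUE)
  expect_lt(max(abs(crossprod(nd, res4))), 1e-8 * t_len)

  expect_error(regress_nuisance(series[1:20, ], nd[1:20, ]), "T > K")
  rank_def <- cbind(nd, nd[, 1])
  expect_warning(regress_nuisance(series, rank_def), "rank deficient")
})

test_that("the ideal band-pass keeps in-band sinusoids and kills out-of-band power", {
  t_len <- 240
  tr <- 1.8
  tgrid <- (seq_len(t_len) - 1) * tr
  f_in <- 22 / (t_len * tr) # ~0.051 Hz, on an FFT bin inside the band
  f_out <- 86 / (t_len * tr) # ~0.199 Hz, outside
  x_in <- sin(2 * pi * f_in * tgrid)
  x_out <- sin(2 * pi * f_out * tgrid)
  amp <- function(x, k) 2 * Mod(fft(x)[k + 1]) / length(x)

  filtered <- bandpass_filter(cbind(x_in, x_out), tr_seconds = tr)
  expect_equal(amp(filtered[, 1], 22), amp(x_in, 22), tolerance = 0.01)
  expect_lt(max(abs(filtered[, 1] - x_in)), 1e-8)
  expect_lt(amp(filtered[, 2], 86), 0.01 * amp(x_out, 86))
  expect_lt(max(abs(filtered[, 2])), 1e-8)

  # constant series: DC is outside the band
  expect_lt(max(abs(bandpass_filter(matrix(5, t_len, 1), tr_seconds = tr))), 1e-10)

  expect_error(bandpass_filter(matrix(rnorm(64)), low_hz = 0.01, high_hz = 0.3,
                               tr_seconds = 1.8), "Nyquist")
  expect_error(bandpass_filter(matrix(rnorm(10)), tr_seconds = 1.8), "32 time points")
})

test_that("the butterworth band-pass behaves like a band filter", {
  skip_if_not_installed("signal")
  t_len <- 240
  tr <- 1.8
  tgrid <- (seq_len(t_len) - 1) * tr
  x_in <- sin(2 * pi * 0.05 * tgrid)
  x_out <- sin(2 * pi * 0.25 * tgrid)
  f <- bandpass_filter(cbind(x_in, x_out), tr_seconds = tr, method = "butterworth")
  expect_gt(sd(f[, 1]) / sd(x_in), 0.8)
  expect_lt(sd(f[, 2]) / sd(x_out), 0.1)
})

test_that("kendall_matrix is tau-b and matches the pair-count oracle", {
  x <- c(1, 2, 3)
  y <- c(1, 3, 2)
  tau <- kendall_matrix(cbind(a = x, b = y))
  expect_equal(tau["a", "b"], 1 / 3)
  expect_identical(tau, t(tau))
  expect_identical(unname(diag(tau)), c(1, 1))

  # monotone transform: tau = 1
  z <- exp(x)
  expect_equal(kendall_matrix(cbind(a = x, b = z))["a", "b"], 1)

  # tie-corrected brute force on random data with ties
  series <- withr::with_seed(8, matrix(sample(1:5, 40, replace = TRUE), 10, 4))
  colnames(series) <- paste0("r", 1:4)
  tau4 <- kendall_matrix(series)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_equal(tau4[i, j], bf_kendall(series[, i], series[, j]))
    }
  }

  const <- cbind(a = x, b = rep(2, 3))
  expect_error(kendall_matrix(const), "'b'")
  expect_error(kendall_matrix(cbind(x, y)[1:2, ]), "3 time points")
})

test_that("fisher transforms are exact inverses with clipping at |r| = 1", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  grid <- seq(-0.999, 0.999, by = 0.111)
  expect_equal(fisher_inv(fisher_z(grid)), grid, tolerance = 1e-12)
  expect_warning(z1 <- fisher_z(1), "clipped")
  expect_equal(suppressWarnings(fisher_z(1)), atanh(1 - 1e-7))
  expect_error(fisher_z(1.2), "<= 1")
})

test_that("group_average pools through Fisher z with unit diagonal", {
  m1 <- matrix(c(1, 0.3, 0.3, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  m2 <- matrix(c(1, 0.7, 0.7, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  avg <- group_average(list(m1, m2))
  expect_equal(avg["a", "b"], tanh((atanh(0.3) + atanh(0.7)) / 2))
  expect_identical(unname(diag(avg)), c(1, 1))

  # single subject passes through; k copies average to themselves
  expect_equal(group_average(list(m1)), connectivity_matrix(m1))
  expect_equal(group_average(list(m2, m2, m2)), connectivity_matrix(m2))
  expect_error(group_average(list(m1, matrix(1, 3, 3))), "same shape")
})

test_that("the full resting chain is deterministic and recovers block structure", {
  w <- gen_modular_matrix(modular_spec(16, c(8, 8), 0.7, 0.15, 0.03, seed = 12))
  panel <- gen_subject_panel(w, 8, t_len = 120, noise_sd = 0.4, seed = 13)
  r1 <- build_resting_matrix(panel)
  r2 <- build_resting_matrix(panel)
  expect_identical(r1, r2)
  expect_identical(r1$n_subjects_used, 8L)

  mods <- attr(w, "modules")
  same <- outer(mods, mods, `==`)
  ut <- upper.tri(r1$matrix)
  within <- r1$matrix[same & ut]
  between <- r1$matrix[!same & ut]
  se <- sqrt(var(within) / length(within) + var(between) / length(between))
  expect_gt(mean(within) - mean(between), 3 * se)
})

test_that("the group matrix is invariant to nuisance signal added to every ROI", {
  w <- gen_modular_matrix(modular_spec(10, c(5, 5), 0.6, 0.2, 0.05, seed = 14))
  panel <- gen_subject_panel(w, 3, t_len = 80, noise_sd = 0.3, seed = 15)
  base <- build_resting_matrix(panel)$matrix

  contaminated <- panel
  for (s in seq_along(panel$series)) {
    nuis_col <- panel$wm_eigs[[s]][, 2]
    contaminated$series[[s]] <- panel$series[[s]] + 50 * nuis_col
  }
  shifted <- build_resting_matrix(contaminated)$matrix
  expect_lt(max(abs(shifted - base)), 1e-6)
})
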