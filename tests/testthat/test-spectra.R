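test_that("intensity-averaged wavelength is the intensity-weighted mean", {
  # point mass: all weight at one wavelength
  s <- spectrum(c(300, 350, 400), c(0, 0, 5), probe = "fluorescence")
  expect_equal(intensity_averaged_wavelength(s), 400)

  # hand sum: (300 + 2*350 + 400) / 4
  s <- spectrum(c(300, 350, 400), c(1, 2, 1), probe = "fluorescence")
  expect_equal(intensity_averaged_wavelength(s), 350)

  # scale invariance and boundedness over generated spectra
  set.seed(42)
  for (i in 1:25) {
    wl <- sort(runif(20, 300, 450))
    iv <- runif(20)
    s1 <- spectrum(wl, iv, probe = "fluorescence")
    s2 <- spectrum(wl, iv * runif(1, 0.1, 50), probe = "fluorescence")
    lb <- intensity_averaged_wavelength(s1)
    expect_equal(intensity_averaged_wavelength(s2), lb)
    expect_gte(lb, min(wl))
    expect_lte(lb, max(wl))
  }
})

test_that("intensity-averaged wavelength rejects degenerate input", {
  z <- spectrum(c(300, 350), c(0, 0), probe = "fluorescence")
  expect_error(intensity_averaged_wavelength(z),
               class = "kinstab_degenerate_spectrum")
  neg <- spectrum(c(300, 350), c(1, -1), probe = "fluorescence")
  expect_error(intensity_averaged_wavelength(neg),
               class = "kinstab_invalid_signal")
  cd <- spectrum(c(210, 250), c(1, 1), probe = "farUV_CD")
  expect_error(intensity_averaged_wavelength(cd),
               class = "kinstab_invalid_spectrum")
})

test_that("mean residue ellipticity conversion is bilinear in geometry", {
  expect_equal(mean_residue_ellipticity(0, 1, 0.1), 0)
  # 10 mdeg at 1 mg/mL, 1 mm path, MRW 110
  expect_equal(mean_residue_ellipticity(10, 1, 0.1), 1100)
  # doubling concentration halves the result; MRE * c * l constant
  set.seed(7)
  for (i in 1:20) {
    th <- runif(1, -30, 30); cc <- runif(1, 0.1, 2); l <- runif(1, 0.05, 1)
    base <- mean_residue_ellipticity(th, cc, l)
    expect_equal(mean_residue_ellipticity(th, 2 * cc, l), base / 2)
    expect_equal(mean_residue_ellipticity(th, cc, l) * cc * l,
                 mean_residue_ellipticity(th, 1, 1) * 1 * 1)
  }
  expect_error(mean_residue_ellipticity(10, 0, 0.1),
               class = "kinstab_invalid_geometry")
  expect_error(mean_residue_ellipticity(10, 1, -1),
               class = "kinstab_invalid_geometry")
})

test_that("A280 concentration conversion matches assay working ranges", {
  expect_equal(concentration_from_a280(0, 44810, 41477), 0)
  # 0.13 AU with the MAPK1 absorptivity/mass gives ~0.120 mg/mL
  expect_equal(concentration_from_a280(0.13, 44810, 41477),
               0.13 / 44810 * 41477)
  expect_lt(abs(concentration_from_a280(0.13, 44810, 41477) - 0.120), 0.001)
  # 1.3 AU with the MAPK3 absorptivity/mass gives ~1.30 mg/mL
  expect_lt(abs(concentration_from_a280(1.3, 43320, 43222) - 1.30), 0.005)
  expect_error(concentration_from_a280(-0.1, 44810, 41477),
               class = "kinstab_invalid_signal")
})

test_that("SVD rank estimation counts independent spectral components", {
  for (k in 1:3) {
    res <- svd_analyze(make_k_state_series(k))
    expect_identical(res$estimated_rank, k)
    # trailing singular values are zero to machine tolerance
    expect_lt(max(res$singular_values[-seq_len(k)]),
              1e-12 * res$singular_values[1])
  }
  # identical spectra form a rank-1 matrix
  conds <- seq(0, 8, length.out = 6)
  same <- spectral_series(conds, lapply(conds,
                                        function(z) make_spectrum(basis_native)))
  expect_identical(svd_analyze(same)$estimated_rank, 1L)
})

test_that("SVD reconstruction is complete and truncation is exact", {
  ser <- make_k_state_series(3, noise_sd = 0.005, seed = 11)
  res <- svd_analyze(ser)
  A <- vapply(ser$spectra, function(s) s$values, numeric(length(far_uv_grid)))
  full <- res$basis_spectra %*% diag(res$singular_values) %*%
    t(res$amplitude_vectors)
  expect_lt(max(abs(full - A)) / max(abs(A)), 1e-10)
  # denoised series equals rank-truncated reconstruction exactly
  r <- res$estimated_rank
  trunc <- res$basis_spectra[, 1:r, drop = FALSE] %*%
    diag(res$singular_values[1:r], r) %*%
    t(res$amplitude_vectors[, 1:r, drop = FALSE])
  D <- vapply(res$denoised_series$spectra, function(s) s$values,
              numeric(length(far_uv_grid)))
  expect_identical(D, unname(trunc))
  expect_true(all(diff(res$singular_values) <= 0))
})

test_that("both rank policies agree on noisy low-rank series", {
  ser <- make_k_state_series(2, noise_sd = 0.01, seed = 3)
  expect_identical(svd_analyze(ser)$estimated_rank, 2L)
  expect_identical(svd_analyze(ser, policy = "autocorrelation")$estimated_rank,
                   2L)
})

test_that("spectral series constructor enforces a shared grid", {
  a <- spectrum(c(210, 220, 230), c(1, 2, 3), probe = "farUV_CD")
  b <- spectrum(c(211, 220, 230), c(1, 2, 3), probe = "farUV_CD")
  expect_error(spectral_series(c(0, 1), list(a, b)),
               class = "kinstab_grid_mismatch")
  expect_error(spectral_series(c(1, 0), list(a, a)),
               class = "kinstab_invalid_series")
})
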