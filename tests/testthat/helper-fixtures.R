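# Shared fixture builders. All synthetic inputs are built in code; Gaussian
# basis shapes stand in for CD band shapes in the SVD tests.

far_uv_grid <- seq(210, 250, by = 1)

basis_native <- exp(-((far_uv_grid - 222) / 8)^2)
basis_unfolded <- exp(-((far_uv_grid - 235) / 6)^2)
basis_intermediate <- sin((far_uv_grid - 210) / 40 * pi)

make_spectrum <- function(values, probe = "farUV_CD") {
  spectrum(far_uv_grid, values, probe = probe)
}

# spectral series whose columns mix k fixed basis spectra along a
# denaturation coordinate; rank is k by construction
make_k_state_series <- function(k, n_cond = 12, noise_sd = 0, seed = 1) {
  conds <- seq(0, 8, length.out = n_cond)
  f <- conds / max(conds)
  weights <- switch(as.character(k),
    "1" = cbind(rep(1, n_cond)),
    "2" = cbind(1 - f, f),
    "3" = {
      pI <- exp(-((conds - 4) / 1.5)^2)
      pU <- f * (1 - pI)
      cbind(pmax(1 - pI - pU, 0), pI, pU)
    },
    stop("k must be 1, 2 or 3")
  )
  bases <- list(basis_native, basis_intermediate, basis_unfolded)
  if (k == 2) bases <- list(basis_native, basis_unfolded)
  spectra <- lapply(seq_len(n_cond), function(i) {
    vals <- Reduce(`+`, Map(function(w, b) w * b, weights[i, ], bases[seq_len(k)]))
    if (noise_sd > 0) {
      vals <- vals + withr_seed_rnorm(seed * 1000 + i, length(vals), noise_sd)
    }
    make_spectrum(vals)
  })
  spectral_series(conds, spectra)
}

withr_seed_rnorm <- function(seed, n, sd) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  stats::rnorm(n, 0, sd)
}

# brute-force Boltzmann two-state oracle: unfolded population from the
# equilibrium constant, baselines interpolated by population
boltzmann_two_state <- function(x, dG, m, yN, sN, yU, sU, Tk = 283.15) {
  K <- exp(-(dG - m * x) / (gas_constant_kcal() * Tk))
  pU <- K / (1 + K)
  (yN + sN * x) * (1 - pU) + (yU + sU * x) * pU
}
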