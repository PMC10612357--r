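#' Construct a wavelength-indexed spectrum
#'
#' A `kinstab_spectrum` holds one wavelength scan from a spectroscopic probe:
#' far-UV circular dichroism (secondary structure), near-UV CD (tertiary
#' packing of aromatic residues) or intrinsic fluorescence emission.
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly
#'   increasing, all positive.
#' @param values Signal at each wavelength (mdeg for CD, arbitrary units for
#'   fluorescence); same length as `wavelengths`.
#' @param probe One of `"farUV_CD"`, `"nearUV_CD"`, `"fluorescence"`.
#' @param temperature Acquisition temperature in degrees C (optional).
#' @param sample_id Free-text sample identifier.
#' @param concentration Protein concentration in mg/mL (optional, > 0).
#' @param path_length Cuvette path length in cm (optional, > 0).
#'
#' @return An object of class `kinstab_spectrum`.
#' @export
spectrum <- function(wavelengths, values,
                     probe = c("farUV_CD", "nearUV_CD", "fluorescence"),
                     temperature = NA_real_, sample_id = "",
                     concentration = NULL, path_length = NULL) {
  probe <- match.arg(probe)
  stopifnot_numeric(wavelengths, "wavelengths")
  stopifnot_numeric(values, "values")
  if (length(wavelengths) < 2L || length(wavelengths) != length(values)) {
    ks_stop("wavelengths and values must have equal length >= 2",
            "invalid_spectrum")
  }
  if (any(wavelengths <= 0) || any(diff(wavelengths) <= 0)) {
    ks_stop("wavelengths must be strictly increasing and positive",
            "invalid_spectrum")
  }
  for (nm in c("concentration", "path_length")) {
    v <- get(nm)
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)) {
      ks_stop(sprintf("`%s`, when given, must be a single positive number", nm),
              "invalid_spectrum")
    }
  }
  structure(
    list(wavelengths = as.numeric(wavelengths), values = as.numeric(values),
         probe = probe, temperature = temperature, sample_id = sample_id,
         concentration = concentration, path_length = path_length),
    class = "kinstab_spectrum"
  )
}

#' @export
print.kinstab_spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s, %d points, %.1f-%.1f nm\n",
              x$probe, length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Construct a spectral series over a condition axis
#'
#' Bundles spectra recorded along an ordered condition axis (denaturant
#' concentration in M GdmCl, or temperature in degrees C) on one shared
#' wavelength grid, the unit analysed by [svd_analyze()].
#'
#' @param condition_values Numeric vector, nondecreasing, one per spectrum.
#' @param spectra List of [spectrum()] objects sharing an identical
#'   wavelength grid.
#'
#' @return An object of class `kinstab_spectral_series`.
#' @export
spectral_series <- function(condition_values, spectra) {
  stopifnot_numeric(condition_values, "condition_values")
  if (any(diff(condition_values) < 0)) {
    ks_stop("condition_values must be nondecreasing", "invalid_series")
  }
  if (!is.list(spectra) || length(spectra) < 2L ||
      length(spectra) != length(condition_values)) {
    ks_stop("need >= 2 spectra, one per condition value", "invalid_series")
  }
  if (!all(vapply(spectra, inherits, logical(1), "kinstab_spectrum"))) {
    ks_stop("spectra must all be kinstab_spectrum objects", "invalid_series")
  }
  grid <- spectra[[1L]]$wavelengths
  same <- vapply(spectra, function(s) {
    length(s$wavelengths) == length(grid) && all(s$wavelengths == grid)
  }, logical(1))
  if (!all(same)) {
    ks_stop("all member spectra must share an identical wavelength grid",
            "grid_mismatch")
  }
  structure(
    list(condition_values = as.numeric(condition_values), spectra = spectra,
         wavelengths = grid),
    class = "kinstab_spectral_series"
  )
}

series_matrix <- function(series) {
  vapply(series$spectra, function(s) s$values,
         numeric(length(series$wavelengths)))
}

#' Intensity-averaged emission wavelength
#'
#' Reduces a fluorescence emission spectrum to its intensity-weighted mean
#' wavelength, lambda-bar = sum(I_i * lambda_i) / sum(I_i). This integral
#' observable is robust to noise and reports shifts in the shape and position
#' of the tryptophan emission band, i.e. changes in tertiary environment.
#' (The source method is sometimes printed with the wavelength inverted,
#' sum(I_i / lambda_i) / sum(I_i); that form is dimensionally inconsistent
#' with a result in nm and is not used here.)
#'
#' @param spec A fluorescence [spectrum()]; all intensities must be
#'   nonnegative, at least one positive.
#'
#' @return Length-one numeric, nm; always within the scanned wavelength range.
#' @export
#'
#' @examples
#' s <- spectrum(c(300, 350, 400), c(1, 2, 1), probe = "fluorescence")
#' intensity_averaged_wavelength(s) # 350
intensity_averaged_wavelength <- function(spec) {
  if (!inherits(spec, "kinstab_spectrum")) {
    ks_stop("`spec` must be a kinstab_spectrum", "invalid_spectrum")
  }
  if (spec$probe != "fluorescence") {
    ks_stop("intensity-averaged wavelength is defined for fluorescence spectra",
            "invalid_spectrum")
  }
  if (any(spec$values < 0)) {
    ks_stop("negative fluorescence intensity", "invalid_signal")
  }
  total <- sum(spec$values)
  if (total == 0) {
    ks_stop("all-zero intensities: average wavelength undefined",
            "degenerate_spectrum")
  }
  sum(spec$values * spec$wavelengths) / total
}

#' Mean residue ellipticity
#'
#' Converts a raw CD signal (mdeg) to mean residue ellipticity,
#' `[theta] = theta * MRW / (10 * l * c)` in deg cm^2 dmol^-1, normalising
#' the signal per peptide bond so spectra of different proteins and
#' concentrations are comparable.
#'
#' @param theta Raw ellipticity in mdeg (may be a vector).
#' @param concentration Protein concentration in mg/mL, > 0.
#' @param path_length Cuvette path length in cm, > 0.
#' @param mean_residue_mass Mean residue molecular mass in g/mol; default 110,
#'   the standard value for a typical amino-acid composition.
#'
#' @return Mean residue ellipticity, deg cm^2 dmol^-1; linear in `theta`.
#' @export
#'
#' @examples
#' mean_residue_ellipticity(10, concentration = 1, path_length = 0.1) # 1100
mean_residue_ellipticity <- function(theta, concentration, path_length,
                                     mean_residue_mass = 110) {
  stopifnot_numeric(theta, "theta")
  ok <- function(v) is.numeric(v) && length(v) == 1L && !is.na(v) && v > 0
  if (!ok(concentration) || !ok(path_length)) {
    ks_stop("concentration and path_length must be single positive numbers",
            "invalid_geometry")
  }
  if (!ok(mean_residue_mass)) {
    ks_stop("mean_residue_mass must be a single positive number",
            "invalid_geometry")
  }
  theta * mean_residue_mass / (10 * path_length * concentration)
}

#' Protein concentration from absorbance at 280 nm
#'
#' Beer-Lambert conversion of A280 to mass concentration:
#' `c = a280 / (epsilon * l) * M`, with the molar concentration in M and the
#' result in mg/mL (g/L).
#'
#' @param a280 Absorbance at 280 nm (AU), >= 0.
#' @param molar_absorptivity Molar absorptivity at 280 nm, M^-1 cm^-1, > 0.
#' @param molecular_mass Protein molecular mass in Da, > 0.
#' @param path_length Path length in cm, default 1.0.
#'
#' @return Concentration in mg/mL.
#' @export
concentration_from_a280 <- function(a280, molar_absorptivity, molecular_mass,
                                    path_length = 1.0) {
  stopifnot_numeric(a280, "a280")
  if (any(a280 < 0)) ks_stop("negative absorbance", "invalid_signal")
  ok <- function(v) is.numeric(v) && length(v) == 1L && !is.na(v) && v > 0
  if (!ok(molar_absorptivity) || !ok(molecular_mass) || !ok(path_length)) {
    ks_stop("molar_absorptivity, molecular_mass and path_length must be positive",
            "invalid_geometry")
  }
  a280 / (molar_absorptivity * path_length) * molecular_mass
}

#' SVD component analysis of a spectral series
#'
#' Decomposes the wavelength-by-condition signal matrix by singular value
#' decomposition, estimates the number of independent spectral components,
#' and returns the rank-truncated (denoised) reconstruction. The component
#' count is the spectroscopic fingerprint of the number of thermodynamic
#' states populated along the series: two for a two-state transition, three
#' when an intermediate is populated.
#'
#' Two rank policies are available. `"singular_value"` (default) retains
#' components whose singular value exceeds `threshold_factor` times the
#' median of the trailing half of the singular spectrum (the noise floor),
#' with an absolute floor of `1e-8 * s1` so noiseless low-rank matrices are
#' not over-counted. `"autocorrelation"` retains components whose basis
#' spectrum (left singular vector) has non-centered lag-1 autocorrelation
#' above `autocorrelation_min`: signal components are smooth along the
#' wavelength axis, noise components oscillate.
#'
#' @param series A [spectral_series()].
#' @param policy Rank-selection policy, `"singular_value"` or
#'   `"autocorrelation"`.
#' @param threshold_factor Multiple of the trailing-half median singular value
#'   a component must exceed; default 5.
#' @param autocorrelation_min Minimum lag-1 autocorrelation for the
#'   autocorrelation policy; default 0.8.
#'
#' @return An object of class `kinstab_svd_result` with elements
#'   `singular_values` (nonincreasing), `basis_spectra` (left singular
#'   vectors, wavelengths x components), `amplitude_vectors` (right singular
#'   vectors, conditions x components), `estimated_rank`, `denoised_series`
#'   (a [spectral_series()] rebuilt from the first `estimated_rank`
#'   components) and `policy`.
#' @export
svd_analyze <- function(series, policy = c("singular_value", "autocorrelation"),
                        threshold_factor = 5, autocorrelation_min = 0.8) {
  policy <- match.arg(policy)
  if (!inherits(series, "kinstab_spectral_series")) {
    ks_stop("`series` must be a kinstab_spectral_series", "invalid_series")
  }
  A <- series_matrix(series)
  dec <- svd(A)
  s <- dec$d

  retained <- switch(policy,
    singular_value = {
      tail_half <- s[seq.int(max(1L, floor(length(s) / 2) + 1L), length(s))]
      thr <- max(threshold_factor * stats::median(tail_half), 1e-8 * s[1L])
      s > thr
    },
    autocorrelation = {
      # non-centered lag-1 autocorrelation of a unit vector: near 1 for
      # smooth (signal) vectors, near 0 or negative for noise vectors
      lag1 <- function(v) {
        d <- sum(v^2)
        if (d == 0) 0 else sum(v[-1L] * v[-length(v)]) / d
      }
      vapply(seq_along(s), function(k) {
        s[k] > 0 && lag1(dec$u[, k]) >= autocorrelation_min
      }, logical(1))
    }
  )
  rank <- sum(retained)
  if (s[1L] > 0) rank <- max(rank, 1L)

  denoised <- if (rank > 0) {
    dec$u[, seq_len(rank), drop = FALSE] %*%
      diag(s[seq_len(rank)], rank) %*%
      t(dec$v[, seq_len(rank), drop = FALSE])
  } else {
    matrix(0, nrow(A), ncol(A))
  }
  den_spectra <- lapply(seq_along(series$spectra), function(i) {
    s0 <- series$spectra[[i]]
    s0$values <- denoised[, i]
    s0
  })

  structure(
    list(singular_values = s,
         basis_spectra = dec$u,
         amplitude_vectors = dec$v,
         estimated_rank = as.integer(rank),
         denoised_series = spectral_series(series$condition_values, den_spectra),
         policy = policy),
    class = "kinstab_svd_result"
  )
}

#' @export
print.kinstab_svd_result <- function(x, ...) {
  cat(sprintf("<svd_result> estimated rank %d (%s policy)\n",
              x$estimated_rank, x$policy))
  cat("singular values:",
      paste(signif(utils::head(x$singular_values, 5), 3), collapse = ", "),
      if (length(x$singular_values) > 5) "...", "\n")
  invisible(x)
}
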