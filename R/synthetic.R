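# Seeded generators producing instrument-style datasets with the statistical
# structure the fitting stages assume. Every generator returns both the
# dataset and the generating truth, and identical seeds give identical
# output. The default noise model is homoscedastic Gaussian with standard
# deviation 2% of the noiseless signal span.

noise_sd_default <- function(signal, noise_sd) {
  if (!is.null(noise_sd)) return(noise_sd)
  0.02 * diff(range(signal))
}

#' Generate a two-state equilibrium unfolding series
#'
#' Evaluates the two-state linear extrapolation model ([two_state_signal()])
#' on a denaturant grid and adds i.i.d. Gaussian noise.
#'
#' @param dG_H2O,m True thermodynamic parameters (kcal/mol, kcal/mol/M).
#' @param yN,sN,yU,sU True baseline parameters.
#' @param denaturant Denaturant grid, M; default 0 to 8 in 0.25 M steps.
#' @param temperature Temperature, K; default 283.15.
#' @param noise_sd Gaussian noise SD in observable units; default 2% of the
#'   noiseless span; 0 gives the exact curve.
#' @param probe Observable label for the series.
#' @param seed Mandatory integer seed.
#'
#' @return A list with `series` (a [denaturation_series()]) and `truth`
#'   (named list of every generating parameter).
#' @export
gen_two_state_series <- function(dG_H2O, m, yN = 1, sN = 0, yU = 0, sU = 0,
                                 denaturant = seq(0, 8, by = 0.25),
                                 temperature = 283.15, noise_sd = NULL,
                                 probe = "CD222", seed) {
  clean <- two_state_signal(denaturant, dG_H2O, m, yN, sN, yU, sU,
                            temperature = temperature)
  sd_use <- noise_sd_default(clean, noise_sd)
  obs <- with_seed(seed, clean + stats::rnorm(length(clean), 0, sd_use))
  list(
    series = denaturation_series(denaturant, obs, probe = probe,
                                 temperature = temperature),
    truth = list(dG_H2O = dG_H2O, m = m, midpoint = dG_H2O / m,
                 yN = yN, sN = sN, yU = yU, sU = sU,
                 temperature = temperature, noise_sd = sd_use, seed = seed)
  )
}

#' Generate a three-state equilibrium unfolding series
#'
#' Forward model of [three_state_signal()] plus Gaussian noise.
#'
#' @param D50_IN,m_IN,D50_UI,m_UI,F_I,aN,bN,aU,bU True parameters (see
#'   [three_state_signal()]).
#' @inheritParams gen_two_state_series
#'
#' @return A list with `series` and `truth`.
#' @export
gen_three_state_series <- function(D50_IN, m_IN, D50_UI, m_UI, F_I,
                                   aN = 1, bN = 0, aU = 0, bU = 0,
                                   denaturant = seq(0, 8, by = 0.25),
                                   temperature = 283.15, noise_sd = NULL,
                                   probe = "CD222", seed) {
  clean <- three_state_signal(denaturant, D50_IN, m_IN, D50_UI, m_UI, F_I,
                              aN, bN, aU, bU, temperature = temperature)
  sd_use <- noise_sd_default(clean, noise_sd)
  obs <- with_seed(seed, clean + stats::rnorm(length(clean), 0, sd_use))
  list(
    series = denaturation_series(denaturant, obs, probe = probe,
                                 temperature = temperature),
    truth = list(D50_IN = D50_IN, m_IN = m_IN, D50_UI = D50_UI, m_UI = m_UI,
                 F_I = F_I, aN = aN, bN = bN, aU = aU, bU = bU,
                 temperature = temperature, noise_sd = sd_use, seed = seed)
  )
}

#' Generate a thermal melt scan
#'
#' Sum of one or two logistic transitions with linear baselines: the
#' derivative extremum of each logistic sits exactly at its center, so the
#' true apparent Tm values are the `tm` argument.
#'
#' @param tm True transition center(s), degrees C (length 1 or 2).
#' @param amplitude Transition amplitude(s), signal units; recycled.
#' @param width Transition width(s) (logistic scale parameter, degrees C);
#'   recycled; default 2.
#' @param baseline Intercept of the pre-transition baseline; default -20
#'   (a typical folded-protein ellipticity at 222 nm, mdeg scale).
#' @param baseline_slope Linear drift per degree C; default 0.
#' @param temperatures Scan grid, degrees C; default 20 to 90 every 0.5.
#' @param noise_sd Gaussian noise SD; default 2% of span; 0 for noiseless.
#' @param seed Mandatory integer seed.
#'
#' @return A list with `melt` (a [thermal_melt()]) and `truth`.
#' @export
gen_thermal_melt <- function(tm = 55, amplitude = 15, width = 2,
                             baseline = -20, baseline_slope = 0,
                             temperatures = seq(20, 90, by = 0.5),
                             noise_sd = NULL, seed) {
  np <- length(tm)
  amplitude <- rep_len(amplitude, np)
  width <- rep_len(width, np)
  clean <- baseline + baseline_slope * temperatures
  for (j in seq_len(np)) {
    clean <- clean + amplitude[j] / (1 + exp(-(temperatures - tm[j]) / width[j]))
  }
  sd_use <- noise_sd_default(clean, noise_sd)
  obs <- with_seed(seed, clean + stats::rnorm(length(clean), 0, sd_use))
  list(
    melt = thermal_melt(temperatures, obs),
    truth = list(tm = tm, amplitude = amplitude, width = width,
                 baseline = baseline, baseline_slope = baseline_slope,
                 noise_sd = sd_use, seed = seed)
  )
}

# Substrate depletion under Michaelis-Menten kinetics, integrated with lsoda.
integrate_depletion <- function(S0, Km, Vmax, times) {
  out <- deSolve::ode(
    y = c(S = S0), times = times,
    func = function(t, y, p) list(-p$Vmax * y[1L] / (p$Km + y[1L])),
    parms = list(Km = Km, Vmax = Vmax)
  )
  as.numeric(out[, "S"])
}

#' Generate a kinase assay progress curve
#'
#' Integrates substrate depletion dS/dt = -Vmax S / (Km + S), converts
#' product to fluorescence through the emitted calibration factor, and adds
#' Gaussian noise.
#'
#' @param Km,Vmax True Michaelis-Menten parameters (uM, uM/s).
#' @param S0 Initial substrate concentration, uM.
#' @param enzyme_nM Enzyme concentration, nM (metadata; Vmax already
#'   reflects it).
#' @param calibration AU per uM product; default 100.
#' @param times Sampling times, s; default 0 to 300 every 5.
#' @param temperature Assay temperature, degrees C.
#' @param noise_sd Gaussian noise SD in AU; default 2% of span; 0 exact.
#' @param seed Mandatory integer seed.
#'
#' @return A list with `curve` (a [progress_curve()]) and `truth`.
#' @export
gen_progress_curve <- function(Km, Vmax, S0, enzyme_nM, calibration = 100,
                               times = seq(0, 300, by = 5), temperature = 30,
                               noise_sd = NULL, seed) {
  S <- integrate_depletion(S0, Km, Vmax, times)
  product <- S0 - S
  clean <- product * calibration
  sd_use <- noise_sd_default(clean, noise_sd)
  obs <- with_seed(seed, clean + stats::rnorm(length(clean), 0, sd_use))
  list(
    curve = progress_curve(times, obs, substrate_conc = S0,
                           enzyme_conc = enzyme_nM,
                           temperature = temperature,
                           calibration = calibration),
    truth = list(Km = Km, Vmax = Vmax, S0 = S0, enzyme_nM = enzyme_nM,
                 calibration = calibration,
                 initial_rate = Vmax * S0 / (Km + S0),
                 noise_sd = sd_use, seed = seed)
  )
}

#' Generate initial-rate observations over a substrate span
#'
#' Direct Michaelis-Menten rates v = Vmax S / (Km + S) with Gaussian noise,
#' for [fit_michaelis_menten()].
#'
#' @param Km,Vmax True parameters.
#' @param substrate Substrate grid, uM; default 10 concentrations spanning
#'   0.069 to 40 uM, the span of the fluorogenic peptide assay.
#' @param temperature Degrees C; default 30.
#' @param noise_sd Gaussian noise SD in uM/s; default 2% of span; 0 exact.
#' @param seed Mandatory integer seed.
#'
#' @return A list with `points` (data frame of rate observations, negative
#'   noise excursions truncated at 0) and `truth`.
#' @export
gen_rate_points <- function(Km, Vmax,
                            substrate = exp(seq(log(0.069), log(40),
                                                length.out = 10)),
                            temperature = 30, noise_sd = NULL, seed) {
  clean <- Vmax * substrate / (Km + substrate)
  sd_use <- noise_sd_default(clean, noise_sd)
  v <- with_seed(seed, clean + stats::rnorm(length(clean), 0, sd_use))
  list(
    points = data.frame(substrate_conc = substrate, rate = pmax(v, 0),
                        temperature = temperature),
    truth = list(Km = Km, Vmax = Vmax, substrate = substrate,
                 noise_sd = sd_use, seed = seed)
  )
}

#' Generate an activity-versus-temperature profile
#'
#' Arrhenius activity k(T) = A exp(-Ea / (R T)) at and below the temperature
#' of maximal activity; above it the activity is multiplied by a logistic
#' inactivation factor 1 / (1 + exp((T - midpoint) / width)) so the profile
#' has an interior maximum on the grid at `tmax` while the ascending limb
#' remains exactly Arrhenius. The inactivation term is a fixture device only
#' -- it gives [find_tmax()] something to detect and is not a physical model
#' of thermal inactivation.
#'
#' @param Ea True activation energy, kcal/mol.
#' @param tmax Temperature of maximal activity on the grid, degrees C.
#' @param k_ref Rate at `t_ref` (sets the prefactor A); default 1.
#' @param t_ref Reference temperature for `k_ref`, degrees C; default 30.
#' @param temperatures Assay grid, degrees C; default
#'   `c(10, 15, 20, 25, 30, 35, 37, 40, 42, 45)`.
#' @param inactivation_midpoint Logistic midpoint, degrees C; default
#'   `tmax + 3`.
#' @param inactivation_width Logistic width, degrees C; default 1.
#' @param noise_sd Gaussian noise SD (rate units); default 2% of span; 0
#'   exact.
#' @param seed Mandatory integer seed.
#'
#' @return A list with `points` (data frame of rates by temperature) and
#'   `truth` (including the prefactor `A`).
#' @export
gen_temperature_activity <- function(Ea, tmax, k_ref = 1, t_ref = 30,
                                     temperatures = c(10, 15, 20, 25, 30,
                                                      35, 37, 40, 42, 45),
                                     inactivation_midpoint = tmax + 3,
                                     inactivation_width = 1,
                                     noise_sd = NULL, seed) {
  A <- k_ref / exp(-Ea / (R_KCAL * (t_ref + 273.15)))
  TK <- temperatures + 273.15
  arr <- A * exp(-Ea / (R_KCAL * TK))
  inact <- ifelse(
    temperatures <= tmax, 1,
    1 / (1 + exp((temperatures - inactivation_midpoint) /
                   inactivation_width)))
  clean <- arr * inact
  sd_use <- noise_sd_default(clean, noise_sd)
  v <- with_seed(seed, clean + stats::rnorm(length(clean), 0, sd_use))
  list(
    points = data.frame(substrate_conc = NA_real_, rate = pmax(v, 0),
                        temperature = temperatures),
    truth = list(Ea = Ea, A = A, tmax = tmax, k_ref = k_ref, t_ref = t_ref,
                 inactivation_midpoint = inactivation_midpoint,
                 inactivation_width = inactivation_width,
                 noise_sd = sd_use, seed = seed)
  )
}
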