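#' Construct a kinase assay progress curve
#'
#' Fluorescence at 490 nm versus time from a chelation-enhanced fluorescence
#' (ChEF) assay: phosphorylation of the sensor peptide increases emission,
#' so the early slope reports the phosphorylation rate. The
#' fluorescence-to-product calibration (AU per micromolar phosphopeptide) is
#' an explicit input because it is instrument- and batch-specific.
#'
#' @param time Seconds, strictly increasing from 0; 0-300 s typical.
#' @param fluorescence Signal at 490 nm, AU.
#' @param substrate_conc Sensor peptide concentration, micromolar.
#' @param enzyme_conc Active kinase concentration, nanomolar, > 0.
#' @param temperature Assay temperature, degrees C.
#' @param calibration AU per micromolar product, > 0.
#'
#' @return An object of class `kinstab_progress_curve`.
#' @export
progress_curve <- function(time, fluorescence, substrate_conc, enzyme_conc,
                           temperature = 30, calibration = 1) {
  stopifnot_numeric(time, "time")
  stopifnot_numeric(fluorescence, "fluorescence")
  if (length(time) < 3L || length(time) != length(fluorescence)) {
    ks_stop("need matched time/fluorescence vectors with >= 3 points",
            "invalid_curve")
  }
  if (time[1L] < 0 || any(diff(time) <= 0)) {
    ks_stop("time must be strictly increasing from 0", "invalid_curve")
  }
  ok <- function(v) is.numeric(v) && length(v) == 1L && !is.na(v) && v > 0
  if (!ok(calibration)) ks_stop("calibration must be > 0", "invalid_curve")
  if (!ok(enzyme_conc)) ks_stop("enzyme_conc must be > 0", "invalid_curve")
  if (!ok(substrate_conc)) ks_stop("substrate_conc must be > 0",
                                   "invalid_curve")
  structure(
    list(time = as.numeric(time), fluorescence = as.numeric(fluorescence),
         substrate_conc = substrate_conc, enzyme_conc = enzyme_conc,
         temperature = temperature, calibration = calibration),
    class = "kinstab_progress_curve"
  )
}

#' A single initial-rate observation
#'
#' @param substrate_conc Substrate concentration, micromolar.
#' @param rate Initial velocity, micromolar per second, >= 0.
#' @param temperature Degrees C.
#'
#' @return An object of class `kinstab_rate_point`.
#' @export
rate_point <- function(substrate_conc, rate, temperature = 30) {
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate < 0) {
    ks_stop("rate must be a single nonnegative number", "invalid_input")
  }
  structure(list(substrate_conc = substrate_conc, rate = rate,
                 temperature = temperature),
            class = "kinstab_rate_point")
}

rate_points_df <- function(points) {
  if (inherits(points, "kinstab_rate_point")) points <- list(points)
  if (is.data.frame(points)) {
    need <- c("substrate_conc", "rate", "temperature")
    if (!all(need %in% names(points))) {
      ks_stop("rate-point data frame needs substrate_conc, rate, temperature",
              "invalid_input")
    }
    return(points[need])
  }
  if (!all(vapply(points, inherits, logical(1), "kinstab_rate_point"))) {
    ks_stop("`points` must be rate_point objects or a data frame",
            "invalid_input")
  }
  data.frame(
    substrate_conc = vapply(points, `[[`, numeric(1), "substrate_conc"),
    rate = vapply(points, `[[`, numeric(1), "rate"),
    temperature = vapply(points, `[[`, numeric(1), "temperature")
  )
}

#' Initial rate from a progress curve
#'
#' Fits a straight line to the early, approximately linear phase of a
#' progress curve and converts the slope to micromolar product per second.
#' The window is the earliest span satisfying both limits: at most
#' `max_window` seconds and at most a `max_conversion` fraction of the
#' substrate converted (default 10%), so substrate depletion does not bias
#' the slope.
#'
#' @param curve A [progress_curve()].
#' @param max_window Longest window in seconds; default 60.
#' @param max_conversion Largest allowed fractional substrate conversion in
#'   the window; default 0.10.
#' @param noise_factor A slope more negative than `-noise_factor` standard
#'   errors is rejected as an invalid assay; default 3.
#'
#' @return A [rate_point()] carrying the curve's substrate concentration and
#'   temperature.
#' @export
initial_rate <- function(curve, max_window = 60, max_conversion = 0.10,
                         noise_factor = 3) {
  if (!inherits(curve, "kinstab_progress_curve")) {
    ks_stop("`curve` must be a kinstab_progress_curve", "invalid_curve")
  }
  tt <- curve$time
  product_uM <- (curve$fluorescence - curve$fluorescence[1L]) / curve$calibration
  keep <- tt <= (tt[1L] + max_window) &
    product_uM <= max_conversion * curve$substrate_conc
  # window must be a contiguous early span
  if (any(!keep)) keep[seq.int(which.min(keep), length(keep))] <- FALSE
  if (sum(keep) < 3L) {
    ks_stop("no linear early phase: fewer than 3 usable points in the window",
            "no_linear_phase")
  }
  fit <- stats::lm(product_uM[keep] ~ tt[keep])
  slope <- unname(stats::coef(fit)[2L])
  se <- suppressWarnings(summary(fit))$coefficients[2L, "Std. Error"]
  if (is.finite(se) && se > 0 && slope < -noise_factor * se) {
    ks_stop("negative rate beyond noise: assay invalid", "invalid_assay")
  }
  rate_point(curve$substrate_conc, max(slope, 0), curve$temperature)
}

#' Fit Michaelis-Menten kinetics
#'
#' Nonlinear least-squares fit of v = Vmax * S / (Km + S) to initial rates
#' at >= 5 substrate concentrations. Turnover and efficiency follow exactly
#' from the fit: kcat = Vmax / [E] (enzyme in micromolar, i.e. nM / 1000)
#' and kcat/Km = efficiency.
#'
#' @param points Rate observations: a list of [rate_point()] or a data frame
#'   with columns `substrate_conc`, `rate`, `temperature`.
#' @param enzyme_conc Enzyme concentration in nanomolar, > 0.
#'
#' @return A `kinstab_mm_fit` with `Km` (uM), `Vmax` (uM/s), `kcat` (1/s),
#'   `efficiency` (1/s/uM), `enzyme_conc` (nM) and `standard_errors`.
#'   A `kinstab_poor_saturation` warning is raised when the largest assayed
#'   substrate concentration is below the fitted Km.
#' @export
fit_michaelis_menten <- function(points, enzyme_conc) {
  df <- rate_points_df(points)
  if (nrow(df) < 5L) {
    ks_stop("need >= 5 substrate concentrations", "invalid_input")
  }
  if (!is.numeric(enzyme_conc) || length(enzyme_conc) != 1L ||
      is.na(enzyme_conc) || enzyme_conc <= 0) {
    ks_stop("enzyme_conc (nM) must be a single positive number",
            "invalid_input")
  }
  S <- df$substrate_conc
  v <- df$rate
  vmax0 <- max(v)
  km0 <- S[which.min(abs(v - vmax0 / 2))]
  if (km0 <= 0) km0 <- stats::median(S)
  res <- ks_nls(
    c(Vmax = vmax0, Km = km0),
    function(p) v - p[1L] * S / (p[2L] + S),
    lower = c(1e-12, 1e-9), upper = c(Inf, Inf),
    what = "Michaelis-Menten"
  )
  p <- res$par
  if (max(S) < p[["Km"]]) {
    ks_warn(sprintf(
      "poor saturation: max substrate %.3g uM is below fitted Km %.3g uM",
      max(S), p[["Km"]]), "poor_saturation")
  }
  e_uM <- enzyme_conc * 1e-3
  kcat <- p[["Vmax"]] / e_uM
  structure(
    list(Km = p[["Km"]], Vmax = p[["Vmax"]], kcat = kcat,
         efficiency = kcat / p[["Km"]], enzyme_conc = enzyme_conc,
         standard_errors = res$se, covariance = res$cov,
         temperature = df$temperature[1L], n = nrow(df)),
    class = "kinstab_mm_fit"
  )
}

#' @export
print.kinstab_mm_fit <- function(x, ...) {
  cat(sprintf(
    "<mm_fit> Km = %.3g uM, kcat = %.3g 1/s, kcat/Km = %.3g 1/s/uM\n",
    x$Km, x$kcat, x$efficiency))
  invisible(x)
}

#' Temperature of maximal activity
#'
#' Returns the temperature on the measured grid with the largest rate. No
#' interpolation is applied: the assay reports activity on discrete grid
#' temperatures only. A maximum on the grid edge raises a
#' `kinstab_edge_maximum` warning (the true optimum may lie outside the
#' scanned range); an exact tie is resolved to the lower temperature with a
#' `kinstab_tie` warning.
#'
#' @param points Rate observations over >= 4 temperatures (list of
#'   [rate_point()] or data frame).
#'
#' @return The grid temperature of maximal activity, degrees C.
#' @export
find_tmax <- function(points) {
  df <- rate_points_df(points)
  df <- df[order(df$temperature), ]
  if (nrow(df) < 4L) ks_stop("need >= 4 temperatures", "invalid_input")
  best <- which(df$rate == max(df$rate))
  if (length(best) > 1L) {
    ks_warn("tied maximal rates: reporting the lower temperature", "tie")
    best <- best[1L]
  }
  if (best == 1L || best == nrow(df)) {
    ks_warn("maximal rate at the edge of the temperature grid",
            "edge_maximum")
  }
  df$temperature[best]
}

#' Fit the Arrhenius activation energy
#'
#' Nonlinear least-squares fit of k = A * exp(-Ea / (R T)) over the
#' ascending limb of the activity-temperature profile, i.e. only points at
#' or below the temperature of maximal activity `tmax` are fitted (points
#' above `tmax` reflect inactivation, not the catalytic barrier, and are
#' excluded, never silently fitted). Temperatures are converted to kelvin;
#' R = 1.987e-3 kcal/mol/K, so Ea is in kcal/mol.
#'
#' @param points Rate observations over temperature (list of [rate_point()]
#'   or data frame); at least 3 points with positive rate at T <= `tmax`.
#' @param tmax Temperature of maximal activity, degrees C (see
#'   [find_tmax()]).
#'
#' @return A `kinstab_arrhenius_fit` with `Ea` (kcal/mol), `A` (1/s),
#'   `Tmax`, `fit_temperatures` and `standard_error_Ea`.
#' @export
fit_arrhenius <- function(points, tmax) {
  df <- rate_points_df(points)
  use <- df$temperature <= tmax & df$rate > 0
  df <- df[use, ]
  if (nrow(df) < 3L) {
    ks_stop("fewer than 3 usable points at or below tmax",
            "insufficient_range")
  }
  TK <- df$temperature + 273.15
  k <- df$rate
  # log-linear start values
  ll <- stats::lm(log(k) ~ I(1 / TK))
  Ea0 <- -unname(stats::coef(ll)[2L]) * R_KCAL
  A0 <- exp(unname(stats::coef(ll)[1L]))
  res <- ks_nls(
    c(A = A0, Ea = max(Ea0, 0.1)),
    function(p) k - p[1L] * exp(-p[2L] / (R_KCAL * TK)),
    lower = c(1e-300, 1e-6), upper = c(Inf, Inf),
    what = "Arrhenius"
  )
  p <- res$par
  structure(
    list(Ea = p[["Ea"]], A = p[["A"]], Tmax = tmax,
         fit_temperatures = sort(df$temperature),
         standard_error_Ea = unname(res$se["Ea"]),
         n = nrow(df)),
    class = "kinstab_arrhenius_fit"
  )
}

#' @export
print.kinstab_arrhenius_fit <- function(x, ...) {
  cat(sprintf("<arrhenius_fit> Ea = %.2f kcal/mol over %d temperatures <= Tmax %.1f degC\n",
              x$Ea, x$n, x$Tmax))
  invisible(x)
}

#' Log-linear Arrhenius estimate
#'
#' Ordinary least squares of log(k) on 1/T, the linearised form of the
#' Arrhenius law. Kept alongside [fit_arrhenius()] as an independent check:
#' on noiseless data the two estimates of Ea coincide.
#'
#' @inheritParams fit_arrhenius
#'
#' @return A list with `Ea` (kcal/mol) and `A` (1/s).
#' @export
arrhenius_loglinear <- function(points, tmax) {
  df <- rate_points_df(points)
  df <- df[df$temperature <= tmax & df$rate > 0, ]
  if (nrow(df) < 2L) {
    ks_stop("fewer than 2 usable points at or below tmax",
            "insufficient_range")
  }
  TK <- df$temperature + 273.15
  co <- stats::coef(stats::lm(log(df$rate) ~ I(1 / TK)))
  list(Ea = -unname(co[2L]) * R_KCAL, A = exp(unname(co[1L])))
}
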