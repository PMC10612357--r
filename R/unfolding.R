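#' Construct an equilibrium denaturation series
#'
#' One observable (far-UV CD ellipticity at 222 nm, or the intensity-averaged
#' fluorescence emission wavelength) measured at increasing guanidinium
#' chloride concentrations at constant temperature, the input to
#' [fit_two_state()] and [fit_three_state()].
#'
#' @param denaturant GdmCl concentrations in M, nonnegative, nondecreasing,
#'   at least 8 points (the transition plus both baselines must be sampled).
#' @param observable Signal at each concentration (deg cm^2 dmol^-1 for
#'   CD222, nm for avg_wavelength).
#' @param probe `"CD222"` or `"avg_wavelength"`.
#' @param temperature Temperature in K (> 0); default 283.15 (10 degrees C,
#'   the standard acquisition temperature for these experiments).
#' @param replicate_id Free-text replicate label.
#'
#' @return An object of class `kinstab_denaturation_series`.
#' @export
denaturation_series <- function(denaturant, observable,
                                probe = c("CD222", "avg_wavelength"),
                                temperature = 283.15, replicate_id = "r1") {
  probe <- match.arg(probe)
  stopifnot_numeric(denaturant, "denaturant")
  stopifnot_numeric(observable, "observable")
  if (length(denaturant) < 8L || length(denaturant) != length(observable)) {
    ks_stop("need matched denaturant/observable vectors with >= 8 points",
            "invalid_series")
  }
  if (any(denaturant < 0) || any(diff(denaturant) < 0)) {
    ks_stop("denaturant concentrations must be nonnegative and nondecreasing",
            "invalid_series")
  }
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      is.na(temperature) || temperature <= 0) {
    ks_stop("temperature must be a single positive value in K",
            "invalid_series")
  }
  structure(
    list(denaturant = as.numeric(denaturant),
         observable = as.numeric(observable),
         probe = probe, temperature = temperature,
         replicate_id = as.character(replicate_id)),
    class = "kinstab_denaturation_series"
  )
}

#' Two-state linear extrapolation model signal
#'
#' Evaluates the observable predicted by the two-state (N <-> U) linear
#' extrapolation model with sloping baselines:
#' \deqn{y(x) = \frac{y_N + s_N x + (y_U + s_U x) K(x)}{1 + K(x)},\quad
#'       K(x) = \exp\!\big(-(\Delta G_{H2O} - m x)/(RT)\big)}
#' where `x` is the denaturant concentration in M. The unfolding free energy
#' is assumed linear in denaturant, `dG(x) = dG_H2O - m*x`, so the transition
#' midpoint is `dG_H2O / m` ([midpoint_from_lem()]).
#'
#' @param x Denaturant concentration(s), M, >= 0.
#' @param dG_H2O Unfolding free energy in water, kcal/mol.
#' @param m Denaturant dependence of dG, kcal/mol/M.
#' @param yN,sN Native baseline intercept and slope.
#' @param yU,sU Unfolded baseline intercept and slope.
#' @param temperature Temperature in K; default 283.15.
#'
#' @return Predicted observable, same length as `x`.
#' @export
#'
#' @examples
#' # equal populations at the midpoint, flat baselines:
#' two_state_signal(2.5, dG_H2O = 2.5, m = 1, yN = 1, sN = 0, yU = 0, sU = 0)
two_state_signal <- function(x, dG_H2O, m, yN, sN, yU, sU,
                             temperature = 283.15) {
  if (any(x < 0)) ks_stop("denaturant concentration must be >= 0",
                          "invalid_input")
  RT <- R_KCAL * temperature
  K <- exp(-(dG_H2O - m * x) / RT)
  (yN + sN * x + (yU + sU * x) * K) / (1 + K)
}

#' Transition midpoint from the linear extrapolation model
#'
#' The denaturant concentration at which native and unfolded states are
#' equipopulated: `[GdmCl]_0.5 = dG_H2O / m`.
#'
#' @param dG_H2O Unfolding free energy in water, kcal/mol.
#' @param m Denaturant dependence, kcal/mol/M, > 0.
#'
#' @return Midpoint concentration in M.
#' @export
#'
#' @examples
#' midpoint_from_lem(2.51, 0.91) # 2.76 M
midpoint_from_lem <- function(dG_H2O, m) {
  stopifnot_numeric(dG_H2O, "dG_H2O")
  stopifnot_numeric(m, "m")
  if (any(m <= 0)) ks_stop("m must be positive", "invalid_slope")
  dG_H2O / m
}

# Initial parameter guesses shared by the unfolding fitters: baselines from
# linear fits to the first/last 15% of points, transition midpoint(s) from
# extrema of a smoothed first derivative.
init_baselines <- function(x, y) {
  n <- length(x)
  k <- max(2L, ceiling(0.15 * n))
  lo <- seq_len(k)
  hi <- seq.int(n - k + 1L, n)
  fit_or_flat <- function(idx) {
    if (length(unique(x[idx])) < 2L) c(mean(y[idx]), 0)
    else stats::coef(stats::lm(y[idx] ~ x[idx]))
  }
  cn <- fit_or_flat(lo)
  cu <- fit_or_flat(hi)
  list(yN = unname(cn[1]), sN = unname(cn[2]),
       yU = unname(cu[1]), sU = unname(cu[2]))
}

smoothed_derivative_peaks <- function(x, y, n_peaks = 1L) {
  # derivative on midpoints, then a 3-point moving average
  dx <- diff(x)
  dx[dx == 0] <- min(dx[dx > 0], 1e-6)
  d <- diff(y) / dx
  if (length(d) >= 3L) d <- stats::filter(d, rep(1 / 3, 3), sides = 2)
  d[is.na(d)] <- 0
  xm <- (x[-1L] + x[-length(x)]) / 2
  mag <- abs(as.numeric(d))
  peaks <- order(mag, decreasing = TRUE)
  sel <- integer(0)
  for (p in peaks) {
    if (all(abs(xm[p] - xm[sel]) > diff(range(x)) / 6)) sel <- c(sel, p)
    if (length(sel) == n_peaks) break
  }
  sort(xm[sel])
}

#' Fit the two-state linear extrapolation model
#'
#' Nonlinear least-squares fit of [two_state_signal()] to one or more
#' denaturation series, estimating `dG_H2O`, `m` and the four baseline
#' parameters. With `share_m = TRUE`, a single m value is estimated jointly
#' across all series (global fit across replicates of one probe) while all
#' other parameters remain per-series.
#'
#' @param series A [denaturation_series()] or a list of them.
#' @param share_m Estimate one common m across all series; default `FALSE`.
#' @param temperature Temperature in K; defaults to the series' own value.
#'
#' @return A `kinstab_two_state_fit` (or a list of them, one per input
#'   series, each reporting the shared m when `share_m`), with elements
#'   `dG_H2O`, `m`, `midpoint` (= dG_H2O/m exactly), `yN`, `sN`, `yU`, `sU`,
#'   `standard_errors`, `covariance`, `temperature`, `convergence`.
#' @export
fit_two_state <- function(series, share_m = FALSE, temperature = NULL) {
  single <- inherits(series, "kinstab_denaturation_series")
  ser_list <- if (single) list(series) else series
  if (!all(vapply(ser_list, inherits, logical(1),
                  "kinstab_denaturation_series"))) {
    ks_stop("`series` must be denaturation_series objects", "invalid_series")
  }

  if (!share_m || length(ser_list) == 1L) {
    fits <- lapply(ser_list, fit_two_state_one, temperature = temperature)
    return(if (single) fits[[1L]] else fits)
  }
  fit_two_state_shared(ser_list, temperature)
}

check_bracketing <- function(x, dG, m, temperature) {
  RT <- R_KCAL * temperature
  pN <- function(xx) 1 / (1 + exp(-(dG - m * xx) / RT))
  if (pN(min(x)) < 0.7 || (1 - pN(max(x))) < 0.7) {
    ks_stop(paste0("transition not bracketed: the series lacks a native or ",
                   "unfolded plateau (fitted midpoint ",
                   sprintf("%.2f", dG / m), " M on range [",
                   sprintf("%.2f", min(x)), ", ", sprintf("%.2f", max(x)),
                   "] M)"), "unbracketed_transition")
  }
  invisible(TRUE)
}

fit_two_state_one <- function(ser, temperature = NULL) {
  Tk <- if (is.null(temperature)) ser$temperature else temperature
  x <- ser$denaturant
  y <- ser$observable
  bl <- init_baselines(x, y)
  mid0 <- smoothed_derivative_peaks(x, y, 1L)
  if (length(mid0) == 0L) mid0 <- stats::median(x)
  m0 <- 1.5
  start <- c(dG_H2O = m0 * mid0, m = m0,
             yN = bl$yN, sN = bl$sN, yU = bl$yU, sU = bl$sU)
  res <- ks_nls(
    start,
    function(p) y - two_state_signal(x, p[1L], p[2L], p[3L], p[4L],
                                     p[5L], p[6L], temperature = Tk),
    lower = c(-Inf, 1e-6, -Inf, -Inf, -Inf, -Inf),
    upper = c(Inf, 20, Inf, Inf, Inf, Inf),
    what = "two-state"
  )
  p <- res$par
  check_bracketing(x, p[["dG_H2O"]], p[["m"]], Tk)

  structure(
    list(dG_H2O = p[["dG_H2O"]], m = p[["m"]],
         midpoint = p[["dG_H2O"]] / p[["m"]],
         yN = p[["yN"]], sN = p[["sN"]], yU = p[["yU"]], sU = p[["sU"]],
         standard_errors = res$se, covariance = res$cov,
         temperature = Tk, probe = ser$probe,
         replicate_id = ser$replicate_id,
         residual_ss = res$deviance,
         n = length(x), shared_m = FALSE,
         convergence = res$converged),
    class = "kinstab_two_state_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fit_two_state_shared <- function(ser_list, temperature = NULL) {
  ns <- length(ser_list)
  Tk <- vapply(ser_list, function(s) {
    if (is.null(temperature)) s$temperature else temperature
  }, numeric(1))

  starts <- lapply(ser_list, function(ser) {
    bl <- init_baselines(ser$denaturant, ser$observable)
    mid0 <- smoothed_derivative_peaks(ser$denaturant, ser$observable, 1L)
    if (length(mid0) == 0L) mid0 <- stats::median(ser$denaturant)
    c(dG_H2O = 1.5 * mid0, yN = bl$yN, sN = bl$sN, yU = bl$yU, sU = bl$sU)
  })
  par0 <- c(m = 1.5, unlist(starts))

  unpack <- function(par) {
    m <- par[1L]
    per <- matrix(par[-1L], nrow = 5L)
    list(m = m, per = per)
  }
  resid_fun <- function(par) {
    u <- unpack(par)
    unlist(lapply(seq_len(ns), function(i) {
      p <- u$per[, i]
      ser_list[[i]]$observable -
        two_state_signal(ser_list[[i]]$denaturant, p[1L], u$m,
                         p[2L], p[3L], p[4L], p[5L], temperature = Tk[i])
    }))
  }
  res <- ks_nls(par0, resid_fun,
                lower = c(1e-6, rep(-Inf, 5L * ns)),
                upper = c(20, rep(Inf, 5L * ns)),
                what = "shared-m global")
  u <- unpack(res$par)
  cov <- res$cov
  se_all <- if (!is.null(cov)) sqrt(pmax(diag(cov), 0)) else
    rep(NA_real_, length(res$par))

  lapply(seq_len(ns), function(i) {
    p <- u$per[, i]
    idx <- c(1L, 1L + (i - 1L) * 5L + 1:5)
    se <- stats::setNames(se_all[idx][c(2, 1, 3, 4, 5, 6)],
                          c("dG_H2O", "m", "yN", "sN", "yU", "sU"))
    check_bracketing(ser_list[[i]]$denaturant, p[1L], u$m, Tk[i])
    structure(
      list(dG_H2O = unname(p[1L]), m = unname(u$m),
           midpoint = unname(p[1L] / u$m),
           yN = unname(p[2L]), sN = unname(p[3L]),
           yU = unname(p[4L]), sU = unname(p[5L]),
           standard_errors = se,
           covariance = if (is.null(cov)) NULL else cov[idx, idx],
           temperature = Tk[i], probe = ser_list[[i]]$probe,
           replicate_id = ser_list[[i]]$replicate_id,
           residual_ss = res$deviance, n = length(ser_list[[i]]$denaturant),
           shared_m = TRUE, convergence = TRUE),
      class = "kinstab_two_state_fit"
    )
  })
}

#' @export
print.kinstab_two_state_fit <- function(x, ...) {
  cat(sprintf(
    "<two_state_fit> dG_H2O = %.2f kcal/mol, m = %.2f kcal/mol/M, midpoint = %.2f M%s\n",
    x$dG_H2O, x$m, x$midpoint, if (x$shared_m) " (shared m)" else ""))
  invisible(x)
}

#' Three-state (N <-> I <-> U) unfolding signal
#'
#' Evaluates the observable for a three-state equilibrium with a populated
#' intermediate and linear native/unfolded baselines:
#' \deqn{F(x) = \frac{F_N + e_1 (F_I + F_U e_2)}{1 + e_1 (1 + e_2)}}
#' with \eqn{e_1 = \exp(m_{IN}(x - D50_{IN})/RT)},
#' \eqn{e_2 = \exp(m_{UI}(x - D50_{UI})/RT)},
#' \eqn{F_N = a_N + b_N x}, \eqn{F_U = a_U + b_U x} and constant \eqn{F_I}.
#' `D50_IN`/`m_IN` are the midpoint and m value of the N->I step and
#' `D50_UI`/`m_UI` those of the I->U step.
#'
#' @param x Denaturant concentration(s), M, >= 0.
#' @param D50_IN,m_IN Midpoint (M) and m value (kcal/mol/M) of the first
#'   transition.
#' @param D50_UI,m_UI Midpoint and m value of the second transition.
#' @param F_I Observable of the intermediate state (constant).
#' @param aN,bN Native baseline intercept and slope.
#' @param aU,bU Unfolded baseline intercept and slope.
#' @param temperature Temperature in K; default 283.15.
#'
#' @return Predicted observable, same length as `x`.
#' @export
three_state_signal <- function(x, D50_IN, m_IN, D50_UI, m_UI, F_I,
                               aN, bN, aU, bU, temperature = 283.15) {
  if (any(x < 0)) ks_stop("denaturant concentration must be >= 0",
                          "invalid_input")
  RT <- R_KCAL * temperature
  e1 <- exp(m_IN * (x - D50_IN) / RT)
  e2 <- exp(m_UI * (x - D50_UI) / RT)
  FN <- aN + bN * x
  FU <- aU + bU * x
  (FN + e1 * (F_I + FU * e2)) / (1 + e1 * (1 + e2))
}

#' Fit the three-state intermediate unfolding model
#'
#' Nonlinear least-squares fit of [three_state_signal()] (9 parameters:
#' two midpoint/m pairs, the intermediate signal F_I and two linear
#' baselines) to a denaturation series exhibiting a non-two-state shape.
#'
#' Initialisation: baselines from the first/last 15% of points, the two
#' midpoints from the two largest extrema of a smoothed first derivative
#' (falling back to the 1/3 and 2/3 quantiles of the denaturant range),
#' m values started at 2 kcal/mol/M, F_I at the observable nearest the
#' mid-plateau. m values are bounded in (0, 20].
#'
#' @param series A [denaturation_series()].
#' @param temperature Temperature in K; defaults to the series' value.
#'
#' @return A `kinstab_three_state_fit` with the 9 parameters,
#'   `standard_errors`, `covariance` and convergence diagnostics. A warning
#'   of class `kinstab_boundary_fit` is raised if an m value sits at its
#'   bound.
#' @export
fit_three_state <- function(series, temperature = NULL) {
  if (!inherits(series, "kinstab_denaturation_series")) {
    ks_stop("`series` must be a denaturation_series", "invalid_series")
  }
  Tk <- if (is.null(temperature)) series$temperature else temperature
  x <- series$denaturant
  y <- series$observable
  bl <- init_baselines(x, y)
  mids <- smoothed_derivative_peaks(x, y, 2L)
  rng <- range(x)
  if (length(mids) < 2L) {
    mids <- rng[1L] + diff(rng) * c(1, 2) / 3
  }
  # F_I: observable nearest the midpoint between the two transitions
  xm <- mean(mids)
  F_I0 <- y[which.min(abs(x - xm))]

  start <- c(D50_IN = mids[1L], m_IN = 2, D50_UI = mids[2L], m_UI = 2,
             F_I = F_I0, aN = bl$yN, bN = bl$sN, aU = bl$yU, bU = bl$sU)
  res <- ks_nls(
    start,
    function(p) y - three_state_signal(x, p[1L], p[2L], p[3L], p[4L], p[5L],
                                       p[6L], p[7L], p[8L], p[9L],
                                       temperature = Tk),
    lower = c(0, 1e-6, 0, 1e-6, -Inf, -Inf, -Inf, -Inf, -Inf),
    upper = c(max(x) * 2, 20, max(x) * 2, 20, Inf, Inf, Inf, Inf, Inf),
    maxiter = 1000, what = "three-state"
  )
  p <- res$par
  if (any(abs(p[c("m_IN", "m_UI")] - 20) < 1e-6) ||
      any(p[c("m_IN", "m_UI")] <= 2e-6)) {
    ks_warn("an m value sits at its bound; parameters are unreliable",
            "boundary_fit")
  }

  structure(
    c(as.list(p),
      list(standard_errors = res$se, covariance = res$cov,
           temperature = Tk, probe = series$probe,
           replicate_id = series$replicate_id,
           residual_ss = res$deviance, n = length(x),
           convergence = res$converged)),
    class = "kinstab_three_state_fit"
  )
}

#' @export
print.kinstab_three_state_fit <- function(x, ...) {
  cat(sprintf(
    "<three_state_fit> D50(I-N) = %.2f M (m %.2f), D50(U-I) = %.2f M (m %.2f)\n",
    x$D50_IN, x$m_IN, x$D50_UI, x$m_UI))
  invisible(x)
}

aicc_from_rss <- function(rss, n, k, rss_floor = 0) {
  # k model parameters + 1 for the residual variance; the floor keeps the
  # comparison meaningful on (near-)noiseless data, where both models reach
  # machine-precision residuals and log(RSS) differences are arbitrary
  rss <- max(rss, rss_floor)
  kk <- k + 1
  aic <- n * log(rss / n) + 2 * kk
  if (n - kk - 1 > 0) aic + 2 * kk * (kk + 1) / (n - kk - 1) else aic
}

#' Choose between two-state and three-state unfolding models
#'
#' Fits both models to a series and selects by corrected AIC, with a
#' parsimony tie-break (a three-state model must improve AICc by more than
#' `delta_aicc` to be chosen) and an override: an SVD component count of 3
#' or more ([svd_analyze()]) forces the three-state model, since a third
#' independent spectral component is direct evidence of a populated
#' intermediate.
#'
#' @param series A [denaturation_series()].
#' @param svd_hint Optional integer, the estimated SVD rank of the matching
#'   spectral series.
#' @param temperature Temperature in K; defaults to the series' value.
#' @param delta_aicc Minimum AICc improvement required of the three-state
#'   model; default 2.
#'
#' @return A `kinstab_model_selection` with `chosen` (`"two_state"` or
#'   `"three_state"`), `criterion_values` (named AICc), `svd_rank_hint`,
#'   and the two fits (`NULL` where a fit failed).
#' @export
select_model <- function(series, svd_hint = NULL, temperature = NULL,
                         delta_aicc = 2) {
  f2 <- tryCatch(fit_two_state(series, temperature = temperature),
                 kinstab_error = function(e) NULL)
  f3 <- tryCatch(suppressWarnings(
    fit_three_state(series, temperature = temperature)),
    kinstab_error = function(e) NULL)
  if (is.null(f2) && is.null(f3)) {
    ks_stop("both unfolding fits failed", "no_model")
  }

  floor_rss <- (1e-8 * diff(range(series$observable)))^2 *
    length(series$observable)
  crit <- c(
    two_state = if (!is.null(f2))
      aicc_from_rss(f2$residual_ss, f2$n, 6L, floor_rss) else Inf,
    three_state = if (!is.null(f3))
      aicc_from_rss(f3$residual_ss, f3$n, 9L, floor_rss) else Inf
  )
  chosen <- if (!is.null(svd_hint) && !is.na(svd_hint) && svd_hint >= 3 &&
                !is.null(f3)) {
    "three_state"
  } else if (crit[["two_state"]] - crit[["three_state"]] > delta_aicc) {
    "three_state"
  } else {
    "two_state"
  }
  if (chosen == "two_state" && is.null(f2)) chosen <- "three_state"

  structure(
    list(chosen = chosen, criterion_values = crit,
         svd_rank_hint = svd_hint,
         two_state = f2, three_state = f3),
    class = "kinstab_model_selection"
  )
}

#' @export
print.kinstab_model_selection <- function(x, ...) {
  cat(sprintf("<model_selection> chosen: %s (AICc two=%.1f, three=%.1f)\n",
              x$chosen, x$criterion_values[["two_state"]],
              x$criterion_values[["three_state"]]))
  invisible(x)
}
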