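#' Construct a thermal melt scan
#'
#' Ellipticity at 222 nm tracked while heating, typically 20 to 90 degrees C
#' at 1 degree/min sampled every 0.5 degrees. Because these melts are
#' irreversible, only apparent melting temperatures are extracted
#' ([melting_temperatures()]); no van't Hoff thermodynamics are attempted.
#'
#' @param temperatures Degrees C, strictly increasing, >= 20 points.
#' @param ellipticity222 Signal at 222 nm (mdeg or mean residue ellipticity).
#' @param heating_rate Degrees C per minute; default 1.
#' @param sample_id Free-text sample label.
#'
#' @return An object of class `kinstab_thermal_melt`.
#' @export
thermal_melt <- function(temperatures, ellipticity222, heating_rate = 1,
                         sample_id = "") {
  stopifnot_numeric(temperatures, "temperatures")
  stopifnot_numeric(ellipticity222, "ellipticity222")
  if (length(temperatures) < 20L ||
      length(temperatures) != length(ellipticity222)) {
    ks_stop("need matched vectors with >= 20 points", "invalid_scan")
  }
  if (any(diff(temperatures) <= 0)) {
    ks_stop("temperatures must be strictly increasing", "invalid_scan")
  }
  structure(
    list(temperatures = as.numeric(temperatures),
         ellipticity222 = as.numeric(ellipticity222),
         heating_rate = heating_rate, sample_id = as.character(sample_id)),
    class = "kinstab_thermal_melt"
  )
}

#' Apparent melting temperatures from the derivative of a thermal scan
#'
#' Estimates d(theta)/dT with a moving-polynomial (Savitzky-Golay) first
#' derivative filter and reports the temperatures of all derivative extrema
#' whose topographic prominence (height above the connecting col, which
#' discounts noise bumps riding on a transition shoulder) exceeds the
#' threshold:
#' one Tm for a cooperative monophasic melt, two for a biphasic melt with a
#' populated intermediate. Peak positions are refined by parabolic
#' interpolation around the discrete maximum, so Tm resolution is finer than
#' the grid step. The result is invariant to affine transformation of the
#' signal (the dominant derivative sign orients the search).
#'
#' @param melt A [thermal_melt()].
#' @param smoothing_window Width of the derivative-filter window in degrees
#'   C; default 5. Internally rounded to an odd number of grid points >= 5.
#'   Narrower windows resolve closely spaced transitions but admit noise
#'   peaks; 5 degrees is reliable at a few percent signal noise while still
#'   resolving transitions separated by ~3 transition widths.
#' @param poly_order Polynomial order of the smoother; default 2.
#' @param prominence Fraction of the global derivative maximum a peak's
#'   prominence must reach; default 0.1.
#'
#' @return A `kinstab_tm_result` with `tm_values` (degrees C, ascending),
#'   `peak_prominences` (derivative magnitude at each peak, signal
#'   units/degree C), `smoothing_window` and `reversible = FALSE`.
#' @export
melting_temperatures <- function(melt, smoothing_window = 5,
                                 poly_order = 2, prominence = 0.1) {
  if (!inherits(melt, "kinstab_thermal_melt")) {
    ks_stop("`melt` must be a kinstab_thermal_melt", "invalid_scan")
  }
  tt <- melt$temperatures
  th <- melt$ellipticity222
  step <- stats::median(diff(tt))

  # window in points: odd, >= poly_order + 2, >= 5
  wpts <- max(5L, poly_order + 3L, round(smoothing_window / step))
  if (wpts %% 2L == 0L) wpts <- wpts + 1L
  wpts <- min(wpts, if (length(tt) %% 2L == 0L) length(tt) - 1L else length(tt))

  # moving-polynomial first derivative; edge estimates use one-sided
  # windows and are excluded from the peak search
  d <- as.numeric(signal::sgolayfilt(th, p = poly_order, n = wpts, m = 1)) /
    step
  half <- (wpts - 1L) %/% 2L
  d[c(seq_len(half), seq.int(length(d) - half + 1L, length(d)))] <- NA
  interior <- which(!is.na(d))
  dmax <- max(abs(d[interior]))
  # floor against floating-point fuzz on a genuinely flat scan
  if (dmax <= 1e-9 * (max(abs(th)) + 1)) {
    ks_stop("flat scan: no thermal transition detected", "no_transition")
  }
  sgn <- sign(d[interior][which.max(abs(d[interior]))])
  g <- sgn * d  # oriented derivative; transitions are positive peaks

  cand <- interior[-c(1L, length(interior))]
  cand <- cand[g[cand] > g[cand - 1L] & g[cand] >= g[cand + 1L] & g[cand] > 0]
  # topographic prominence: height above the higher of the two cols
  # connecting the peak to higher terrain (or to the series edge)
  prom_of <- function(i) {
    col_side <- function(idx_seq) {
      lo <- Inf
      for (j in idx_seq) {
        if (g[j] > g[i]) return(lo)
        lo <- min(lo, g[j])
      }
      lo
    }
    left <- col_side(rev(interior[interior < i]))
    right <- col_side(interior[interior > i])
    # clamp the col at zero: the oriented derivative's natural baseline
    g[i] - max(min(left, g[i]), min(right, g[i]), 0)
  }
  proms <- vapply(cand, prom_of, numeric(1))
  thr <- prominence * max(g[interior])
  peaks <- cand[proms >= thr]
  proms <- proms[proms >= thr]
  if (length(peaks) == 0L) {
    ks_stop("no derivative extremum above the prominence threshold",
            "no_transition")
  }

  # parabolic refinement around each discrete peak
  tm <- vapply(peaks, function(i) {
    y0 <- g[i - 1L]; y1 <- g[i]; y2 <- g[i + 1L]
    den <- y0 - 2 * y1 + y2
    off <- if (den == 0) 0 else 0.5 * (y0 - y2) / den
    off <- max(-0.5, min(0.5, off))
    tt[i] + off * step
  }, numeric(1))

  ord <- order(tm)
  structure(
    list(tm_values = tm[ord], peak_prominences = proms[ord],
         smoothing_window = smoothing_window, reversible = FALSE,
         sample_id = melt$sample_id),
    class = "kinstab_tm_result"
  )
}

#' @export
print.kinstab_tm_result <- function(x, ...) {
  cat(sprintf("<tm_result> Tm = %s degC (apparent, irreversible melt)\n",
              paste(sprintf("%.1f", x$tm_values), collapse = ", ")))
  invisible(x)
}
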