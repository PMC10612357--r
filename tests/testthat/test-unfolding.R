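test_that("two-state signal matches the Boltzmann population oracle", {
  set.seed(101)
  for (i in 1:30) {
    dG <- runif(1, 0.5, 6); m <- runif(1, 0.5, 4)
    yN <- runif(1, -2, 2); sN <- runif(1, -0.1, 0.1)
    yU <- runif(1, -2, 2); sU <- runif(1, -0.1, 0.1)
    Tk <- runif(1, 275, 310)
    x <- seq(0, 8, length.out = 17)
    expect_equal(two_state_signal(x, dG, m, yN, sN, yU, sU, temperature = Tk),
                 boltzmann_two_state(x, dG, m, yN, sN, yU, sU, Tk),
                 tolerance = 1e-12)
  }
})

test_that("two-state signal has the expected plateaus and midpoint", {
  # equal populations at the midpoint, flat baselines
  expect_equal(two_state_signal(2.5, 2.5, 1, 1, 0, 0, 0), 0.5)
  # native plateau at zero denaturant for the stable wild-type parameters
  expect_equal(two_state_signal(0, 2.51, 0.91, 1, 0, 0, 0),
               0.9886, tolerance = 1e-4)
  # unfolded limit tracks the unfolded baseline
  expect_equal(two_state_signal(8, 2.5, 1, 1, 0, 0.2, -0.02),
               0.2 - 0.02 * 8, tolerance = 5e-3)
  # monotone decreasing for flat baselines with yN > yU
  y <- two_state_signal(seq(0, 8, 0.1), 2.5, 1, 1, 0, 0, 0)
  expect_true(all(diff(y) < 0))
})

test_that("midpoint follows from the linear extrapolation identity", {
  expect_equal(round(midpoint_from_lem(2.51, 0.91), 2), 2.76)
  expect_equal(round(midpoint_from_lem(1.84, 0.93), 2), 1.98)
  expect_equal(midpoint_from_lem(0, 5), 0)
  expect_error(midpoint_from_lem(2, 0), class = "kinstab_invalid_slope")
  expect_error(midpoint_from_lem(2, -1), class = "kinstab_invalid_slope")
})

test_that("two-state fit recovers noiseless truth and the Eq.-5 identity", {
  g <- gen_two_state_series(2.5, 1.0, yN = 1, sN = 0.01, yU = 0, sU = -0.01,
                            noise_sd = 0, seed = 1)
  f <- fit_two_state(g$series)
  expect_lt(abs(f$dG_H2O - 2.5) / 2.5, 1e-6)
  expect_lt(abs(f$m - 1.0), 1e-6)
  expect_identical(f$midpoint, f$dG_H2O / f$m)
  for (p in c("yN", "sN", "yU", "sU")) {
    expect_lt(abs(f[[p]] - g$truth[[p]]), 1e-5)
  }
})

test_that("noisy two-state fits are unbiased with CRLB-consistent spread", {
  # dispersion of dG estimates should match the fit-reported standard error;
  # single-series information content at 2% noise permits ~0.3 kcal/mol
  errs <- c(); zs <- c()
  for (s in 1:40) {
    g <- gen_two_state_series(2.51, 0.91, yN = 1, sN = 0.01, yU = 0,
                              sU = -0.01,
                              denaturant = seq(0, 8, length.out = 30),
                              seed = s)
    f <- tryCatch(fit_two_state(g$series), error = function(e) NULL)
    if (is.null(f)) next
    errs <- c(errs, f$dG_H2O - 2.51)
    zs <- c(zs, (f$dG_H2O - 2.51) / f$standard_errors[["dG_H2O"]])
  }
  expect_gt(length(errs), 35)
  expect_lt(abs(mean(errs)), 0.15)        # unbiased
  expect_lt(median(abs(zs)), 1.5)         # spread consistent with reported SE
  expect_lt(median(abs(errs)), 0.5)       # and with the information bound
})

test_that("shared-m global fit estimates one m across replicates", {
  sers <- lapply(1:3, function(r) {
    gen_two_state_series(2.51, 0.91, yN = 1, sN = 0.01, yU = 0, sU = -0.01,
                         denaturant = seq(0, 8, length.out = 30),
                         seed = 100 + r)$series
  })
  fits <- fit_two_state(sers, share_m = TRUE)
  expect_length(fits, 3)
  ms <- vapply(fits, `[[`, numeric(1), "m")
  expect_identical(ms[1], ms[2])
  expect_identical(ms[1], ms[3])
  expect_lt(abs(ms[1] - 0.91), 0.15)
  for (f in fits) expect_identical(f$midpoint, f$dG_H2O / f$m)
})

test_that("an unbracketed transition is refused", {
  # midpoint at the top of the scanned range: no unfolded plateau
  g <- gen_two_state_series(8, 1.0, noise_sd = 0, seed = 1,
                            denaturant = seq(0, 8, length.out = 20))
  expect_error(fit_two_state(g$series),
               class = "kinstab_unbracketed_transition")
})

test_that("three-state signal has correct limits and equipopulation point", {
  # native plateau when the first transition is far away
  expect_equal(three_state_signal(0, 2, 3, 5, 3, 0.5, 1, 0, 0, 0), 1,
               tolerance = 1e-4)
  # unfolded limit tracks the unfolded baseline
  expect_equal(three_state_signal(8, 1, 3, 3, 3, 0.5, 1, 0, 0.2, -0.01),
               0.2 - 0.01 * 8, tolerance = 1e-3)
  # N and I equipopulated at D50_IN when U is negligible: (F_N + F_I) / 2
  expect_equal(three_state_signal(1, 1, 4, 6, 4, 0.6, 1, 0, 0, 0),
               (1 + 0.6) / 2, tolerance = 1e-6)
  expect_error(three_state_signal(-1, 1, 3, 3, 3, 0.5, 1, 0, 0, 0),
               class = "kinstab_invalid_input")
})

test_that("three-state fit recovers noiseless truth and is a fixed point", {
  g <- gen_three_state_series(1.0, 3.0, 3.1, 2.0, F_I = 0.6,
                              aN = 1, bN = 0.01, aU = 0, bU = -0.005,
                              noise_sd = 0, seed = 1)
  f <- fit_three_state(g$series)
  for (p in c("D50_IN", "m_IN", "D50_UI", "m_UI", "F_I")) {
    expect_lt(abs(f[[p]] - g$truth[[p]]) / abs(g$truth[[p]]), 1e-5)
  }
  # refitting the fitted curve's own predictions returns the same parameters
  pred <- three_state_signal(g$series$denaturant, f$D50_IN, f$m_IN, f$D50_UI,
                             f$m_UI, f$F_I, f$aN, f$bN, f$aU, f$bU,
                             temperature = f$temperature)
  f2 <- fit_three_state(denaturation_series(g$series$denaturant, pred))
  for (p in c("D50_IN", "m_IN", "D50_UI", "m_UI", "F_I")) {
    expect_equal(f2[[p]], f[[p]], tolerance = 1e-6)
  }
})

test_that("three-state fits converge across a realistic parameter grid", {
  grid <- expand.grid(D50_IN = c(0.8, 1.2), D50_UI = c(2.8, 3.5),
                      m_IN = c(2.5, 3.5), m_UI = 2.5)
  n_ok <- 0; n_tot <- 0
  for (i in seq_len(nrow(grid))) {
    for (s in 1:5) {
      n_tot <- n_tot + 1
      g <- gen_three_state_series(grid$D50_IN[i], grid$m_IN[i],
                                  grid$D50_UI[i], grid$m_UI[i], F_I = 0.55,
                                  seed = i * 100 + s)
      f <- tryCatch(suppressWarnings(fit_three_state(g$series)),
                    error = function(e) NULL)
      if (!is.null(f) && isTRUE(f$convergence)) n_ok <- n_ok + 1
    }
  }
  expect_gte(n_ok / n_tot, 0.95)
})

test_that("model selection prefers the generating model", {
  g2 <- gen_two_state_series(2.51, 0.91, yN = 1, sN = 0.01, yU = 0,
                             sU = -0.01, seed = 5)
  sel2 <- select_model(g2$series)
  expect_identical(sel2$chosen, "two_state")

  g3 <- gen_three_state_series(1.2, 3.0, 3.5, 2.5, F_I = 0.55,
                               noise_sd = 0.01, seed = 6)
  sel3 <- select_model(g3$series)
  expect_identical(sel3$chosen, "three_state")

  # an SVD rank of 3 overrides an ambiguous criterion
  sel_forced <- select_model(g2$series, svd_hint = 3)
  expect_identical(sel_forced$chosen, "three_state")
})

test_that("a two-state truth fitted as three-state merges the transitions", {
  g <- gen_two_state_series(2.5, 1.0, noise_sd = 0, seed = 1)
  f3 <- suppressWarnings(fit_three_state(g$series))
  pred <- three_state_signal(g$series$denaturant, f3$D50_IN, f3$m_IN,
                             f3$D50_UI, f3$m_UI, f3$F_I, f3$aN, f3$bN,
                             f3$aU, f3$bU, temperature = f3$temperature)
  # curve reproduced, but the extra states add no real structure
  expect_lt(max(abs(pred - g$series$observable)), 1e-3)
  expect_identical(select_model(g$series)$chosen, "two_state")
})
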