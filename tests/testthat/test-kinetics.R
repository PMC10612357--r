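test_that("initial rate reduces a linear trace to slope over calibration", {
  tt <- seq(0, 300, by = 5)
  cv <- progress_curve(tt, 5 * tt, substrate_conc = 100, enzyme_conc = 5,
                       calibration = 100)
  r <- initial_rate(cv)
  expect_equal(r$rate, 0.05, tolerance = 1e-12)

  flat <- progress_curve(tt, rep(10, length(tt)), substrate_conc = 10,
                         enzyme_conc = 5, calibration = 100)
  expect_equal(initial_rate(flat)$rate, 0)
})

test_that("initial rate tracks the true velocity under substrate depletion", {
  Km <- 1.81; Vmax <- 1.10e-2; S0 <- 10 * Km
  g <- gen_progress_curve(Km, Vmax, S0 = S0, enzyme_nM = 5, noise_sd = 0,
                          seed = 1)
  r <- initial_rate(g$curve)
  v0 <- Vmax * S0 / (Km + S0)
  expect_lt(abs(r$rate - v0) / v0, 0.02)
})

test_that("Michaelis-Menten fit reproduces the wild-type parameter sets", {
  # MAPK1 wild type: Km 1.81 uM, Vmax 1.10e-2 uM/s at 5 nM enzyme
  rp <- gen_rate_points(1.81, 1.10e-2, noise_sd = 0, seed = 1)
  f <- fit_michaelis_menten(rp$points, enzyme_conc = 5.0)
  expect_equal(round(f$kcat, 2), 2.20)
  expect_equal(round(f$efficiency, 2), 1.22)
  expect_lt(abs(f$Km - 1.81) / 1.81, 1e-6)

  # MAPK3 wild type: Km 3.17 uM, Vmax 1.638e-2 uM/s at 8 nM enzyme
  rp3 <- gen_rate_points(3.17, 1.638e-2, noise_sd = 0, seed = 1)
  f3 <- fit_michaelis_menten(rp3$points, enzyme_conc = 8.0)
  expect_equal(round(f3$kcat, 2), 2.05)
  expect_equal(round(f3$efficiency, 2), 0.65)
})

test_that("kcat and efficiency identities hold exactly on every fit", {
  set.seed(21)
  for (i in 1:10) {
    Km <- runif(1, 0.5, 20); Vmax <- 10^runif(1, -4, -1)
    e_nM <- runif(1, 0.5, 500)
    rp <- gen_rate_points(Km, Vmax, noise_sd = 0.03 * Vmax, seed = i)
    f <- suppressWarnings(fit_michaelis_menten(rp$points, e_nM))
    expect_identical(f$kcat, f$Vmax / (f$enzyme_conc * 1e-3))
    expect_identical(f$efficiency, f$kcat / f$Km)
    expect_gt(f$Km, 0); expect_gt(f$Vmax, 0)
  }
})

test_that("poor saturation is flagged", {
  S <- seq(0.01, 0.2, length.out = 6)  # far below Km
  pts <- data.frame(substrate_conc = S, rate = 1e-2 * S / (5 + S),
                    temperature = 30)
  expect_warning(fit_michaelis_menten(pts, 5),
                 class = "kinstab_poor_saturation")
})

test_that("find_tmax picks the grid maximum and flags edges and ties", {
  g <- gen_temperature_activity(9.95, tmax = 30, noise_sd = 0, seed = 1)
  expect_equal(find_tmax(g$points), 30.0)

  up <- data.frame(substrate_conc = NA, rate = 1:5,
                   temperature = c(10, 20, 30, 40, 45))
  expect_warning(tm <- find_tmax(up), class = "kinstab_edge_maximum")
  expect_equal(tm, 45)

  tie <- data.frame(substrate_conc = NA, rate = c(1, 3, 3, 2),
                    temperature = c(10, 20, 30, 40))
  expect_warning(tm2 <- find_tmax(tie), class = "kinstab_tie")
  expect_equal(tm2, 20)
})

test_that("Arrhenius fit recovers Ea exactly on noiseless data", {
  g <- gen_temperature_activity(9.95, tmax = 30, noise_sd = 0, seed = 1)
  f <- fit_arrhenius(g$points, 30)
  expect_lt(abs(f$Ea - 9.95) / 9.95, 1e-6)
  expect_true(all(f$fit_temperatures <= 30))
})

test_that("two-point closed form, log-linear and nonlinear Arrhenius agree", {
  R <- gas_constant_kcal()
  T1 <- 283.15; T2 <- 303.15; Ea <- 7.5; A <- 1e6
  k1 <- A * exp(-Ea / (R * T1)); k2 <- A * exp(-Ea / (R * T2))
  closed <- R * log(k1 / k2) / (1 / T2 - 1 / T1)
  expect_equal(closed, Ea, tolerance = 1e-12)
  pts <- data.frame(substrate_conc = NA, rate = c(k1, k2),
                    temperature = c(T1, T2) - 273.15)
  expect_equal(arrhenius_loglinear(pts, 30.1)$Ea, Ea, tolerance = 1e-9)

  g <- gen_temperature_activity(4.28, tmax = 37, noise_sd = 0, seed = 2)
  nl <- fit_arrhenius(g$points, 37)$Ea
  ll <- arrhenius_loglinear(g$points, 37)$Ea
  expect_lt(abs(nl - ll) / ll, 1e-6)
})

test_that("points above Tmax are excluded, never silently fitted", {
  g <- gen_temperature_activity(9.95, tmax = 30, noise_sd = 0, seed = 1)
  f <- fit_arrhenius(g$points, 30)
  expect_true(all(f$fit_temperatures <= 30))
  expect_lt(max(f$fit_temperatures), max(g$points$temperature))
  # too few usable points below tmax
  expect_error(fit_arrhenius(g$points[g$points$temperature >= 25, ], 30),
               class = "kinstab_insufficient_range")
})

test_that("Km recovery is robust at the assay's substrate span", {
  errs <- vapply(1:40, function(s) {
    rp <- gen_rate_points(1.81, 1.10e-2, noise_sd = 0.05 * 1.10e-2, seed = s)
    f <- suppressWarnings(fit_michaelis_menten(rp$points, 5))
    abs(f$Km - 1.81) / 1.81
  }, numeric(1))
  expect_lt(median(errs), 0.15)
})
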