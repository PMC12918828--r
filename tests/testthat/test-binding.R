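test_that("fraction_ligand_bound solves the mass-action quadratic", {
  # stoichiometric limit: excess protein, no dissociation
  expect_equal(fraction_ligand_bound(30e-9, 15e-9, 0), 1)
  expect_equal(fraction_ligand_bound(0, 15e-9, 1e-9), 0)
  # equal P = L = Kd against the textbook quadratic-formula branch
  expect_equal(fraction_ligand_bound(15e-9, 15e-9, 15e-9),
               complex_quadratic(15e-9, 15e-9, 15e-9) / 15e-9,
               tolerance = 1e-12)
  # the rationalised branch stays accurate when Kd << P, L
  expect_equal(fraction_ligand_bound(30e-9, 15e-9, 1e-18), 1,
               tolerance = 1e-9)
  expect_error(fraction_ligand_bound(-1e-9, 15e-9, 1e-9), ">= 0")
})

test_that("fraction_ligand_bound is monotone in protein and in Kd", {
  set.seed(5)
  for (i in 1:25) {
    l <- 10^runif(1, -10, -7)
    kd <- 10^runif(1, -11, -6)
    p <- sort(10^runif(20, -12, -6))
    fr <- fraction_ligand_bound(p, l, kd)
    expect_true(all(diff(fr) >= -1e-12))
    kds <- sort(10^runif(10, -11, -6))
    fr_kd <- vapply(kds, function(k)
      fraction_ligand_bound(5e-9, l, k), numeric(1))
    expect_true(all(diff(fr_kd) <= 1e-12))
  }
})

test_that("regime classification follows the ligand/Kd thresholds", {
  expect_equal(classify_regime(15e-9, 1e-9), "titration")
  expect_equal(classify_regime(1e-9, 1e-9), "binding")   # boundary inclusive
  expect_equal(classify_regime(5e-9, 1e-9), "intermediate")
  expect_error(classify_regime(0, 1e-9), "> 0")
})

test_that("equilibration time finds the first quiet scan", {
  conc <- 10^seq(-10, -8, length.out = 6)
  tp <- 0:10
  # exponential approach with a 1 h time constant, sampled hourly: the first
  # step with a relative change under 2% ends at t = 5 h
  f <- outer(rep(1000, 6), 1 - exp(-tp)) + 1
  ser <- titration_series(conc, 15e-9, f, timepoints = tp)
  eq <- equilibration_time(ser, rel_tol = 0.02)
  expect_equal(eq$time_h, 5)
  expect_true(eq$equilibrated)

  # constant series is at equilibrium from the first scan
  cs <- titration_series(conc, 15e-9, matrix(500, 6, 5), timepoints = 0:4)
  expect_equal(equilibration_time(cs)$time_h, 0)

  # monotone drift never plateaus: last timepoint, flagged
  dr <- titration_series(conc, 15e-9, outer(rep(100, 6), 1.5^(0:4)),
                         timepoints = 0:4)
  ed <- equilibration_time(dr)
  expect_equal(ed$time_h, 4)
  expect_false(ed$equilibrated)

  expect_error(equilibration_time(
    titration_series(conc, 15e-9, matrix(1, 6, 2), timepoints = 0:1)),
    "3 timepoints")
})

test_that("apparent Kd in the titration regime is the half-ligand artefact", {
  # true Kd far below the 15 nM limiting ligand: the 4PL midpoint reports
  # ~L/2, not the affinity
  ts <- make_titration(0.1e-9, 15e-9)
  fit <- fit_apparent_kd(ts, "logistic4")
  expect_equal(fit$kd_apparent, 7.5e-9, tolerance = 0.05)
  expect_true(is.na(fit$kd_exact))
  expect_lte(fit$bottom, fit$top)
})

test_that("exact isotherm recovers the generating Kd in the binding regime", {
  conc <- 10^seq(log10(1e-9), log10(1e-6), length.out = 10)
  ts <- make_titration(50e-9, 0.1e-9, concentrations = conc)
  fit <- fit_apparent_kd(ts, "exact_isotherm")
  expect_equal(fit$kd_exact, 50e-9, tolerance = 1e-3)
  expect_equal(fit$regime, "binding")
})

test_that("noisy isotherm fit matches a profiled grid-search oracle", {
  conc <- 10^seq(log10(2e-9), log10(500e-9), length.out = 10)
  ts <- make_titration(20e-9, 2e-9, concentrations = conc,
                       noise_sd_frac = 0.01, seed = 271)
  fit <- fit_apparent_kd(ts, "exact_isotherm")
  oracle <- grid_search_kd(ts, 10^seq(log10(1e-9), log10(200e-9),
                                      length.out = 600))
  expect_equal(fit$kd_exact, oracle$kd, tolerance = 0.03)
  expect_lte(sqrt(sum((ts$fluorescence - fit$fitted)^2)),
             sqrt(oracle$rss) * (1 + 1e-6))
})

test_that("EC50 tracks L/2 in the titration regime and Kd in the binding regime", {
  # titration regime, L = 100 x Kd: the artefact pins EC50 near L/2 (the
  # free-Hill 4PL carries a few-percent structural bias; 5% bound)
  t1 <- make_titration(0.15e-9, 15e-9)
  f1 <- fit_apparent_kd(t1, "logistic4")
  expect_equal(f1$kd_apparent, 7.5e-9, tolerance = 0.05)
  # binding regime, L = Kd/100: EC50 approaches the true Kd
  t2 <- make_titration(50e-9, 0.5e-9,
                       concentrations = 10^seq(log10(2e-9), log10(1.5e-6),
                                               length.out = 12))
  f2 <- fit_apparent_kd(t2, "logistic4")
  expect_equal(f2$kd_apparent, 50e-9, tolerance = 0.05)
})

test_that("seeded synthetic titrations are recovered with low median error", {
  set.seed(17)
  errs <- vapply(1:24, function(i) {
    kd <- 10^runif(1, 0, 2) * 1e-9
    ts <- make_titration(kd, kd / 10,
                         concentrations = kd * 10^seq(-1.5, 1.5,
                                                      length.out = 9),
                         noise_sd_frac = 0.01, seed = 4000 + i)
    fit <- fit_apparent_kd(ts, "exact_isotherm")
    abs(fit$kd_exact / kd - 1)
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})
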