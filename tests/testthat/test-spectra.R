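test_that("spectrum container enforces physical constraints", {
  expect_error(make_spectrum(c(500, 400), c(1, 1), "absorbance"),
               "strictly increasing")
  expect_error(make_spectrum(500, 1, "absorbance"), "at least 2")
  expect_error(make_spectrum(c(400, 500), c(1, NA), "absorbance"),
               "non-finite")
  expect_error(make_spectrum(c(400, 500), c(0.5, 1.05), "reflectance"),
               "must lie in")
  # measurement slack just above unity is tolerated for fractional kinds
  s <- make_spectrum(c(400, 500), c(0.5, 1.01), "reflectance")
  expect_s3_class(s, "bbs_spectrum")
})

test_that("find_peak locates band maxima with sub-grid refinement", {
  wl <- 600:720
  s <- make_spectrum(wl, exp(-(wl - 673)^2 / (2 * 15^2)), "absorbance")
  pk <- find_peak(s, c(600, 720))
  expect_equal(pk$peak_wavelength, 673, tolerance = 1e-6)
  expect_false(pk$flat)

  flat <- make_spectrum(wl, rep(0.4, length(wl)), "absorbance")
  pf <- find_peak(flat, c(610, 700))
  expect_true(pf$flat)
  expect_equal(pf$peak_wavelength, 655)

  # two-Gaussian mixture against dense evaluation of the analytic mixture
  mix <- function(x) exp(-(x - 660)^2 / (2 * 20^2)) +
    0.8 * exp(-(x - 690)^2 / (2 * 10^2))
  grid <- seq(600, 720, by = 0.5)
  oracle <- dense_argmax(mix, 600, 720, 0.01)
  pk2 <- find_peak(make_spectrum(grid, mix(grid), "absorbance"), c(600, 720))
  expect_lt(abs(pk2$peak_wavelength - oracle), 0.25)

  expect_error(find_peak(s, c(100, 200)), "outside spectrum")
})

test_that("find_peak recovers single-Gaussian centers within half a grid step",
{
  set.seed(41)
  for (i in 1:20) {
    center <- runif(1, 620, 700)
    sigma <- runif(1, 8, 30)
    step <- sample(c(0.5, 1, 2), 1)
    wl <- seq(600, 720, by = step)
    bm <- band_model(center, sigma, 1, "absorption")
    pk <- find_peak(make_spectrum(wl, eval_bands(bm, wl), "absorbance"),
                    c(600, 720))
    expect_lt(abs(pk$peak_wavelength - center), 0.5 * step)
  }
})

test_that("fit_extinction recovers Beer-Lambert slopes", {
  conc <- seq(0, 10e-6, length.out = 6)
  fit <- fit_extinction(conc, 39900 * conc, 376)
  expect_equal(fit$epsilon, 39900, tolerance = 1e-9)
  expect_equal(fit$intercept, 0, tolerance = 1e-6)
  expect_false(fit$negative_slope)

  zero <- fit_extinction(conc, rep(0, 6), 376)
  expect_equal(zero$epsilon, 0)
  expect_equal(zero$intercept, 0)

  # noisy series must match the hand-coded normal-equations solution
  set.seed(7)
  a <- 39900 * conc * (1 + rnorm(6, 0, 0.01)) + 0.002
  fit2 <- fit_extinction(conc, a, 376)
  oracle <- ols_normal_equations(conc, a)
  expect_equal(fit2$epsilon, unname(oracle["slope"]), tolerance = 1e-9)
  expect_equal(fit2$intercept, unname(oracle["intercept"]), tolerance = 1e-9)

  # scale equivariance: concentrations x k divides the slope by k exactly
  fit3 <- fit_extinction(conc * 3.7, a, 376)
  expect_equal(fit3$epsilon * 3.7, fit2$epsilon, tolerance = 1e-12)

  expect_error(fit_extinction(conc[1:2], a[1:2], 376), "3 points")
  expect_error(fit_extinction(rep(2e-6, 5), a[1:5], 376), "rank-deficient")
})

test_that("Q-band enhancement is a guarded ratio with reciprocity", {
  expect_equal(q_band_enhancement(36449, 11200), 3.254375,
               tolerance = 1e-9)
  expect_equal(q_band_enhancement(28034, 11200), 2.503036,
               tolerance = 1e-6)
  expect_equal(q_band_enhancement(11200, 11200), 1)
  set.seed(13)
  for (i in 1:10) {
    ab <- runif(2, 1e3, 1e5)
    expect_equal(q_band_enhancement(ab[1], ab[2]) *
                   q_band_enhancement(ab[2], ab[1]), 1, tolerance = 1e-12)
  }
  expect_error(q_band_enhancement(36449, 0), "positive")
})

test_that("relative quantum yield follows the gradient method exactly", {
  a <- seq(0.01, 0.1, length.out = 5)
  ref <- data.frame(absorbance = a, integrated_emission = 2800 * a)
  # identity: sample == reference recovers the reference yield exactly
  expect_equal(relative_quantum_yield(ref, ref, 0.28)$qy, 0.28)

  # gradient ratio constructed as 1.24/28 recovers 1.24%
  smp <- data.frame(absorbance = a,
                    integrated_emission = 2800 * (1.24 / 28) * a)
  res <- relative_quantum_yield(smp, ref, 0.28)
  expect_equal(res$qy, 0.0124)

  # arbitrary noiseless series: gradients equal the closed-form
  # zero-intercept slopes sum(xy)/sum(x^2)
  y1 <- c(3, 7, 11, 19, 23); y2 <- c(5, 9, 16, 22, 31)
  r2 <- relative_quantum_yield(
    data.frame(absorbance = a, integrated_emission = y1),
    data.frame(absorbance = a, integrated_emission = y2), 0.28)
  expect_equal(r2$gradient_sample, sum(a * y1) / sum(a * a))
  expect_equal(r2$gradient_reference, sum(a * y2) / sum(a * a))

  # invariance to a common emission scale factor
  r3 <- relative_quantum_yield(
    data.frame(absorbance = a, integrated_emission = 17.3 * y1),
    data.frame(absorbance = a, integrated_emission = 17.3 * y2), 0.28)
  expect_equal(r3$qy, r2$qy, tolerance = 1e-12)

  # refractive-index correction enters squared
  r4 <- relative_quantum_yield(ref, ref, 0.28, n_sample = 1.4,
                               n_reference = 1.333)
  expect_equal(r4$qy, 0.28 * (1.4 / 1.333)^2)

  expect_warning(relative_quantum_yield(
    data.frame(absorbance = c(0.001, 0.05, 0.1),
               integrated_emission = c(1, 50, 100)), ref, 0.28),
    "validity range")
  expect_error(relative_quantum_yield(
    data.frame(absorbance = a, integrated_emission = -y1), ref, 0.28),
    "nonpositive")
})

test_that("denaturation metrics recover Q-band collapse and Soret shift", {
  wl <- 340:760
  native <- make_spectrum(wl, 0.5 * exp(-(wl - 390)^2 / (2 * 18^2)) +
                            0.30 * exp(-(wl - 673)^2 / (2 * 15^2)),
                          "absorbance")
  denat <- make_spectrum(wl, 0.45 * exp(-(wl - 376)^2 / (2 * 18^2)) +
                           0.12 * exp(-(wl - 672)^2 / (2 * 15^2)),
                         "absorbance")
  m <- denaturation_metrics(native, denat)
  expect_equal(m$soret_shift, 14, tolerance = 0.01)
  expect_equal(m$q_fold_decrease, 2.5, tolerance = 0.001)

  id <- denaturation_metrics(native, native)
  expect_equal(id$q_fold_decrease, 1)
  expect_equal(id$soret_shift, 0)

  short <- make_spectrum(400:700, rep(0.1, 301), "absorbance")
  expect_error(denaturation_metrics(short, short), "350-750")
})

test_that("red edge sits at the steepest reflectance rise", {
  wl <- seq(650, 800, by = 1)
  sig <- function(x) 1 / (1 + exp(-(x - 700) / 5))
  r <- make_spectrum(wl, 0.05 + 0.6 * sig(wl), "reflectance")
  expect_equal(red_edge_position(r)$wavelength, 700, tolerance = 0.5)

  ramp <- make_spectrum(wl, seq(0.1, 0.6, length.out = length(wl)),
                        "reflectance")
  rr <- red_edge_position(ramp)
  expect_true(rr$flat)
  expect_equal(rr$wavelength, 725)

  set.seed(99)
  noisy <- make_spectrum(wl, pmin(1, pmax(0, 0.05 + 0.6 * sig(wl) +
                                            rnorm(length(wl), 0, 0.003))),
                         "reflectance")
  rn <- red_edge_position(noisy, smooth_window = 7L)
  expect_lt(abs(rn$wavelength - 700), 2)

  expect_error(red_edge_position(r, window = c(700, 703)), "fewer than")
})
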