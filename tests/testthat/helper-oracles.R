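# Independent oracles used across test files. Each is deliberately written
# from a different formulation than the implementation it checks.

# OLS slope/intercept straight from the normal equations.
ols_normal_equations <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(slope = slope, intercept = intercept)
}

# Dense brute-force argmax of a function on [lo, hi].
dense_argmax <- function(f, lo, hi, step = 0.01) {
  x <- seq(lo, hi, by = step)
  x[which.max(f(x))]
}

# Quadratic-formula solution of the 1:1 complex concentration (the textbook
# form; the package uses the rationalised branch).
complex_quadratic <- function(p, l, kd) {
  s <- p + l + kd
  (s - sqrt(s^2 - 4 * p * l)) / 2
}

# Profiled grid search for the exact-isotherm Kd: for each trial Kd the
# (f0, dF) pair is the exact linear least-squares solution, so the grid
# minimum is the global optimum up to grid resolution.
grid_search_kd <- function(series, kd_grid) {
  conc <- series$protein_concentrations
  y <- series$fluorescence
  best <- NULL
  for (kd in kd_grid) {
    fr <- fraction_ligand_bound(conc, series$ligand_total, kd)
    fit <- stats::lm(y ~ fr)
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(kd = kd, rss = rss)
  }
  best
}

# Numerically integrated CDF of the 2D Henyey-Greenstein density.
hg2d_cdf <- function(theta, g, n_grid = 20001) {
  tt <- seq(-pi, pi, length.out = n_grid)
  dens <- (1 - g^2) / (2 * pi * (1 + g^2 - 2 * g * cos(tt)))
  cdf <- cumsum(c(0, (dens[-1] + dens[-n_grid]) / 2 * diff(tt)))
  approx(tt, cdf / cdf[n_grid], theta)$y
}
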