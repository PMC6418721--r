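# Independent oracles and fixture builders used across the suite.
# These deliberately avoid the package's own interpolation code paths.

# Brute-force area-at-pressure: scan all segments of a monotonized curve
# for the bracketing pair and interpolate by the two-point line formula.
brute_area_at_pressure <- function(curve, p) {
  pr <- curve$pressure
  ar <- curve$area
  vapply(p, function(q) {
    if (q < min(pr) || q > max(pr)) stop("out of range")
    for (i in seq_len(length(pr) - 1L)) {
      if (pr[i] <= q && q <= pr[i + 1L]) {
        if (pr[i + 1L] == pr[i]) return(ar[i])
        return(ar[i] + (q - pr[i]) * (ar[i + 1L] - ar[i]) /
                 (pr[i + 1L] - pr[i]))
      }
    }
    stop("no bracketing segment found")
  }, numeric(1))
}

# Brute-force additivity rule: weighted sum of two brute-force
# interpolations (independent of ideal_additive_isotherm).
brute_additive_area <- function(lipid, polymer, x_lipid, p) {
  x_lipid * brute_area_at_pressure(lipid, p) +
    (1 - x_lipid) * brute_area_at_pressure(polymer, p)
}

# Closed-form ordinary least squares via the normal equations, returning
# the x-intercept (independent of mip_from_series / lm.fit).
ols_x_intercept <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  -intercept / slope
}

# Seeded random monotone isotherm (strictly decreasing area, strictly
# increasing pressure), for property-style tests.
random_monotone_curve <- function(seed, n = 50L, a_hi = 150, a_lo = 40) {
  set.seed(seed)
  area <- sort(runif(n, a_lo, a_hi), decreasing = TRUE)
  pressure <- cumsum(runif(n, 0.01, 1.5))
  isotherm_curve(area, pressure)
}

# Random curve with injected back-relaxation dips (violating pressure
# monotonicity) for monotonize() property tests.
random_dippy_curve <- function(seed, n = 50L) {
  set.seed(seed)
  area <- sort(runif(n, 40, 150), decreasing = TRUE)
  pressure <- cumsum(runif(n, 0.01, 1.5))
  dips <- sample(2:n, 8L)
  pressure[dips] <- pressure[dips] - runif(8L, 0.5, 3)
  pressure <- pmax(pressure, -0.4)
  isotherm_curve(area, pressure)
}

expect_curve_equal <- function(a, b, tol = 0) {
  if (tol == 0) {
    expect_identical(a$area, b$area)
    expect_identical(a$pressure, b$pressure)
  } else {
    expect_equal(a$area, b$area, tolerance = tol)
    expect_equal(a$pressure, b$pressure, tolerance = tol)
  }
}
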