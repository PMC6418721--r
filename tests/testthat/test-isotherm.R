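test_that("monotonize applies the running-maximum / largest-area-tie rule", {
  c1 <- isotherm_curve(c(100, 90, 80), c(1.0, 0.8, 2.0))
  m1 <- monotonize(c1)
  expect_equal(m1$area, c(100, 80))
  expect_equal(m1$pressure, c(1.0, 2.0))

  # already strictly increasing pressure: identity
  c2 <- random_monotone_curve(11)
  expect_curve_equal(monotonize(c2), c2)

  # degenerate after collapse
  flat <- isotherm_curve(c(120, 110, 100), c(2, 2, 2))
  expect_error(monotonize(flat), class = "langmuir_degenerate_curve")
})

test_that("monotonize invariants hold on seeded dippy curves", {
  for (s in 1:100) {
    cc <- random_dippy_curve(s)
    m <- monotonize(cc)
    expect_true(all(diff(m$area) < 0))
    expect_true(all(diff(m$pressure) > 0))
    expect_lte(length(m$area), length(cc$area))
    expect_curve_equal(monotonize(m), m)  # idempotent
  }
})

test_that("area_at_pressure interpolates piecewise-linearly, no extrapolation", {
  cc <- isotherm_curve(c(100, 80, 60), c(10, 15, 30))
  expect_equal(area_at_pressure(cc, 15), 80)          # grid point
  cc2 <- isotherm_curve(c(100, 80), c(10, 20))
  expect_equal(area_at_pressure(cc2, 15), 90)          # linear midpoint
  expect_error(area_at_pressure(cc2, 25), class = "langmuir_out_of_range")
  expect_error(area_at_pressure(cc2, 5), class = "langmuir_out_of_range")
  raw <- isotherm_curve(c(100, 90, 80), c(1.0, 0.8, 2.0))
  expect_error(area_at_pressure(raw, 1), class = "langmuir_not_monotonized")
})

test_that("area_at_pressure matches the brute-force segment oracle", {
  for (s in c(3, 17)) {
    cc <- random_monotone_curve(s)
    set.seed(s + 1000)
    q <- runif(200, min(cc$pressure), max(cc$pressure))
    expect_equal(area_at_pressure(cc, q), brute_area_at_pressure(cc, q),
                 tolerance = 1e-9)
    # non-increasing in pressure
    qs <- sort(q)
    expect_true(all(diff(area_at_pressure(cc, qs)) <= 0))
  }
})

test_that("pressure/area interpolation round trips on strictly monotone curves", {
  cc <- random_monotone_curve(5)
  q <- seq(min(cc$pressure), max(cc$pressure), length.out = 37)
  expect_equal(pressure_at_area(cc, area_at_pressure(cc, q)), q,
               tolerance = 1e-9)
})

test_that("lift_off_area finds the threshold crossing", {
  cc <- isotherm_curve(c(120, 110), c(0.0, 1.0))
  expect_equal(lift_off_area(cc, threshold = 0.5), 115)

  flat <- isotherm_curve(c(120, 110, 100), c(0, 0.01, 0.02))
  expect_error(lift_off_area(flat), class = "langmuir_no_lift_off")

  # synthetic lipid preset: Volmer parameters place the 0.5 mN/m crossing
  # at 110 A^2 by construction
  m <- monotonize(simulate_lipid_isotherm())
  expect_equal(lift_off_area(m), 110, tolerance = 0.5)
})

test_that("compressibility modulus matches closed forms", {
  # affine isotherm Pi = a - b*A  ->  Cs_inv = b*A exactly, everywhere on
  # the interior grid
  a_grid <- seq(120, 60, length.out = 101)
  b <- 0.35
  lin <- isotherm_curve(a_grid, 42 - b * a_grid)
  cm <- compressibility_modulus(lin)
  expect_equal(cm$cs_inv, b * cm$area, tolerance = 1e-6)

  # Volmer branch: Cs_inv = A*kT/(A-omega)^2 within 2% away from edges
  kT <- thermal_energy(20)
  omega <- 50
  pi_coh <- kT / 60 - 0.5
  av <- seq(108, 78, length.out = 200)
  volmer <- isotherm_curve(av, kT / (av - omega) - pi_coh)
  cmv <- compressibility_modulus(volmer)
  analytic <- cmv$area * kT / (cmv$area - omega)^2
  expect_lt(max(abs(cmv$cs_inv / analytic - 1)), 0.02)

  # plateau of a two-phase isotherm: near-zero modulus
  m <- monotonize(simulate_lipid_isotherm())
  cmp <- compressibility_modulus(m)
  # interior of the plateau: windows fully inside the coexistence branch
  plateau <- cmp[cmp$pressure > 9.08 & cmp$pressure < 9.25, ]
  expect_gt(nrow(plateau), 3)
  expect_true(all(plateau$cs_inv < 5))

  expect_error(compressibility_modulus(monotonize(random_monotone_curve(2, n = 5L))),
               class = "langmuir_window")
})

test_that("transition_onset locates the programmed plateau onset", {
  m <- monotonize(simulate_lipid_isotherm())
  tf <- transition_onset(m)
  expect_true(tf$found)
  expect_equal(tf$transition_onset_pressure, 9.0, tolerance = 0.5)
  expect_gte(tf$lift_off_area, tf$transition_onset_area)

  # strictly linear isotherm: no-transition flag, not an error
  a_grid <- seq(120, 60, length.out = 101)
  lin <- isotherm_curve(a_grid, 42 - 0.35 * a_grid)
  tl <- transition_onset(lin)
  expect_false(tl$found)
  expect_true(is.na(tl$transition_onset_pressure))
})

test_that("isotherm files round trip through the csv dialect", {
  cc <- isotherm_curve(c(100, 80, 60), c(1, 5, 20), convention = "per_lipid",
                       temperature = 22.5, label = "demo")
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_isotherm(cc, path)
  back <- read_isotherm(path)
  expect_equal(back$area, cc$area)
  expect_equal(back$pressure, cc$pressure)
  expect_identical(back$convention, "per_lipid")
  expect_equal(back$temperature, 22.5)
  expect_identical(back$label, "demo")
})

test_that("curve validation rejects malformed input", {
  expect_error(isotherm_curve(100, 1), class = "langmuir_degenerate_curve")
  expect_error(isotherm_curve(c(100, -5), c(1, 2)), class = "langmuir_argument")
  expect_error(isotherm_curve(c(100, 90), c(-1, 2)), class = "langmuir_argument")
})
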