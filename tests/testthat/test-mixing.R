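test_that("mole_fractions builds exact mixture specs", {
  m <- mole_fractions(10, 1)
  expect_equal(m$x_polymer, 1 / 11)
  expect_identical(m$x_lipid + m$x_polymer, 1)
  expect_equal(mole_fractions(1, 1)$x_polymer, 0.5)
  expect_equal(mole_fractions(100, 1)$x_polymer, 1 / 101)
  expect_equal(mole_fractions(5, 0)$x_polymer, 0)  # pure-lipid limit
  expect_error(mole_fractions(0, 1), class = "langmuir_argument")
  expect_error(mole_fractions(10, -1), class = "langmuir_argument")
})

test_that("ideal_additive_isotherm reproduces hand arithmetic and identities", {
  lipid <- isotherm_curve(c(100, 80, 60), c(5, 10, 20))
  polymer <- isotherm_curve(c(2000, 1200, 600), c(5, 10, 20))
  mix <- mole_fractions(10, 1)

  calc <- ideal_additive_isotherm(lipid, polymer, mix, c(7.5, 10, 15))
  expect_equal(area_at_pressure(calc, 10), (10 / 11) * 80 + (1 / 11) * 1200,
               tolerance = 1e-12)

  # x_polymer = 0: identity on the lipid
  pure <- ideal_additive_isotherm(lipid, polymer, mole_fractions(5, 0),
                                  c(6, 10, 18))
  expect_equal(pure$area, area_at_pressure(lipid, c(6, 10, 18)),
               tolerance = 1e-12)

  # identical components: convexity fixed point
  same <- ideal_additive_isotherm(lipid, lipid, mix, c(6, 10, 18))
  expect_equal(sort(same$area), sort(area_at_pressure(lipid, c(6, 10, 18))),
               tolerance = 1e-12)

  # grid outside the overlap
  expect_error(ideal_additive_isotherm(lipid, polymer, mix, c(1, 10)),
               class = "langmuir_out_of_range")
  # convention discipline
  pl <- to_per_lipid(lipid, mix)
  expect_error(ideal_additive_isotherm(pl, polymer, mix, 10),
               class = "langmuir_convention")
})

test_that("additivity is monotone in composition at fixed pressure", {
  lipid <- monotonize(simulate_lipid_isotherm())
  polymer <- monotonize(simulate_polymer_isotherm())
  xs <- c(0.001, 0.01, 0.05, 1 / 11, 0.2)
  areas <- vapply(xs, function(xp) {
    mix <- mole_fractions(1 - xp, xp)
    area_at_pressure(ideal_additive_isotherm(lipid, polymer, mix, c(10, 15)), 15)
  }, numeric(1))
  a_l <- area_at_pressure(lipid, 15)
  a_p <- area_at_pressure(polymer, 15)
  expect_true(all(diff(areas) > 0))
  expect_true(all(areas > min(a_l, a_p) & areas < max(a_l, a_p)))
})

test_that("per-lipid conversion scales by 1/x_lipid and round trips", {
  lipid <- isotherm_curve(c(100, 80, 60), c(5, 10, 20))
  polymer <- isotherm_curve(c(2000, 1200, 600), c(5, 10, 20))
  mix <- mole_fractions(10, 1)
  calc <- ideal_additive_isotherm(lipid, polymer, mix, c(7.5, 10, 15))
  calc_pl <- to_per_lipid(calc, mix)
  expect_identical(calc_pl$convention, "per_lipid")
  expect_equal(area_at_pressure(calc_pl, 10), 200, tolerance = 1e-9)

  back <- to_per_molecule(calc_pl, mix)
  expect_equal(back$area, calc$area, tolerance = 1e-12)

  # pure lipid: unchanged areas
  pure <- to_per_lipid(lipid, mole_fractions(5, 0))
  expect_equal(pure$area, lipid$area)
  expect_error(to_per_lipid(calc_pl, mix), class = "langmuir_convention")
})

test_that("area_shift_vs_lipid subtracts per-lipid areas", {
  pure <- isotherm_curve(c(90, 80, 70), c(5, 15, 30))
  mixc <- isotherm_curve(c(210, 200, 190), c(5, 15, 30),
                         convention = "per_lipid")
  s <- area_shift_vs_lipid(mixc, pure, c(5, 15, 30))
  expect_equal(s$delta_area, c(120, 120, 120))
  expect_identical(s$reference, "pure_lipid")

  # pure lipid against itself: identically zero
  self <- area_shift_vs_lipid(
    isotherm_curve(pure$area, pure$pressure, convention = "per_lipid"),
    pure, c(6, 10, 20))
  expect_equal(self$delta_area, c(0, 0, 0))

  # out-of-range pressures skipped with warning, recorded
  expect_warning(
    s2 <- area_shift_vs_lipid(mixc, pure, c(2, 15, 40)),
    "skipping"
  )
  expect_equal(s2$pressures, 15)
  expect_equal(s2$skipped, c(2, 40))
})

test_that("excess_area_of_mixing is zero for additive films and recovers bumps", {
  lipid <- monotonize(simulate_lipid_isotherm())
  gp <- monotonize(simulate_polymer_isotherm(polymer_film_params("gp_like")))
  mix <- mole_fractions(10, 1)

  mixed <- monotonize(simulate_mixed_isotherm(lipid, gp, mix))
  grid <- mixed$pressure
  calc <- to_per_lipid(ideal_additive_isotherm(lipid, gp, mix, grid), mix)
  ex0 <- excess_area_of_mixing(mixed, calc, grid, mix = mix)
  expect_lt(max(abs(ex0$delta_area)), 1e-6)

  # programmed Gaussian bump, noiseless: recovered at full amplitude
  mixed_b <- monotonize(simulate_mixed_isotherm(
    lipid, gp, mix, excess_profile = gaussian_excess(15, 12, 5)))
  exb <- excess_area_of_mixing(mixed_b, calc, grid, mix = mix)
  pk <- excess_peak(exb, smooth_window = 1L)
  expect_equal(pk$peak, 15, tolerance = 0.05)
  expect_equal(pk$pressure, 12, tolerance = 0.5)
})

test_that("squeeze-out films show negative excess beyond their squeeze-out", {
  lipid <- monotonize(simulate_lipid_isotherm())
  mix <- mole_fractions(10, 1)
  # experimental film loses its polymer at 25 mN/m; the calculated curve
  # keeps the reference polymer (squeeze-out 32.5) in the film
  early <- monotonize(simulate_polymer_isotherm(
    polymer_film_params(squeeze_out_pressure = 25)))
  ref <- monotonize(simulate_polymer_isotherm(polymer_film_params("gp_like")))
  mixed <- monotonize(simulate_mixed_isotherm(lipid, early, mix))
  grid <- seq(5, 45, length.out = 100)
  calc <- to_per_lipid(ideal_additive_isotherm(lipid, ref, mix, grid), mix)
  ex <- excess_area_of_mixing(mixed, calc, seq(27, 31, length.out = 9))
  expect_true(all(ex$delta_area < 0))
})

test_that("delta-area at fixed pressure increases with polymer fraction", {
  lipid <- monotonize(simulate_lipid_isotherm())
  gp <- monotonize(simulate_polymer_isotherm(polymer_film_params("gp_like")))
  shifts <- vapply(c(100, 50, 20, 10), function(r) {
    mix <- mole_fractions(r, 1)
    mixed <- monotonize(simulate_mixed_isotherm(lipid, gp, mix))
    area_shift_vs_lipid(mixed, lipid, c(15, 16))$delta_area[1L]
  }, numeric(1))
  expect_true(all(diff(shifts) > 0))
})

test_that("convergence_pressure detects sustained coincidence", {
  pure <- monotonize(simulate_lipid_isotherm())
  # identical curves converge at the lowest shared pressure
  as_pl <- isotherm_curve(pure$area, pure$pressure, convention = "per_lipid")
  expect_equal(convergence_pressure(as_pl, pure), min(pure$pressure),
               tolerance = 1e-9)

  # programmed squeeze-out pressures are recovered within 1 mN/m
  for (pso in c(30, 45)) {
    poly <- monotonize(simulate_polymer_isotherm(
      polymer_film_params(squeeze_out_pressure = pso), pressure_max = 52))
    mixed <- monotonize(simulate_mixed_isotherm(pure, poly,
                                                mole_fractions(10, 1)))
    expect_equal(convergence_pressure(mixed, pure), pso, tolerance = 1)
  }

  # a film that never converges reports NA
  poly_hi <- monotonize(simulate_polymer_isotherm(
    polymer_film_params(squeeze_out_pressure = 55), pressure_max = 50))
  mixed_hi <- monotonize(simulate_mixed_isotherm(pure, poly_hi,
                                                 mole_fractions(10, 1)))
  expect_true(is.na(convergence_pressure(mixed_hi, pure)))
})

test_that("excess series files round trip", {
  s <- area_shift_vs_lipid(
    isotherm_curve(c(210, 200, 190), c(5, 15, 30), convention = "per_lipid"),
    isotherm_curve(c(90, 80, 70), c(5, 15, 30)),
    c(5, 15, 30), mix = mole_fractions(10, 1))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_excess_series(s, path)
  df <- utils::read.csv(path, comment.char = "#")
  expect_equal(df$pressure_mN_per_m, s$pressures)
  expect_equal(df$delta_area_A2_per_lipid, s$delta_area)
})
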