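test_that("thermal energy converts to monolayer units correctly", {
  # k_B * 293.15 K = 4.0474e-21 J = 404.74 A^2 mN/m  (1 A^2 mN/m = 1e-23 J)
  expect_equal(thermal_energy(20), 1.380649e-23 * 293.15 / 1e-23,
               tolerance = 1e-12)
  expect_equal(thermal_energy(20), 404.7, tolerance = 0.05)
})

test_that("generators are pure functions of (parameters, seed)", {
  a <- simulate_lipid_isotherm(noise_sd_pressure = 0.1, seed = 7)
  b <- simulate_lipid_isotherm(noise_sd_pressure = 0.1, seed = 7)
  expect_identical(a$pressure, b$pressure)
  expect_identical(a$area, b$area)

  pa <- simulate_polymer_isotherm(noise_sd_pressure = 0.1, seed = 3)
  pb <- simulate_polymer_isotherm(noise_sd_pressure = 0.1, seed = 3)
  expect_identical(pa$pressure, pb$pressure)

  ta <- simulate_adsorption_trace(10, noise_sd = 0.1, seed = 5)
  tb <- simulate_adsorption_trace(10, noise_sd = 0.1, seed = 5)
  expect_identical(ta$pressure, tb$pressure)

  ia <- simulate_micrograph(width = 64L, height = 64L, target_phi = 0.3,
                            n_domains = 6L, noise_sd = 5, seed = 11)
  ib <- simulate_micrograph(width = 64L, height = 64L, target_phi = 0.3,
                            n_domains = 6L, noise_sd = 5, seed = 11)
  expect_identical(ia$intensities, ib$intensities)

  # generators do not disturb the caller's RNG stream
  set.seed(1); r1 <- runif(1)
  set.seed(1); invisible(simulate_lipid_isotherm(noise_sd_pressure = 0.1,
                                                 seed = 99)); r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("noise requires a seed", {
  expect_error(simulate_lipid_isotherm(noise_sd_pressure = 0.1),
               class = "langmuir_argument")
  expect_error(simulate_adsorption_trace(5, noise_sd = 0.1),
               class = "langmuir_argument")
})

test_that("noiseless curves pass monotonize unchanged", {
  lip <- simulate_lipid_isotherm()
  ml <- monotonize(lip)
  expect_identical(ml$area, lip$area)
  expect_identical(ml$pressure, lip$pressure)

  poly <- simulate_polymer_isotherm()
  mp <- monotonize(poly)
  expect_identical(length(mp$area), length(poly$area))
})

test_that("lipid preset encodes the programmed landmarks in its ground truth", {
  lip <- simulate_lipid_isotherm()
  gt <- get_ground_truth(lip)
  expect_equal(gt$lift_off_area, 110)
  expect_equal(gt$transition_pressure, 9.0)
  # closed-form check: the Volmer branch passes through the lift-off point
  p <- gt$params
  expect_equal(thermal_energy(p$temperature) / (110 - p$omega) - p$pi_coh,
               0.5, tolerance = 1e-12)
})

test_that("polymer presets differ in squeeze-out as programmed", {
  gp <- monotonize(simulate_polymer_isotherm(polymer_film_params("gp_like")))
  fgp <- monotonize(simulate_polymer_isotherm(polymer_film_params("fgp_like")))
  a_gp <- area_at_pressure(gp, 38)
  a_fgp <- area_at_pressure(fgp, 38)
  residual <- polymer_film_params("gp_like")$residual_area
  expect_lt(abs(a_gp - residual), 0.5)   # squeezed out at 38 mN/m
  expect_gt(a_fgp, residual + 20)        # still anchored at 38 mN/m
  expect_error(polymer_film_params("nope"), class = "langmuir_argument")
})

test_that("mixed-film generator reduces to the additivity rule when E = 0", {
  lip <- monotonize(simulate_lipid_isotherm())
  gp <- monotonize(simulate_polymer_isotherm())
  mix <- mole_fractions(20, 1)
  mixed <- simulate_mixed_isotherm(lip, gp, mix)
  expect_identical(mixed$convention, "per_lipid")
  grid <- mixed$pressure
  manual <- area_at_pressure(lip, grid) +
    (mix$x_polymer / mix$x_lipid) * area_at_pressure(gp, grid)
  expect_equal(mixed$area, manual, tolerance = 1e-12)
  gt <- get_ground_truth(mixed)
  expect_equal(gt$excess_peak, 0)
})

test_that("adsorption traces follow the programmed linear decline", {
  # clamp: at or above the exclusion pressure the trace stays flat
  tr <- simulate_adsorption_trace(45, exclusion_pressure = 42.4)
  expect_equal(max(tr$pressure) - min(tr$pressure), 0)
  expect_equal(get_ground_truth(tr)$delta_pi_eq, 0)

  # noiseless series: construction is exactly linear, so the fitted MIP
  # equals the programmed exclusion pressure to machine precision
  pis <- seq(5, 35, by = 5)
  dp <- vapply(pis, function(p) {
    delta_pi(simulate_adsorption_trace(p, exclusion_pressure = 42.4), "max")
  }, numeric(1))
  expect_equal(mip_from_series(pis, dp)$mip, 42.4, tolerance = 1e-9)
})

test_that("micrograph generator honours target phi or fails loudly", {
  blank <- simulate_micrograph(width = 64L, height = 64L, target_phi = 0,
                               n_domains = 0L, seed = 1)
  expect_true(all(blank$intensities == 200))
  expect_equal(get_ground_truth(blank)$phi, 0)

  img <- simulate_micrograph(width = 128L, height = 128L, target_phi = 0.4,
                             n_domains = 12L, seed = 4)
  expect_lte(abs(get_ground_truth(img)$phi - 0.4), 0.005)

  expect_error(
    simulate_micrograph(width = 64L, height = 64L, target_phi = 0.85,
                        n_domains = 4L, seed = 1),
    class = "langmuir_packing"
  )
})

test_that("ground-truth sidecars serialize to json", {
  tr <- simulate_adsorption_trace(10, noise_sd = 0.1, seed = 2,
                                  n_points = 30L)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_ground_truth(tr, path)
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(gt$generator, "simulate_adsorption_trace")
  expect_equal(gt$exclusion_pressure, 42.4)
  expect_error(write_ground_truth(list(), tempfile()),
               class = "langmuir_argument")
})
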