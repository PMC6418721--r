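# Seeded generators producing every input the analysis modules consume,
# together with ground-truth records, emulating the phenomenology of a
# monofluorinated-DPPC / triblock-copolymer film-balance study:
#
#  * a lipid isotherm with lift-off near 110 A^2/molecule, LE-LC plateau
#    onset near 9 mN/m, a steep LC branch and collapse;
#  * large-area polymer isotherms with a pancake -> brush transition and
#    pressure-driven squeeze-out (sigmoidal loss of interfacial area);
#  * mixed films obeying or violating the additivity rule by a prescribed
#    excess profile;
#  * adsorption traces with fast + slow regimes whose equilibrium
#    Delta Pi declines linearly to zero at a set exclusion pressure;
#  * binary-contrast domain images with a known area fraction.
#
# The Volmer form for the LE branch and the logistic squeeze-out are
# modelling choices of this package, selected as the simplest forms that
# reproduce the qualitative shapes and landmark values of real data.
# Every generator is a pure function of (parameters, seed).

#' Lipid equation-of-state parameters
#'
#' Parameters of the piecewise lipid isotherm model: a (numerically
#' invertible) zero-pressure gas tail, a Volmer liquid-expanded branch
#' `Pi = kT / (A - omega) - pi_coh`, a near-flat LE-LC plateau starting at
#' `transition_pressure`, and a steep liquid-condensed branch up to
#' `collapse_pressure`.  The `fdppc_like` preset is tuned so that, at
#' 20 degC, the lift-off (0.5 mN/m) falls at 110 A^2/molecule and the
#' plateau onset at 9.0 mN/m.
#'
#' @param preset `"fdppc_like"` or `NULL` to pass explicit values.
#' @param omega Excluded area per molecule, A^2.
#' @param lift_off_area Area (A^2) at which the Volmer branch reaches
#'   `lift_off_pressure`; fixes the cohesion pressure `pi_coh`.
#' @param lift_off_pressure Pressure defining lift-off (default 0.5 mN/m).
#' @param temperature Temperature in degC.
#' @param transition_pressure Plateau onset pressure `Pi_t` in mN/m.
#' @param plateau_slope Small positive plateau slope in mN/m per A^2
#'   (default 0.02) keeping `A(Pi)` invertible, as in real plateaus.
#' @param lc_slope Steep LC-branch slope in mN/m per A^2.
#' @param lc_onset_area Area at which the LC branch takes over, A^2.
#' @param collapse_pressure Collapse pressure in mN/m.
#' @return A `lipid_eos_params` list, including the derived `pi_coh` and
#'   the derived Volmer/plateau junction area `transition_area`.
#' @export
lipid_eos_params <- function(preset = "fdppc_like",
                             omega = 50, lift_off_area = 110,
                             lift_off_pressure = 0.5, temperature = 20,
                             transition_pressure = 9.0,
                             plateau_slope = 0.02, lc_slope = 3.0,
                             lc_onset_area = 60, collapse_pressure = 55) {
  if (!is.null(preset) && !identical(preset, "fdppc_like")) {
    lm_stop("langmuir_argument", sprintf("unknown lipid preset '%s'", preset))
  }
  kT <- thermal_energy(temperature)
  pi_coh <- kT / (lift_off_area - omega) - lift_off_pressure
  transition_area <- omega + kT / (transition_pressure + pi_coh)
  p <- list(
    preset = preset %||% "custom", omega = omega,
    lift_off_area = lift_off_area, lift_off_pressure = lift_off_pressure,
    pi_coh = pi_coh, temperature = temperature,
    transition_pressure = transition_pressure,
    plateau_slope = plateau_slope, lc_slope = lc_slope,
    lc_onset_area = lc_onset_area, collapse_pressure = collapse_pressure,
    transition_area = transition_area
  )
  if (omega <= 0 || pi_coh <= 0) {
    lm_stop("langmuir_parameter", "omega and derived pi_coh must be positive")
  }
  if (plateau_slope <= 0 || plateau_slope >= lc_slope) {
    lm_stop("langmuir_parameter", "need 0 < plateau_slope < lc_slope")
  }
  if (transition_pressure >= collapse_pressure) {
    lm_stop("langmuir_parameter",
            "transition_pressure must lie below collapse_pressure")
  }
  if (lc_onset_area >= transition_area) {
    lm_stop("langmuir_parameter",
            "lc_onset_area must lie below the Volmer/plateau junction")
  }
  structure(p, class = "lipid_eos_params")
}

#' Polymer film parameters
#'
#' Parameters of the polymer isotherm model
#' `A(Pi) = residual + (A_surf(Pi) - residual) * f_keep(Pi)` with the
#' compressible pancake-to-brush profile
#' `A_surf(Pi) = pancake_area / (1 + Pi / brush_transition_pressure)^2`
#' and the logistic squeeze-out retention
#' `f_keep(Pi) = 1 / (1 + exp((Pi - squeeze_out_pressure) / squeeze_width))`.
#' Presets `gp_like` and `fgp_like` carry squeeze-out pressures of 32.5
#' and 42.4 mN/m, the exclusion pressures of an amphiphilic triblock
#' copolymer without and with perfluoroalkyl end caps.
#'
#' @param preset `"gp_like"`, `"fgp_like"` or `NULL` for explicit values.
#' @param pancake_area Area per molecule in the pancake regime, A^2
#'   (large; default 2500).
#' @param brush_transition_pressure Pressure scale (mN/m) of the
#'   pancake-to-brush area decay (default 8).
#' @param squeeze_out_pressure Centre of the squeeze-out sigmoid, mN/m.
#' @param squeeze_width Width of the squeeze-out sigmoid, mN/m
#'   (default 0.5; squeeze-out completes within ~2 mN/m, matching the
#'   sharp coincidence of mixed and pure isotherms).
#' @param residual_area Interfacial area retained after squeeze-out, A^2.
#' @return A `polymer_film_params` list.
#' @export
polymer_film_params <- function(preset = NULL, pancake_area = 2500,
                                brush_transition_pressure = 8,
                                squeeze_out_pressure = 32.5,
                                squeeze_width = 0.5, residual_area = 5) {
  if (!is.null(preset)) {
    squeeze_out_pressure <- switch(preset,
      gp_like = 32.5,
      fgp_like = 42.4,
      lm_stop("langmuir_argument", sprintf("unknown polymer preset '%s'", preset))
    )
  }
  if (pancake_area <= 10 * residual_area) {
    lm_stop("langmuir_parameter",
            "pancake_area must greatly exceed residual_area")
  }
  if (squeeze_out_pressure <= brush_transition_pressure) {
    lm_stop("langmuir_parameter",
            "squeeze_out_pressure must exceed brush_transition_pressure")
  }
  if (squeeze_width <= 0) {
    lm_stop("langmuir_parameter", "squeeze_width must be positive")
  }
  structure(
    list(preset = preset %||% "custom", pancake_area = pancake_area,
         brush_transition_pressure = brush_transition_pressure,
         squeeze_out_pressure = squeeze_out_pressure,
         squeeze_width = squeeze_width, residual_area = residual_area),
    class = "polymer_film_params"
  )
}

lipid_eos_pressure <- function(area, p) {
  kT <- thermal_energy(p$temperature)
  # junction areas
  a_tail <- p$omega + kT / (p$pi_coh + 0.01)  # Volmer pressure = 0.01
  a_t <- p$transition_area
  plateau_end_pressure <- p$transition_pressure +
    p$plateau_slope * (a_t - p$lc_onset_area)
  out <- numeric(length(area))
  tail <- area > a_tail
  le <- !tail & area > a_t
  pl <- !tail & !le & area > p$lc_onset_area
  lc <- !tail & !le & !pl
  # "zero-pressure" gas tail: exponentially decaying below the 0.01 mN/m
  # noise floor, strictly increasing under compression so that A(Pi)
  # stays invertible
  out[tail] <- 0.01 * exp(-(area[tail] - a_tail) / 3)
  out[le] <- kT / (area[le] - p$omega) - p$pi_coh
  out[pl] <- p$transition_pressure + p$plateau_slope * (a_t - area[pl])
  out[lc] <- plateau_end_pressure + p$lc_slope * (p$lc_onset_area - area[lc])
  out
}

polymer_film_area <- function(pressure, p) {
  a_surf <- p$pancake_area / (1 + pressure / p$brush_transition_pressure)^2
  f_keep <- 1 / (1 + exp((pressure - p$squeeze_out_pressure) / p$squeeze_width))
  # the 0.002 A^2 per mN/m term is a tiny residual compressibility of the
  # squeezed-out film: it keeps the area strictly decreasing (numerically
  # invertible), in the same spirit as the lipid plateau slope
  p$residual_area + (a_surf - p$residual_area) * f_keep +
    0.002 * (60 - pressure)
}

ground_truth <- function(generator, params, ...) {
  structure(c(list(generator = generator, params = params), list(...)),
            class = "langmuir_ground_truth")
}

#' Retrieve the ground-truth record of a simulated object
#'
#' @param x Any object produced by a `simulate_*` generator.
#' @return The ground-truth record (list), or `NULL` if absent.
#' @export
get_ground_truth <- function(x) attr(x, "ground_truth", exact = TRUE)

#' Simulate a lipid compression isotherm
#'
#' Builds the piecewise lipid curve described in [lipid_eos_params()] on a
#' uniform area grid from `area_max` down to the collapse area, then adds
#' Gaussian pressure noise (pressure is the measured quantity on a film
#' balance; areas are set by the barrier program).  Deterministic per
#' seed; the noiseless curve passes [monotonize()] unchanged.
#'
#' @param params A [lipid_eos_params()] record.
#' @param n_points Number of samples (default 200).
#' @param noise_sd_pressure Gaussian pressure noise SD in mN/m (default 0).
#' @param seed RNG seed; required whenever `noise_sd_pressure > 0`.
#' @param area_max Largest area sampled, A^2 (default 130).
#' @return An [isotherm_curve()] carrying a ground-truth attribute with
#'   the generating parameters, the exact lift-off area, and the plateau
#'   onset pressure (see [get_ground_truth()]).
#' @export
simulate_lipid_isotherm <- function(params = lipid_eos_params(),
                                    n_points = 200L,
                                    noise_sd_pressure = 0, seed = NULL,
                                    area_max = 130) {
  stopifnot(inherits(params, "lipid_eos_params"))
  if (noise_sd_pressure > 0 && is.null(seed)) {
    lm_stop("langmuir_argument", "a seed is required when noise_sd_pressure > 0")
  }
  plateau_end_pressure <- params$transition_pressure +
    params$plateau_slope * (params$transition_area - params$lc_onset_area)
  area_min <- params$lc_onset_area -
    (params$collapse_pressure - plateau_end_pressure) / params$lc_slope
  if (area_min <= 0 || area_min >= area_max) {
    lm_stop("langmuir_parameter", "inconsistent area range for these parameters")
  }
  area <- seq(area_max, area_min, length.out = n_points)
  pressure <- lipid_eos_pressure(area, params)
  if (any(diff(pressure) <= 0)) {
    lm_stop("langmuir_parameter",
            "non-monotone construction: check branch junction parameters")
  }
  if (noise_sd_pressure > 0) {
    pressure <- with_seed(seed,
      pressure + stats::rnorm(n_points, sd = noise_sd_pressure))
    pressure <- pmax(pressure, -0.5)
  }
  curve <- isotherm_curve(area, pressure, convention = "per_molecule",
                         temperature = params$temperature,
                         label = sprintf("simulated lipid (%s)", params$preset))
  attr(curve, "ground_truth") <- ground_truth(
    "simulate_lipid_isotherm", unclass(params),
    lift_off_area = params$lift_off_area,
    lift_off_threshold = params$lift_off_pressure,
    transition_pressure = params$transition_pressure,
    noise_sd_pressure = noise_sd_pressure, seed = seed
  )
  curve
}

#' Simulate a polymer compression isotherm
#'
#' Area decays from the pancake regime through a compressible brush
#' plateau, then drops sigmoidally to `residual_area` centred at
#' `squeeze_out_pressure` (see [polymer_film_params()]).  Samples are
#' placed on a uniform pressure grid and reported in compression order.
#'
#' @param params A [polymer_film_params()] record.
#' @param n_points Number of samples (default 200).
#' @param noise_sd_pressure Gaussian pressure noise SD in mN/m.
#' @param seed RNG seed; required whenever `noise_sd_pressure > 0`.
#' @param pressure_max Largest pressure sampled, mN/m (default 50).
#' @return An [isotherm_curve()] with ground-truth attribute.
#' @export
simulate_polymer_isotherm <- function(params = polymer_film_params("gp_like"),
                                      n_points = 200L,
                                      noise_sd_pressure = 0, seed = NULL,
                                      pressure_max = 50) {
  stopifnot(inherits(params, "polymer_film_params"))
  if (noise_sd_pressure > 0 && is.null(seed)) {
    lm_stop("langmuir_argument", "a seed is required when noise_sd_pressure > 0")
  }
  pressure <- seq(0.02, pressure_max, length.out = n_points)
  area <- polymer_film_area(pressure, params)
  if (noise_sd_pressure > 0) {
    pressure <- with_seed(seed,
      pressure + stats::rnorm(n_points, sd = noise_sd_pressure))
    pressure <- pmax(pressure, -0.5)
  }
  curve <- isotherm_curve(area, pressure, convention = "per_molecule",
                         temperature = 20,
                         label = sprintf("simulated polymer (%s)", params$preset))
  attr(curve, "ground_truth") <- ground_truth(
    "simulate_polymer_isotherm", unclass(params),
    squeeze_out_pressure = params$squeeze_out_pressure,
    noise_sd_pressure = noise_sd_pressure, seed = seed
  )
  curve
}

#' Gaussian excess-area profile
#'
#' Convenience constructor for the excess profile `E(Pi)` consumed by
#' [simulate_mixed_isotherm()]: a Gaussian bump
#' `E(Pi) = amplitude * exp(-(Pi - center)^2 / (2 * width^2))` in A^2 per
#' lipid, the simplest shape for a non-ideality that peaks in the LE-LC
#' coexistence region and fades at high pressure.
#'
#' @param amplitude Peak excess area, A^2 per lipid (default 15).
#' @param center Pressure of the peak, mN/m (default 12).
#' @param width Gaussian width, mN/m (default 5).
#' @return A function of pressure.
#' @export
gaussian_excess <- function(amplitude = 15, center = 12, width = 5) {
  force(amplitude); force(center); force(width)
  function(pressure) amplitude * exp(-(pressure - center)^2 / (2 * width^2))
}

#' Simulate a co-spread mixed-film isotherm (per lipid)
#'
#' Constructs the per-lipid mixed isotherm
#' `A_mix(Pi) = A_lipid(Pi) + (x_p / x_l) * A_polymer(Pi) + E(Pi)`
#' on a pressure grid inside the overlap of both pure curves.  With
#' `E = 0` this is exactly the additivity rule expressed per lipid (the
#' polymer term carries the squeeze-out through the polymer curve); a
#' non-zero `E` programs a known excess area of mixing.  Gaussian pressure
#' noise is added after construction.
#'
#' @param lipid,polymer Monotonized per-molecule pure-component curves.
#' @param mix A [mole_fractions()] specification with `x_polymer > 0`.
#' @param excess_profile `NULL` (ideal) or a function `E(Pi)` in A^2 per
#'   lipid, e.g. [gaussian_excess()].
#' @param noise_sd_pressure Gaussian pressure noise SD in mN/m.
#' @param seed RNG seed; required whenever `noise_sd_pressure > 0`.
#' @param n_points Number of grid points (default 300).
#' @param pressure_range Optional `c(lo, hi)` inside the overlap.
#' @return A `per_lipid` [isotherm_curve()] whose ground truth records the
#'   excess profile values and the polymer squeeze-out pressure.
#' @export
simulate_mixed_isotherm <- function(lipid, polymer, mix,
                                    excess_profile = NULL,
                                    noise_sd_pressure = 0, seed = NULL,
                                    n_points = 300L, pressure_range = NULL) {
  stopifnot(inherits(lipid, "isotherm_curve"),
            inherits(polymer, "isotherm_curve"),
            inherits(mix, "mixture_spec"))
  assert_monotonized(lipid, "simulate_mixed_isotherm")
  assert_monotonized(polymer, "simulate_mixed_isotherm")
  if (mix$x_polymer <= 0) {
    lm_stop("langmuir_argument", "mixture must contain polymer (x_polymer > 0)")
  }
  if (noise_sd_pressure > 0 && is.null(seed)) {
    lm_stop("langmuir_argument", "a seed is required when noise_sd_pressure > 0")
  }
  lo <- max(min(lipid$pressure), min(polymer$pressure))
  hi <- min(max(lipid$pressure), max(polymer$pressure))
  if (!is.null(pressure_range)) {
    if (pressure_range[1L] < lo - 1e-9 || pressure_range[2L] > hi + 1e-9) {
      lm_stop("langmuir_out_of_range",
              "requested pressure_range exceeds the overlap of the pure curves")
    }
    lo <- pressure_range[1L]
    hi <- pressure_range[2L]
  }
  if (hi <= lo) lm_stop("langmuir_out_of_range", "pure curves share no pressure range")
  grid <- seq(lo, hi, length.out = n_points)
  e_fun <- excess_profile %||% function(p) rep(0, length(p))
  e_vals <- e_fun(grid)
  a_mix <- area_at_pressure(lipid, grid) +
    (mix$x_polymer / mix$x_lipid) * area_at_pressure(polymer, grid) +
    e_vals
  pressure <- grid
  if (noise_sd_pressure > 0) {
    pressure <- with_seed(seed,
      pressure + stats::rnorm(n_points, sd = noise_sd_pressure))
    pressure <- pmax(pressure, -0.5)
  }
  curve <- isotherm_curve(a_mix, pressure, convention = "per_lipid",
                         temperature = lipid$temperature,
                         label = sprintf("simulated mixed film %s", mix$ratio))
  gt_poly <- get_ground_truth(polymer)
  attr(curve, "ground_truth") <- ground_truth(
    "simulate_mixed_isotherm",
    list(mixture = unclass(mix), noise_sd_pressure = noise_sd_pressure,
         seed = seed),
    pressure_grid = grid, excess_values = e_vals,
    excess_peak = max(e_vals),
    squeeze_out_pressure = if (!is.null(gt_poly)) gt_poly$squeeze_out_pressure
  )
  curve
}

#' Adsorption-series presets
#'
#' Linear Delta Pi decline parameters for the two polymer archetypes: the
#' slope ties the zero-coverage intercept `Delta Pi(0)` to the equilibrium
#' adsorption pressure of the bare air-water surface (13 mN/m without,
#' 24 mN/m with perfluoroalkyl end caps at 200 nM), divided by the
#' exclusion pressure (32.5 / 42.4 mN/m).
#'
#' @param preset `"gp_like"` or `"fgp_like"`.
#' @return List with `exclusion_pressure` and `slope_magnitude`.
#' @export
adsorption_params <- function(preset = c("fgp_like", "gp_like")) {
  preset <- match.arg(preset)
  switch(preset,
    gp_like = list(preset = preset, exclusion_pressure = 32.5,
                   slope_magnitude = 13 / 32.5),
    fgp_like = list(preset = preset, exclusion_pressure = 42.4,
                    slope_magnitude = 24 / 42.4)
  )
}

#' Simulate a polymer adsorption trace
#'
#' The equilibrium pressure increase declines linearly to zero at the
#' exclusion pressure, `Delta Pi_eq = max(0, slope_magnitude *
#' (exclusion_pressure - pi_ini))`, and the approach to equilibrium is a
#' double-exponential rise:
#' `Pi(t) = pi_ini + Delta Pi_eq * (fast_share * (1 - exp(-t/tau_fast)) +
#' (1 - fast_share) * (1 - exp(-t/tau_slow)))` plus Gaussian noise.
#'
#' @param pi_ini Initial surface pressure, mN/m (>= 0).
#' @param exclusion_pressure True exclusion pressure, mN/m.
#' @param slope_magnitude Delta Pi decline per unit Pi_ini (dimensionless).
#' @param tau_fast,tau_slow Time constants in s (default 30 and 600).
#' @param fast_share Fraction of the rise carried by the fast process.
#' @param noise_sd Gaussian pressure noise SD in mN/m.
#' @param duration Trace duration in s (default 3600, i.e. 6x tau_slow).
#' @param n_points Number of samples (default 240).
#' @param seed RNG seed; required whenever `noise_sd > 0`.
#' @return An [adsorption_trace()] with ground-truth attribute carrying
#'   the true `delta_pi_eq`, time constants and exclusion pressure.
#' @export
simulate_adsorption_trace <- function(pi_ini, exclusion_pressure = 42.4,
                                      slope_magnitude = 24 / 42.4,
                                      tau_fast = 30, tau_slow = 600,
                                      fast_share = 0.6, noise_sd = 0,
                                      duration = 3600, n_points = 240L,
                                      seed = NULL) {
  if (pi_ini < 0 || exclusion_pressure <= 0 || slope_magnitude <= 0 ||
      tau_fast <= 0 || tau_slow <= 0 || fast_share < 0 || fast_share > 1 ||
      duration <= 0) {
    lm_stop("langmuir_argument", "negative or out-of-range trace parameter")
  }
  if (tau_fast >= tau_slow) {
    lm_stop("langmuir_argument", "tau_fast must be smaller than tau_slow")
  }
  if (noise_sd > 0 && is.null(seed)) {
    lm_stop("langmuir_argument", "a seed is required when noise_sd > 0")
  }
  t <- seq(0, duration, length.out = n_points)
  dpi_eq <- max(0, slope_magnitude * (exclusion_pressure - pi_ini))
  p <- pi_ini + dpi_eq * (fast_share * (1 - exp(-t / tau_fast)) +
                            (1 - fast_share) * (1 - exp(-t / tau_slow)))
  if (noise_sd > 0) {
    p <- with_seed(seed, p + stats::rnorm(n_points, sd = noise_sd))
  }
  tr <- adsorption_trace(t, p, pi_ini = pi_ini,
                         label = sprintf("simulated adsorption Pi_ini=%g", pi_ini))
  attr(tr, "ground_truth") <- ground_truth(
    "simulate_adsorption_trace",
    list(pi_ini = pi_ini, exclusion_pressure = exclusion_pressure,
         slope_magnitude = slope_magnitude, tau_fast = tau_fast,
         tau_slow = tau_slow, fast_share = fast_share,
         noise_sd = noise_sd, duration = duration, seed = seed),
    delta_pi_eq = dpi_eq, tau = c(tau_fast, tau_slow),
    exclusion_pressure = exclusion_pressure
  )
  tr
}

# Rasterize one harmonically perturbed elliptical dark domain into `mask`.
rasterize_domain <- function(mask, cx, cy, r0, harm) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  rmax <- r0 * (1 + sum(abs(harm$amp)))
  i0 <- max(1L, floor(cy - rmax)); i1 <- min(nr, ceiling(cy + rmax))
  j0 <- max(1L, floor(cx - rmax)); j1 <- min(nc, ceiling(cx + rmax))
  if (i0 > i1 || j0 > j1) return(mask)
  ii <- i0:i1
  jj <- j0:j1
  dy <- matrix(ii - cy, length(ii), length(jj))
  dx <- matrix(jj - cx, length(ii), length(jj), byrow = TRUE)
  rho <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  rb <- r0 * (1 + Reduce(`+`, Map(
    function(a, k, ph) a * cos(k * theta + ph),
    harm$amp, harm$k, harm$phase
  ), accumulate = FALSE))
  mask[ii, jj] <- mask[ii, jj] | (rho <= rb)
  mask
}

#' Simulate an epifluorescence micrograph with known domain coverage
#'
#' Places `n_domains` non-overlapping, harmonically perturbed elliptical
#' dark domains on a jittered grid (one domain per cell, so arbitrary
#' coverage up to dense packing is attainable), then rescales the domain
#' radii until the realized mask fraction lies within 0.005 of
#' `target_phi`.  The realized mask and its exact fraction are recorded in
#' the ground truth.  Intensities are `background` for the bright
#' (LE/polymer) phase and `background - contrast` inside dark LC domains,
#' plus optional Gaussian noise.
#'
#' @param width,height Image size in pixels (default 256 x 256).
#' @param target_phi Target dark-area fraction in [0, 0.9].
#' @param n_domains Number of domains (default 25).
#' @param shape_irregularity Relative amplitude of the harmonic boundary
#'   perturbation (default 0.2).
#' @param contrast Intensity difference between phases (default 160).
#' @param background Bright-phase intensity (default 200).
#' @param noise_sd Gaussian intensity noise SD (default 0).
#' @param seed RNG seed (required: placement is random).
#' @return A [micrograph()] whose ground truth carries the true mask and
#'   exact area fraction.
#' @export
simulate_micrograph <- function(width = 256L, height = 256L,
                                target_phi = 0.5, n_domains = 25L,
                                shape_irregularity = 0.2, contrast = 160,
                                background = 200, noise_sd = 0,
                                seed = 1L) {
  if (target_phi < 0 || target_phi > 0.9) {
    lm_stop("langmuir_argument", "target_phi must lie in [0, 0.9]")
  }
  if (n_domains < 0) lm_stop("langmuir_argument", "n_domains must be >= 0")
  if (contrast <= 0 || background <= contrast) {
    lm_stop("langmuir_argument",
            "need contrast > 0 and background > contrast (non-negative intensities)")
  }
  build <- function() {
    mask <- matrix(FALSE, height, width)
    if (target_phi > 0 && n_domains > 0) {
      g <- ceiling(sqrt(n_domains))
      cell_w <- width / g
      cell_h <- height / g
      cells <- sample(g * g)[seq_len(n_domains)]
      r0 <- sqrt(target_phi * width * height / (n_domains * pi))
      rmax_cell <- 0.5 * min(cell_w, cell_h)
      harms <- lapply(seq_len(n_domains), function(i) {
        k <- sample(2:5, 2)
        amp_raw <- stats::runif(2, 0.3, 1)
        amp <- shape_irregularity * amp_raw / sum(amp_raw)
        list(k = k, amp = amp, phase = stats::runif(2, 0, 2 * pi))
      })
      centers <- lapply(seq_len(n_domains), function(i) {
        cell <- cells[i] - 1L
        gx <- cell %% g
        gy <- cell %/% g
        slack <- max(0, rmax_cell - r0 * (1 + shape_irregularity))
        jit <- stats::runif(2, -0.8, 0.8) * slack
        c(cx = (gx + 0.5) * cell_w + jit[1L],
          cy = (gy + 0.5) * cell_h + jit[2L])
      })
      scale_max <- rmax_cell / (r0 * (1 + shape_irregularity))
      render <- function(scale) {
        m <- matrix(FALSE, height, width)
        for (i in seq_len(n_domains)) {
          m <- rasterize_domain(m, centers[[i]]["cx"], centers[[i]]["cy"],
                                r0 * scale, harms[[i]])
        }
        m
      }
      # phi(scale) is monotone in the radius scale: bracket, then bisect
      lo_s <- 0.05
      hi_s <- scale_max
      mask <- render(hi_s)
      phi <- sum(mask) / length(mask)
      if (phi + 0.005 < target_phi) {
        lm_stop("langmuir_packing", sprintf(
          "target_phi %.3g unattainable with %d non-overlapping domains (max %.3g)",
          target_phi, n_domains, phi
        ))
      }
      for (iter in seq_len(30L)) {
        mid <- (lo_s + hi_s) / 2
        mask <- render(mid)
        phi <- sum(mask) / length(mask)
        if (abs(phi - target_phi) <= 0.004) break
        if (phi < target_phi) lo_s <- mid else hi_s <- mid
      }
      phi <- sum(mask) / length(mask)
      if (abs(phi - target_phi) > 0.005) {
        lm_stop("langmuir_packing", sprintf(
          "could not reach target_phi %.3g (achieved %.3g)", target_phi, phi
        ))
      }
    }
    img <- matrix(background, height, width) - contrast * mask
    if (noise_sd > 0) {
      img <- img + stats::rnorm(length(img), sd = noise_sd)
      img <- pmax(img, 0)
    }
    list(mask = mask, img = img)
  }
  res <- with_seed(seed, build())
  out <- micrograph(res$img, label = sprintf("simulated micrograph phi=%g",
                                             target_phi))
  attr(out, "ground_truth") <- ground_truth(
    "simulate_micrograph",
    list(width = width, height = height, target_phi = target_phi,
         n_domains = n_domains, shape_irregularity = shape_irregularity,
         contrast = contrast, background = background, noise_sd = noise_sd,
         seed = seed),
    mask = res$mask, phi = sum(res$mask) / length(res$mask)
  )
  out
}

#' Write a ground-truth record as a JSON sidecar
#'
#' Every generated artifact file should travel with the record needed to
#' recompute its expected analysis results.  Matrices (e.g. the true image
#' mask) are stored as nested arrays.
#'
#' @param gt A ground-truth record (see [get_ground_truth()]), or an
#'   object carrying one.
#' @param path Output path (conventionally `<data file>.truth.json`).
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  if (!inherits(gt, "langmuir_ground_truth")) {
    gt2 <- get_ground_truth(gt)
    if (is.null(gt2)) {
      lm_stop("langmuir_argument", "object carries no ground-truth record")
    }
    gt <- gt2
  }
  jsonlite::write_json(unclass(gt), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
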