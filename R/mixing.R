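# Ideal-mixing additivity rule, excess area of mixing, per-lipid area
# shifts, and squeeze-out / convergence pressures for co-spread
# lipid-polymer films.
#
# Convention discipline: the additivity rule is evaluated per total
# molecule and only then converted per lipid for comparison with
# experimental per-lipid isotherms.  Mixing per-lipid with per-molecule
# curves raises a convention error.

#' Mole fractions of a binary lipid-polymer film
#'
#' @param lipid_count,polymer_count Mole counts of the two components,
#'   e.g. `mole_fractions(10, 1)` for a 10:1 lipid:polymer film.
#'   `polymer_count = 0` gives the pure-lipid limit.
#' @return A `mixture_spec`: list with `lipid_count`, `polymer_count`,
#'   `x_lipid`, `x_polymer` (mole fractions summing exactly to 1) and a
#'   `ratio` label.
#' @export
mole_fractions <- function(lipid_count, polymer_count) {
  if (!is.numeric(lipid_count) || length(lipid_count) != 1L ||
      lipid_count <= 0) {
    lm_stop("langmuir_argument", "lipid count must be a positive number")
  }
  if (!is.numeric(polymer_count) || length(polymer_count) != 1L ||
      polymer_count < 0) {
    lm_stop("langmuir_argument", "polymer count must be non-negative")
  }
  total <- lipid_count + polymer_count
  x_p <- polymer_count / total
  structure(
    list(lipid_count = lipid_count, polymer_count = polymer_count,
         x_lipid = 1 - x_p, x_polymer = x_p,
         ratio = sprintf("%g:%g", lipid_count, polymer_count)),
    class = "mixture_spec"
  )
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat(sprintf("<mixture_spec> %s (x_lipid = %.6g, x_polymer = %.6g)\n",
              x$ratio, x$x_lipid, x$x_polymer))
  invisible(x)
}

assert_convention <- function(curve, convention, op) {
  if (!identical(curve$convention, convention)) {
    lm_stop("langmuir_convention", sprintf(
      "%s requires a %s curve, got %s", op, convention, curve$convention
    ))
  }
}

#' Calculated isotherm of an ideally mixing film
#'
#' The additivity rule for an ideal (or fully demixed) binary film predicts
#' the mean molecular area at each surface pressure as the mole-fraction
#' weighted sum of the pure-component areas:
#' `A_calc(Pi) = x_polymer * A_polymer(Pi) + x_lipid * A_lipid(Pi)`.
#' Deviations of the experimental curve from this prediction define the
#' excess area of mixing (see [excess_area_of_mixing()]).
#'
#' @param lipid,polymer Monotonized per-molecule [isotherm_curve()]s of the
#'   pure components.
#' @param mix A [mole_fractions()] specification.
#' @param pressure_grid Strictly increasing pressures (mN/m) inside the
#'   overlap of both curves' pressure ranges.
#' @return A per-molecule `isotherm_curve` sampled on `pressure_grid`.
#' @export
ideal_additive_isotherm <- function(lipid, polymer, mix, pressure_grid) {
  stopifnot(inherits(lipid, "isotherm_curve"),
            inherits(polymer, "isotherm_curve"),
            inherits(mix, "mixture_spec"))
  assert_convention(lipid, "per_molecule", "ideal_additive_isotherm")
  assert_convention(polymer, "per_molecule", "ideal_additive_isotherm")
  assert_monotonized(lipid, "ideal_additive_isotherm")
  assert_monotonized(polymer, "ideal_additive_isotherm")
  pressure_grid <- as.numeric(pressure_grid)
  if (is.unsorted(pressure_grid, strictly = TRUE)) {
    lm_stop("langmuir_argument", "pressure_grid must be strictly increasing")
  }
  a_l <- area_at_pressure(lipid, pressure_grid)
  a_p <- if (mix$x_polymer > 0) area_at_pressure(polymer, pressure_grid) else 0
  a_calc <- mix$x_lipid * a_l + mix$x_polymer * a_p
  isotherm_curve(a_calc, pressure_grid, convention = "per_molecule",
                 temperature = lipid$temperature,
                 label = sprintf("ideal %s", mix$ratio))
}

#' Convert a per-molecule curve to per-lipid areas
#'
#' Mixed-film isotherms are conventionally plotted with the total film area
#' divided by the lipid count only, so that they can be compared directly
#' with the pure-lipid isotherm.  This rescales areas by `1 / x_lipid`.
#'
#' @param curve A per-molecule [isotherm_curve()].
#' @param mix A [mole_fractions()] specification with `x_lipid > 0`.
#' @return A `per_lipid` isotherm.
#' @export
to_per_lipid <- function(curve, mix) {
  stopifnot(inherits(curve, "isotherm_curve"), inherits(mix, "mixture_spec"))
  assert_convention(curve, "per_molecule", "to_per_lipid")
  if (mix$x_lipid <= 0) {
    lm_stop("langmuir_argument", "x_lipid must be positive for per-lipid areas")
  }
  out <- curve
  out$area <- curve$area / mix$x_lipid
  out$convention <- "per_lipid"
  out
}

#' Convert a per-lipid curve back to per-molecule areas
#'
#' Inverse of [to_per_lipid()].
#'
#' @inheritParams to_per_lipid
#' @param curve A per-lipid [isotherm_curve()].
#' @return A `per_molecule` isotherm.
#' @export
to_per_molecule <- function(curve, mix) {
  stopifnot(inherits(curve, "isotherm_curve"), inherits(mix, "mixture_spec"))
  assert_convention(curve, "per_lipid", "to_per_molecule")
  out <- curve
  out$area <- curve$area * mix$x_lipid
  out$convention <- "per_molecule"
  out
}

excess_area_series <- function(pressures, delta_area, reference, mix,
                               skipped = numeric(0)) {
  structure(
    list(pressures = pressures, delta_area = delta_area,
         reference = reference, mixture = mix, skipped = skipped),
    class = "excess_area_series"
  )
}

#' @export
print.excess_area_series <- function(x, ...) {
  cat(sprintf(
    "<excess_area_series> reference = %s, mixture = %s, %d pressures\n",
    x$reference, if (is.null(x$mixture)) "?" else x$mixture$ratio,
    length(x$pressures)
  ))
  print(data.frame(pressure = x$pressures, delta_area = x$delta_area))
  invisible(x)
}

#' @export
as.data.frame.excess_area_series <- function(x, ...) {
  data.frame(pressure_mN_per_m = x$pressures,
             delta_area_A2_per_lipid = x$delta_area)
}

delta_area_core <- function(curve_a, curve_b, pressures, reference, mix) {
  rng_a <- range(curve_a$pressure)
  rng_b <- range(curve_b$pressure)
  ok <- pressures >= max(rng_a[1], rng_b[1]) &
    pressures <= min(rng_a[2], rng_b[2])
  if (any(!ok)) {
    warning(sprintf(
      "skipping %d pressure(s) outside the shared range: %s",
      sum(!ok), paste(signif(pressures[!ok], 4), collapse = ", ")
    ), call. = FALSE)
  }
  p <- pressures[ok]
  if (is.unsorted(p, strictly = TRUE)) {
    lm_stop("langmuir_argument", "pressures must be strictly increasing")
  }
  da <- area_at_pressure(curve_a, p) - area_at_pressure(curve_b, p)
  excess_area_series(p, da, reference, mix, skipped = pressures[!ok])
}

#' Per-lipid area shift of a mixed film relative to the pure lipid
#'
#' `Delta A(Pi) = A_mix_per_lipid(Pi) - A_lipid(Pi)`: the extra apparent
#' area per lipid molecule caused by polymer residing in the film.  Falls
#' to zero once the polymer is fully squeezed out into the subphase.
#'
#' @param mix_curve_per_lipid Monotonized `per_lipid` mixed-film curve.
#' @param pure_lipid_curve Monotonized pure-lipid curve.
#' @param pressures Query pressures (mN/m), strictly increasing.  Values
#'   outside the shared range are skipped with a warning and recorded in
#'   the result's `skipped` field.
#' @param mix Optional [mole_fractions()] recorded in the result.
#' @return An `excess_area_series` with `reference = "pure_lipid"`.
#' @export
area_shift_vs_lipid <- function(mix_curve_per_lipid, pure_lipid_curve,
                                pressures, mix = NULL) {
  stopifnot(inherits(mix_curve_per_lipid, "isotherm_curve"),
            inherits(pure_lipid_curve, "isotherm_curve"))
  assert_convention(mix_curve_per_lipid, "per_lipid", "area_shift_vs_lipid")
  assert_monotonized(mix_curve_per_lipid, "area_shift_vs_lipid")
  assert_monotonized(pure_lipid_curve, "area_shift_vs_lipid")
  delta_area_core(mix_curve_per_lipid, pure_lipid_curve, pressures,
                  "pure_lipid", mix)
}

#' Excess area of mixing
#'
#' `Delta A(Pi) = A_exp(Pi) - A_calc(Pi)` between the experimental
#' mixed-film isotherm and the ideal-mixing prediction (both per lipid).
#' Positive values mean the film occupies more area than additivity
#' predicts, i.e. the components pack less efficiently together than in
#' their neat phases; negative values beyond the squeeze-out pressure mean
#' polymer has left the interface.
#'
#' @param experimental_per_lipid Monotonized `per_lipid` experimental curve.
#' @param calculated_per_lipid Monotonized `per_lipid` calculated curve
#'   (see [ideal_additive_isotherm()] and [to_per_lipid()]).
#' @inheritParams area_shift_vs_lipid
#' @return An `excess_area_series` with `reference = "calculated_ideal"`.
#' @export
excess_area_of_mixing <- function(experimental_per_lipid,
                                  calculated_per_lipid, pressures,
                                  mix = NULL) {
  stopifnot(inherits(experimental_per_lipid, "isotherm_curve"),
            inherits(calculated_per_lipid, "isotherm_curve"))
  assert_convention(experimental_per_lipid, "per_lipid",
                    "excess_area_of_mixing")
  assert_convention(calculated_per_lipid, "per_lipid",
                    "excess_area_of_mixing")
  assert_monotonized(experimental_per_lipid, "excess_area_of_mixing")
  assert_monotonized(calculated_per_lipid, "excess_area_of_mixing")
  delta_area_core(experimental_per_lipid, calculated_per_lipid, pressures,
                  "calculated_ideal", mix)
}

#' Convergence (complete squeeze-out) pressure of a mixed film
#'
#' Finds the smallest pressure above which the per-lipid area of the mixed
#' film stays within `tolerance` (default 2 A^2, the usual molecular-area
#' uncertainty) of the pure-lipid isotherm, sustained over the whole
#' remaining shared range.  Coincidence of mixed and pure isotherms at high
#' pressure signals complete squeeze-out of the polymer into the subphase.
#' A sustained window rather than a single crossing is required for noise
#' robustness.  An absent convergence (returned as `NA`) is a valid
#' outcome, not an error.
#'
#' @inheritParams area_shift_vs_lipid
#' @param tolerance Area tolerance in A^2 per lipid (default 2).
#' @param n_grid Number of evaluation points across the shared range.
#' @return Convergence pressure in mN/m, or `NA_real_` if `|Delta A|`
#'   never stays below `tolerance` through the end of the overlap.
#' @export
convergence_pressure <- function(mix_curve_per_lipid, pure_lipid_curve,
                                 tolerance = 2.0, n_grid = 400L) {
  stopifnot(inherits(mix_curve_per_lipid, "isotherm_curve"),
            inherits(pure_lipid_curve, "isotherm_curve"))
  assert_convention(mix_curve_per_lipid, "per_lipid", "convergence_pressure")
  assert_monotonized(mix_curve_per_lipid, "convergence_pressure")
  assert_monotonized(pure_lipid_curve, "convergence_pressure")
  if (!is.numeric(tolerance) || tolerance <= 0) {
    lm_stop("langmuir_argument", "tolerance must be positive")
  }
  lo <- max(min(mix_curve_per_lipid$pressure), min(pure_lipid_curve$pressure))
  hi <- min(max(mix_curve_per_lipid$pressure), max(pure_lipid_curve$pressure))
  if (hi <= lo) lm_stop("langmuir_out_of_range", "curves share no pressure range")
  grid <- seq(lo, hi, length.out = n_grid)
  da <- area_at_pressure(mix_curve_per_lipid, grid) -
    area_at_pressure(pure_lipid_curve, grid)
  ok <- abs(da) < tolerance
  if (!ok[n_grid]) return(NA_real_)
  # smallest index from which ok holds to the end
  bad <- which(!ok)
  i <- if (length(bad) == 0L) 1L else max(bad) + 1L
  if (i == 1L) return(grid[1L])
  # refine the |Delta A| = tolerance crossing between i-1 and i
  f <- (tolerance - abs(da[i - 1L])) / (abs(da[i]) - abs(da[i - 1L]))
  if (!is.finite(f)) f <- 1
  f <- min(max(f, 0), 1)
  grid[i - 1L] + f * (grid[i] - grid[i - 1L])
}

#' Peak of an excess-area series
#'
#' Returns the maximum excess area and the pressure at which it occurs.
#' The series is pre-smoothed with a centered running mean (default
#' window 11 samples) before the maximum is taken: a raw pointwise
#' maximum is biased upward wherever `A(Pi)` is near-flat (the LE-LC
#' plateau), because inverting a noisy, nearly horizontal isotherm
#' produces large, spiky area errors.
#'
#' @param series An `excess_area_series` sampled on a reasonably dense
#'   pressure grid.
#' @param smooth_window Running-mean window in samples (default 11; use 1
#'   for the raw maximum).
#' @return List with `peak` (A^2 per lipid) and `pressure` (mN/m).
#' @export
excess_peak <- function(series, smooth_window = 11L) {
  stopifnot(inherits(series, "excess_area_series"))
  sm <- running_mean(series$delta_area, smooth_window)
  i <- which.max(sm)
  list(peak = sm[i], pressure = series$pressures[i])
}

#' Write an excess-area series as a comma-separated table
#'
#' Writes `pressure_mN_per_m,delta_area_A2_per_lipid` rows preceded by
#' `#` metadata naming the reference and mixture.
#'
#' @param series An `excess_area_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_excess_series <- function(series, path) {
  stopifnot(inherits(series, "excess_area_series"))
  lines <- c(
    sprintf("# reference=%s", series$reference),
    sprintf("# mixture=%s",
            if (is.null(series$mixture)) "" else series$mixture$ratio),
    "pressure_mN_per_m,delta_area_A2_per_lipid",
    sprintf("%.10g,%.10g", series$pressures, series$delta_area)
  )
  writeLines(lines, path)
  invisible(path)
}
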