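# Data model and feature extraction for single pressure-area isotherms.
#
# Unit conventions, fixed package-wide: molecular area in A^2 (per molecule
# or per lipid), surface pressure in mN/m, time in s, temperature in deg C.
# Compression order is decreasing area.

#' Construct a pressure-area isotherm
#'
#' An `isotherm_curve` stores one compression run as ordered
#' (area, pressure) samples.  Samples are sorted into compression order
#' (strictly by decreasing area on ties of input order) at construction.
#'
#' @param area Molecular areas in A^2 (per molecule or per lipid, see
#'   `convention`).  All must be positive.
#' @param pressure Surface pressures in mN/m.  Values below -0.5 mN/m (the
#'   instrument noise floor) are rejected.
#' @param convention Either `"per_molecule"` (area divided by the total
#'   number of spread molecules) or `"per_lipid"` (divided by the lipid
#'   count only, the convention used when plotting mixed-film isotherms
#'   against the pure lipid).
#' @param temperature Subphase temperature in deg C (default 20).
#' @param label Free-text label.
#' @return An object of class `isotherm_curve`.
#' @seealso [monotonize()], [area_at_pressure()], [lift_off_area()]
#' @export
isotherm_curve <- function(area, pressure,
                           convention = c("per_molecule", "per_lipid"),
                           temperature = 20, label = "") {
  convention <- match.arg(convention)
  area <- as.numeric(area)
  pressure <- as.numeric(pressure)
  if (length(area) != length(pressure)) {
    lm_stop("langmuir_argument", "area and pressure must have equal length")
  }
  if (length(area) < 2L) {
    lm_stop("langmuir_degenerate_curve", "an isotherm needs at least 2 samples")
  }
  if (!all(is.finite(area)) || !all(is.finite(pressure))) {
    lm_stop("langmuir_argument", "non-finite area or pressure sample")
  }
  if (any(area <= 0)) {
    lm_stop("langmuir_argument", "all molecular areas must be positive")
  }
  if (any(pressure < -0.5)) {
    lm_stop("langmuir_argument",
            "pressure below -0.5 mN/m (instrument noise floor)")
  }
  ord <- order(area, decreasing = TRUE)
  structure(
    list(area = area[ord], pressure = pressure[ord],
         convention = convention, temperature = as.numeric(temperature),
         label = as.character(label)),
    class = "isotherm_curve"
  )
}

#' @export
print.isotherm_curve <- function(x, ...) {
  cat(sprintf(
    "<isotherm_curve> %s\n  %d samples, A in [%.4g, %.4g] A^2 (%s), Pi in [%.4g, %.4g] mN/m, %g degC\n",
    if (nzchar(x$label)) x$label else "(unlabelled)",
    length(x$area), min(x$area), max(x$area), x$convention,
    min(x$pressure), max(x$pressure), x$temperature
  ))
  invisible(x)
}

#' @export
as.data.frame.isotherm_curve <- function(x, ...) {
  data.frame(area = x$area, pressure = x$pressure)
}

n_samples <- function(curve) length(curve$area)

is_monotonized <- function(curve) {
  all(diff(curve$area) < 0) && all(diff(curve$pressure) > 0)
}

assert_monotonized <- function(curve, op) {
  if (!is_monotonized(curve)) {
    lm_stop("langmuir_not_monotonized", sprintf(
      "%s requires a monotonized curve; call monotonize() first", op
    ))
  }
}

#' Enforce monotone compression behaviour on an isotherm
#'
#' Real traces carry pressure noise and occasional back-relaxation dips.
#' `monotonize()` replaces pressure by its running maximum along the
#' compression direction and collapses runs of equal pressure to the
#' largest-area sample (first attainment during compression), so that
#' pressure is strictly increasing and `A(Pi)` is single-valued.  The
#' first-attainment convention places plateau pressures at the transition
#' onset rather than its completion.  The operation is idempotent and never
#' increases the sample count.
#'
#' @param curve An [isotherm_curve()].
#' @return A monotonized `isotherm_curve`.
#' @export
monotonize <- function(curve) {
  stopifnot(inherits(curve, "isotherm_curve"))
  p <- cummax(curve$pressure)
  keep <- c(TRUE, diff(p) > 0)  # first (largest-area) sample of each tie run
  if (sum(keep) < 2L) {
    lm_stop("langmuir_degenerate_curve",
            "fewer than 2 samples survive monotonization")
  }
  out <- curve
  out$area <- curve$area[keep]
  out$pressure <- p[keep]
  out
}

#' Interpolate molecular area at a surface pressure
#'
#' Piecewise-linear interpolation of `A` as a function of `Pi` on a
#' monotonized curve.  Queries outside the sampled pressure range are an
#' error: the package never extrapolates, so downstream mixing analyses
#' restrict themselves to the overlapping pressure range of their inputs.
#'
#' @param curve A monotonized [isotherm_curve()].
#' @param pressure Surface pressure(s) in mN/m.
#' @return Molecular area(s) in A^2, vectorized over `pressure`.
#' @export
area_at_pressure <- function(curve, pressure) {
  stopifnot(inherits(curve, "isotherm_curve"))
  assert_monotonized(curve, "area_at_pressure")
  interp_strict(curve$pressure, curve$area, pressure, what = "pressure")
}

#' Interpolate surface pressure at a molecular area
#'
#' Symmetric counterpart of [area_at_pressure()], used mainly for
#' round-trip consistency checks.
#'
#' @inheritParams area_at_pressure
#' @param area Molecular area(s) in A^2.
#' @return Surface pressure(s) in mN/m.
#' @export
pressure_at_area <- function(curve, area) {
  stopifnot(inherits(curve, "isotherm_curve"))
  assert_monotonized(curve, "pressure_at_area")
  interp_strict(rev(curve$area), rev(curve$pressure), area, what = "area")
}

#' Lift-off area of a compression isotherm
#'
#' The lift-off area is the molecular area at which the surface pressure
#' first deviates from zero during compression.  Operationally the curve is
#' read at the point where pressure first reaches `threshold` (default
#' 0.5 mN/m, the usual pressure uncertainty of a Wilhelmy film balance).
#'
#' Detection is noise-aware: the pressure signal is pre-smoothed with a
#' centered running mean to locate the crossing, and the estimate is then
#' refined by a local straight-line fit of the raw samples inside
#' `refine_halfwidth` A^2 of the crossing.  Running-maximum monotonization
#' clips negative noise excursions and would bias a naive crossing towards
#' larger areas, so `lift_off_area()` deliberately works on the samples as
#' given (monotonized input gives identical results in the noiseless case).
#'
#' @param curve An [isotherm_curve()] (raw or monotonized).
#' @param threshold Pressure threshold in mN/m, must be positive.
#' @param smooth_window Running-mean window (samples) for crossing search.
#' @param refine_halfwidth Half-width in A^2 of the local fit window
#'   (default 4, a bias-variance compromise: wider windows average more
#'   noise but pick up curvature of the LE branch).
#' @return Lift-off area in A^2.
#' @export
lift_off_area <- function(curve, threshold = 0.5, smooth_window = 11L,
                          refine_halfwidth = 4) {
  stopifnot(inherits(curve, "isotherm_curve"))
  if (!is.numeric(threshold) || threshold <= 0) {
    lm_stop("langmuir_argument", "threshold must be positive")
  }
  a <- curve$area
  p <- curve$pressure
  n <- length(a)
  ps <- if (n >= 5L) running_mean(p, smooth_window) else p
  hit <- which(ps >= threshold)
  if (length(hit) == 0L) {
    lm_stop("langmuir_no_lift_off", sprintf(
      "pressure never reaches the lift-off threshold %g mN/m", threshold
    ))
  }
  i <- hit[1L]
  if (i == 1L) return(a[1L])  # curve starts above threshold
  # linear crossing between the bracketing (smoothed) samples
  f <- (threshold - ps[i - 1L]) / (ps[i] - ps[i - 1L])
  a0 <- a[i - 1L] + f * (a[i] - a[i - 1L])
  # refine on raw samples around the crossing
  idx <- which(abs(a - a0) <= refine_halfwidth)
  if (length(idx) >= 5L) {
    fit <- stats::lm.fit(cbind(1, a[idx]), p[idx])
    slope <- fit$coefficients[2L]
    if (is.finite(slope) && slope < 0) {
      a_ref <- (threshold - fit$coefficients[1L]) / slope
      if (abs(a_ref - a0) <= refine_halfwidth) return(unname(a_ref))
    }
  }
  a0
}

#' Compressibility modulus along an isotherm
#'
#' The in-plane compression modulus `Cs^-1 = -A * dPi/dA` (mN/m) is the
#' standard quantitative proxy for monolayer phase state: liquid-expanded
#' branches show moderate values, LE-LC coexistence plateaus values near
#' zero, and condensed branches large values.  The derivative is estimated
#' by a symmetric local quadratic fit (default window 11 samples) and the
#' modulus is returned on the interior grid where the full window fits.
#'
#' @param curve A monotonized [isotherm_curve()].
#' @param window Odd smoothing window length in samples (default 11).
#' @return A data.frame with columns `area`, `pressure`, `cs_inv`.
#' @export
compressibility_modulus <- function(curve, window = 11L) {
  stopifnot(inherits(curve, "isotherm_curve"))
  assert_monotonized(curve, "compressibility_modulus")
  d <- local_quadratic_deriv(curve$area, curve$pressure, window = window)
  keep <- !is.na(d)
  data.frame(
    area = curve$area[keep],
    pressure = curve$pressure[keep],
    cs_inv = -curve$area[keep] * d[keep]
  )
}

#' Locate the LE-LC transition onset
#'
#' In a compression isotherm the onset of the liquid-expanded to
#' liquid-condensed transition appears as a kink followed by a near-flat
#' plateau, i.e. a collapse of the compressibility modulus.  The onset is
#' located as the first interior point (in compression order, past
#' lift-off) whose `Cs^-1` falls below `fraction` (default 0.25) of the
#' running median of the preceding LE branch, sustained for `consecutive`
#' samples for noise robustness.  How such kink points are read off is not
#' standardized; this criterion is the package's documented choice.
#'
#' Like [lift_off_area()], this works on the samples as given: the
#' running-maximum tie collapse of [monotonize()] would decimate a noisy
#' near-flat plateau and bias the local derivative, whereas raw pressure
#' noise is zero-mean and averages out of the local quadratic fit.
#' Monotonized input gives identical results in the noiseless case.  The
#' onset pressure is read from the running-mean smoothed signal.
#'
#' @param curve An [isotherm_curve()] (raw or monotonized) spanning the
#'   transition.
#' @param window Smoothing window passed to [compressibility_modulus()].
#' @param fraction Fraction of the preceding LE-branch median `Cs^-1`
#'   below which a point qualifies as plateau (default 0.25).
#' @param lift_threshold Lift-off threshold in mN/m (default 0.5); points
#'   below it are excluded from the LE reference median.
#' @param consecutive Number of consecutive qualifying samples required.
#' @return An object of class `transition_features`: a list with fields
#'   `found`, `lift_off_area`, `transition_onset_pressure`,
#'   `transition_onset_area`, `plateau_end_area`, `collapse_pressure`.
#'   When no qualifying onset exists, `found` is `FALSE` and the
#'   transition fields are `NA` (no error is thrown).
#' @export
transition_onset <- function(curve, window = 11L, fraction = 0.25,
                             lift_threshold = 0.5, consecutive = 2L) {
  stopifnot(inherits(curve, "isotherm_curve"))
  d <- local_quadratic_deriv(curve$area, curve$pressure, window = window)
  keep <- !is.na(d)
  cm <- data.frame(
    area = curve$area[keep],
    pressure = running_mean(curve$pressure, window)[keep],
    cs_inv = -curve$area[keep] * d[keep]
  )
  lo <- tryCatch(lift_off_area(curve, threshold = lift_threshold),
                 langmuir_no_lift_off = function(e) NA_real_)
  feats <- structure(
    list(found = FALSE, lift_off_area = lo,
         transition_onset_pressure = NA_real_,
         transition_onset_area = NA_real_,
         plateau_end_area = NA_real_,
         collapse_pressure = max(curve$pressure)),
    class = "transition_features"
  )
  live <- which(cm$pressure >= lift_threshold)
  if (length(live) < 6L) return(feats)
  n <- nrow(cm)
  onset <- NA_integer_
  med <- NA_real_
  for (k in seq(6L, length(live))) {
    i <- live[k]
    prev <- live[seq_len(k - 1L)]
    med_k <- stats::median(cm$cs_inv[prev])
    run <- i:min(n, i + consecutive - 1L)
    if (length(run) == consecutive &&
        all(cm$cs_inv[run] < fraction * med_k)) {
      onset <- i
      med <- med_k
      break
    }
  }
  if (is.na(onset)) return(feats)
  feats$found <- TRUE
  feats$transition_onset_pressure <- cm$pressure[onset]
  feats$transition_onset_area <- cm$area[onset]
  after <- which(seq_len(n) > onset & cm$cs_inv >= med)
  if (length(after)) feats$plateau_end_area <- cm$area[after[1L]]
  feats
}

#' @export
print.transition_features <- function(x, ...) {
  cat("<transition_features>\n")
  cat(sprintf("  lift-off area        : %s A^2\n", fmt_num(x$lift_off_area)))
  if (x$found) {
    cat(sprintf("  transition onset Pi_t: %s mN/m at %s A^2\n",
                fmt_num(x$transition_onset_pressure),
                fmt_num(x$transition_onset_area)))
    cat(sprintf("  plateau end area     : %s A^2\n", fmt_num(x$plateau_end_area)))
  } else {
    cat("  no LE-LC transition detected\n")
  }
  cat(sprintf("  max recorded pressure: %s mN/m\n", fmt_num(x$collapse_pressure)))
  invisible(x)
}

# ---- file dialect -----------------------------------------------------------

#' Read an isotherm from a comma-separated file
#'
#' Format: optional `#`-prefixed metadata lines (`# label=`,
#' `# temperature_C=`, `# convention=`), then a header line
#' `area_A2_per_molecule,pressure_mN_per_m` and one sample per line.
#'
#' @param path File path.
#' @return An [isotherm_curve()].
#' @export
read_isotherm <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- parse_meta(meta_lines)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  if (ncol(df) < 2L) lm_stop("langmuir_io", "expected two comma-separated columns")
  isotherm_curve(
    area = df[[1L]], pressure = df[[2L]],
    convention = meta[["convention"]] %||% "per_molecule",
    temperature = as.numeric(meta[["temperature_C"]] %||% 20),
    label = meta[["label"]] %||% ""
  )
}

#' Write an isotherm to a comma-separated file
#'
#' @param curve An [isotherm_curve()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_isotherm <- function(curve, path) {
  stopifnot(inherits(curve, "isotherm_curve"))
  header_col <- if (curve$convention == "per_lipid") {
    "area_A2_per_lipid"
  } else {
    "area_A2_per_molecule"
  }
  lines <- c(
    sprintf("# label=%s", curve$label),
    sprintf("# temperature_C=%.10g", curve$temperature),
    sprintf("# convention=%s", curve$convention),
    sprintf("%s,pressure_mN_per_m", header_col),
    sprintf("%.10g,%.10g", curve$area, curve$pressure)
  )
  writeLines(lines, path)
  invisible(path)
}

parse_meta <- function(lines) {
  out <- list()
  for (ln in lines) {
    ln <- sub("^#\\s*", "", ln)
    if (!grepl("=", ln, fixed = TRUE)) next
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    out[[key]] <- val
  }
  out
}
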