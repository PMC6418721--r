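# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Boltzmann factor kT in monolayer units
#'
#' Converts the thermal energy k_B * T into the unit system used throughout
#' the package, square Angstrom times mN/m (1 A^2 * mN/m = 1e-23 J).  At
#' 20 degrees C this evaluates to 404.7 A^2 mN/m.
#'
#' @param temperature_c Temperature in degrees Celsius.
#' @return Thermal energy in A^2 * mN/m.
#' @export
thermal_energy <- function(temperature_c = 20) {
  stopifnot(is.numeric(temperature_c), temperature_c > -273.15)
  1.380649 * (273.15 + temperature_c)
}

# Classed errors so callers can distinguish failure modes programmatically.
lm_stop <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "langmuir_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

# Evaluate `code` under a fixed RNG state, restoring the caller's state
# afterwards.  All simulator randomness flows through this helper; no
# global seed is ever mutated.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Strictly ordered linear interpolation with hard range checking: monolayer
# analyses must never extrapolate (the polymer isotherm simply ends near its
# squeeze-out), so out-of-range queries are errors, not NA.
interp_strict <- function(x, y, xout, what = "pressure") {
  rng <- range(x)
  bad <- xout < rng[1] - 1e-9 | xout > rng[2] + 1e-9
  if (any(bad)) {
    lm_stop("langmuir_out_of_range", sprintf(
      "%s value(s) %s outside sampled range [%.6g, %.6g]; refusing to extrapolate",
      what, paste(signif(xout[bad], 6), collapse = ", "), rng[1], rng[2]
    ))
  }
  xout <- pmin(pmax(xout, rng[1]), rng[2])
  stats::approx(x, y, xout = xout, ties = "ordered")$y
}

# Centered running mean with shrinking windows at the edges (used for
# pre-smoothing noisy pressure signals before crossing detection).
running_mean <- function(x, window) {
  n <- length(x)
  window <- max(1L, min(as.integer(window), n))
  if (window %% 2L == 0L) window <- window - 1L
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    mean(x[lo:hi])
  }, numeric(1))
}

# Derivative dy/dx at the center of a symmetric window by local quadratic
# least squares (Savitzky-Golay in spirit, but tolerant of slightly
# non-uniform grids).  Returns NA outside the interior grid.
local_quadratic_deriv <- function(x, y, window = 11L) {
  n <- length(x)
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  if (n < window) {
    lm_stop("langmuir_window", sprintf(
      "need at least %d samples for smoothing window %d, got %d",
      window, window, n
    ))
  }
  h <- (window - 1L) %/% 2L
  d <- rep(NA_real_, n)
  for (i in (h + 1L):(n - h)) {
    idx <- (i - h):(i + h)
    xi <- x[idx] - x[i]
    yi <- y[idx]
    X <- cbind(1, xi, xi^2)
    beta <- tryCatch(solve(crossprod(X), crossprod(X, yi)),
                     error = function(e) NULL)
    if (!is.null(beta)) d[i] <- beta[2L]
  }
  d
}

fmt_num <- function(x, digits = 4) formatC(x, format = "g", digits = digits)
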