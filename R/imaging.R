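# Minimal epifluorescence-image analysis: segmentation of condensed (LC)
# domains, area-fraction statistics, and the consistency check between
# observed dark-domain coverage and the coverage predicted from isotherms.
#
# Dark-phase convention: with a probe excluded from the condensed phase
# (RH-DHPE-style imaging) the LC domains appear dark; `invert = TRUE`
# handles probes that accumulate in the LC phase (NBD-DPPE-style), where
# the domains are bright.

#' Construct a micrograph
#'
#' @param intensities Numeric matrix of non-negative grayscale
#'   intensities, at least 16 x 16.
#' @param pixel_size Optional pixel edge length in micrometres.
#' @param label Free-text label.
#' @return An object of class `micrograph`.
#' @export
micrograph <- function(intensities, pixel_size = NA_real_, label = "") {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    lm_stop("langmuir_argument", "intensities must be a numeric matrix")
  }
  if (nrow(intensities) < 16L || ncol(intensities) < 16L) {
    lm_stop("langmuir_argument", "micrograph must be at least 16 x 16 pixels")
  }
  if (!all(is.finite(intensities)) || any(intensities < 0)) {
    lm_stop("langmuir_argument", "intensities must be finite and non-negative")
  }
  structure(
    list(intensities = intensities, pixel_size = pixel_size,
         label = as.character(label)),
    class = "micrograph"
  )
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf(
    "<micrograph> %s\n  %d x %d pixels, intensity in [%.4g, %.4g]%s\n",
    if (nzchar(x$label)) x$label else "(unlabelled)",
    nrow(x$intensities), ncol(x$intensities),
    min(x$intensities), max(x$intensities),
    if (is.na(x$pixel_size)) "" else sprintf(", %.4g um/px", x$pixel_size)
  ))
  invisible(x)
}

#' Otsu's threshold of an intensity sample
#'
#' Classic histogram-based threshold maximizing the between-class
#' variance, computed on a 256-bin histogram over the intensity range.
#'
#' @param x Numeric vector (or matrix) of intensities.
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold value on the intensity scale.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0) {
    lm_stop("langmuir_degenerate_threshold",
            "constant image: Otsu threshold is undefined")
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, n_bins)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 /
    (w0[valid] * w1[valid])
  breaks[which.max(sigma_b) + 1L]
}

#' Segment dark (condensed-phase) domains
#'
#' Produces a binary mask that is `TRUE` where the intensity lies below the
#' threshold (or above it with `invert = TRUE`).  The threshold is chosen
#' by Otsu's method or supplied as a fixed level.
#'
#' @param image A [micrograph()].
#' @param method `"otsu"` or `"fixed"`.
#' @param level Threshold level, required for `method = "fixed"`.
#' @param invert Set `TRUE` when condensed domains are bright (probe
#'   partitioning into the LC phase).
#' @return A logical matrix with attributes `threshold` and `invert`.
#' @export
segment_dark_domains <- function(image, method = c("otsu", "fixed"),
                                 level = NULL, invert = FALSE) {
  stopifnot(inherits(image, "micrograph"))
  method <- match.arg(method)
  thr <- switch(method,
    otsu = otsu_threshold(image$intensities),
    fixed = {
      if (is.null(level) || !is.numeric(level)) {
        lm_stop("langmuir_argument", "method 'fixed' requires a numeric level")
      }
      level
    }
  )
  mask <- if (invert) image$intensities > thr else image$intensities < thr
  attr(mask, "threshold") <- thr
  attr(mask, "invert") <- invert
  mask
}

# Two-pass 8-connectivity labelling (union-find).  Border-touching
# components count like any other.
label_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nxt <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!mask[i, j]) next
      neigh <- integer(0)
      if (i > 1L && mask[i - 1L, j]) neigh <- c(neigh, labels[i - 1L, j])
      if (j > 1L) {
        if (mask[i, j - 1L]) neigh <- c(neigh, labels[i, j - 1L])
        if (i > 1L && mask[i - 1L, j - 1L]) neigh <- c(neigh, labels[i - 1L, j - 1L])
        if (i < nr && mask[i + 1L, j - 1L]) neigh <- c(neigh, labels[i + 1L, j - 1L])
      }
      if (length(neigh) == 0L) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        labels[i, j] <- nxt
      } else {
        roots <- vapply(unique(neigh), find, integer(1))
        r <- min(roots)
        labels[i, j] <- r
        for (rr in roots) parent[rr] <- r
      }
    }
  }
  if (nxt == 0L) return(labels)
  roots <- vapply(seq_len(nxt), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  pos <- labels > 0L
  labels[pos] <- relab[labels[pos]]
  labels
}

#' Domain statistics of a binary mask
#'
#' Area fraction as the exact pixel ratio, plus connected-component count
#' (8-connectivity, border-touching components included) and mean domain
#' area in pixels.
#'
#' @param mask Logical matrix, e.g. from [segment_dark_domains()].
#' @return An object of class `domain_stats`: list with `area_fraction`,
#'   `domain_count`, `mean_domain_area` (`NA` when the mask is empty).
#' @export
domain_stats <- function(mask) {
  if (!is.logical(mask) || !is.matrix(mask)) {
    lm_stop("langmuir_argument", "mask must be a logical matrix")
  }
  phi <- sum(mask) / length(mask)
  labels <- label_components(mask)
  count <- max(labels)
  structure(
    list(area_fraction = phi, domain_count = count,
         mean_domain_area = if (count > 0L) sum(mask) / count else NA_real_),
    class = "domain_stats"
  )
}

#' @export
print.domain_stats <- function(x, ...) {
  cat(sprintf(
    "<domain_stats> phi = %.4f, %d domain(s)%s\n",
    x$area_fraction, x$domain_count,
    if (is.na(x$mean_domain_area)) "" else
      sprintf(", mean area %.4g px^2", x$mean_domain_area)
  ))
  invisible(x)
}

#' Isotherm-predicted condensed-phase coverage
#'
#' Once the LE-LC transition of the lipid is essentially complete, the
#' condensed lipid occupies approximately the pure-lipid area per molecule,
#' while the mixed film's per-lipid area also carries the polymer's share.
#' The predicted dark-domain coverage is therefore
#' `phi_pred = A_pure_lipid(Pi) / A_mix_per_lipid(Pi)`, clamped to [0, 1].
#' Whether the transition is complete at the chosen pressure is the
#' caller's responsibility and is recorded as a flag on the result.
#'
#' @param pressure Surface pressure in mN/m; must lie inside both curves'
#'   sampled ranges.
#' @param pure_lipid Monotonized pure-lipid [isotherm_curve()].
#' @param mix_per_lipid Monotonized `per_lipid` mixed-film curve.
#' @param transition_complete Caller's assertion that the LE-LC transition
#'   is essentially complete at `pressure` (recorded as an attribute).
#' @return Predicted coverage in [0, 1] with attribute
#'   `transition_complete`.
#' @export
predicted_lc_coverage <- function(pressure, pure_lipid, mix_per_lipid,
                                  transition_complete = TRUE) {
  stopifnot(inherits(pure_lipid, "isotherm_curve"),
            inherits(mix_per_lipid, "isotherm_curve"))
  assert_convention(mix_per_lipid, "per_lipid", "predicted_lc_coverage")
  assert_monotonized(pure_lipid, "predicted_lc_coverage")
  assert_monotonized(mix_per_lipid, "predicted_lc_coverage")
  a_pure <- area_at_pressure(pure_lipid, pressure)
  a_mix <- area_at_pressure(mix_per_lipid, pressure)
  phi <- pmin(pmax(a_pure / a_mix, 0), 1)
  attr(phi, "transition_complete") <- isTRUE(transition_complete)
  phi
}

# ---- file dialect -----------------------------------------------------------
# Grayscale images travel as plain-text ASCII PGM (P2), the text-only
# stand-in for 8/16-bit grayscale PNG/TIFF.

#' Read a plain (ASCII, P2) PGM image
#'
#' @param path File path.
#' @param label Optional label for the resulting [micrograph()].
#' @return A [micrograph()].
#' @export
read_pgm <- function(path, label = "") {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  tokens <- scan(text = paste(lines, collapse = " "), what = character(),
                 quiet = TRUE)
  if (tokens[1L] != "P2") {
    lm_stop("langmuir_io", "only plain ASCII PGM (P2) images are supported")
  }
  w <- as.integer(tokens[2L])
  h <- as.integer(tokens[3L])
  vals <- as.numeric(tokens[-(1:4)])
  if (length(vals) != w * h) {
    lm_stop("langmuir_io", sprintf(
      "PGM payload has %d values, expected %d", length(vals), w * h
    ))
  }
  # PGM is row-major top-to-bottom; store rows as matrix rows
  micrograph(matrix(vals, nrow = h, ncol = w, byrow = TRUE), label = label)
}

#' Write a micrograph or mask as plain (ASCII, P2) PGM
#'
#' Logical masks are written with maxval 1; numeric images are rounded to
#' integers.
#'
#' @param x A [micrograph()] or a logical/numeric matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(x, path) {
  m <- if (inherits(x, "micrograph")) x$intensities else x
  if (is.logical(m)) m <- m * 1L
  m <- round(m)
  maxval <- max(1, max(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(m), nrow(m)),
               sprintf("%d", maxval)), con)
  apply(m, 1L, function(row) {
    writeLines(paste(row, collapse = " "), con)
  })
  invisible(path)
}
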