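# Band-level analytics: class-average spectra with SD envelopes, peak
# detection with prominence filtering, named-band heights, the 1655/1444
# lipid-saturation ratio and assignment lookup against a band library.

#' Class-average spectrum with SD envelope
#'
#' Channelwise mean and population standard deviation over all rows of one
#' class.
#'
#' @param dataset A `spectral_dataset`.
#' @param class_label Class to average (must be present in the labels).
#' @return Object of class `average_spectrum`: list with `grid`, `mean`,
#'   `sd`, `n` and `class_label`.
#' @export
class_average <- function(dataset, class_label) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  rows <- which(dataset$labels == class_label)
  if (!length(rows)) stop("unknown class label '", class_label, "'")
  X <- dataset$intensities[rows, , drop = FALSE]
  mu <- colMeans(X)
  sdv <- sqrt(pmax(colMeans(X^2) - mu^2, 0))  # population SD
  structure(list(grid = dataset$grid, mean = mu, sd = sdv,
                 n = length(rows), class_label = class_label,
                 segments = dataset$segments),
            class = "average_spectrum")
}

#' @export
print.average_spectrum <- function(x, ...) {
  cat("average_spectrum:", x$class_label, "(n =", x$n, "spectra,",
      length(x$grid), "channels)\n")
  invisible(x)
}

#' @export
plot.average_spectrum <- function(x, ...) {
  graphics::plot(x$grid, x$mean, type = "n",
                 xlab = expression(paste("Raman shift (", cm^-1, ")")),
                 ylab = "Intensity (a.u.)",
                 main = paste0(x$class_label, " mean spectrum ± SD"), ...)
  graphics::polygon(c(x$grid, rev(x$grid)),
                    c(x$mean + x$sd, rev(x$mean - x$sd)),
                    col = "grey85", border = NA)
  graphics::lines(x$grid, x$mean)
  invisible(x)
}

.spectrum_parts <- function(x, grid) {
  if (inherits(x, "average_spectrum")) list(y = x$mean, grid = x$grid)
  else if (inherits(x, "raman_spectrum")) list(y = x$intensities, grid = x$grid)
  else {
    .check_grid(grid)
    list(y = x, grid = grid)
  }
}

# Topographic prominence of a local maximum: height minus the higher of the
# two valley floors found while walking out until a taller point (or the
# window edge) is met.
.peak_prominence <- function(y, i) {
  left_min <- y[i]
  j <- i - 1
  while (j >= 1 && y[j] <= y[i]) {
    left_min <- min(left_min, y[j])
    j <- j - 1
  }
  if (j < 1) left_base <- min(y[seq_len(i)]) else left_base <- left_min
  right_min <- y[i]
  j <- i + 1
  while (j <= length(y) && y[j] <= y[i]) {
    right_min <- min(right_min, y[j])
    j <- j + 1
  }
  if (j > length(y)) right_base <- min(y[i:length(y)]) else right_base <- right_min
  y[i] - max(left_base, right_base)
}

#' Detect peaks in a spectral window
#'
#' Finds strict local maxima inside a wavenumber window, filters them by
#' topographic prominence (as a fraction of the window maximum), refines the
#' apex position by parabolic interpolation through the three channels around
#' the maximum, and reports positions rounded to the nearest integer cm^-1,
#' sorted by descending height.
#'
#' @param x An `average_spectrum`, `raman_spectrum`, or intensity vector
#'   (baseline-corrected).
#' @param grid Wavenumber grid (vector input only).
#' @param window Length-2 vector `c(lo, hi)` in cm^-1.
#' @param min_prominence Minimum prominence as a fraction of the maximum
#'   intensity inside the window.
#' @return Data frame with columns `position`, `height`, `prominence`.
#' @export
detect_peaks <- function(x, grid = NULL, window = NULL, min_prominence = 0.1) {
  parts <- .spectrum_parts(x, grid)
  y <- parts$y
  g <- parts$grid
  if (is.null(window)) window <- range(g)
  idx <- which(g >= window[1] & g <= window[2])
  if (!length(idx)) stop("empty peak-detection window")
  yw <- y[idx]
  gw <- g[idx]
  n <- length(yw)
  empty <- data.frame(position = numeric(0), height = numeric(0),
                      prominence = numeric(0))
  if (n < 3) return(empty)
  is_max <- which(yw[2:(n - 1)] > yw[1:(n - 2)] &
                  yw[2:(n - 1)] > yw[3:n]) + 1L
  if (!length(is_max)) return(empty)
  wmax <- max(yw)
  prom <- vapply(is_max, function(i) .peak_prominence(yw, i), 0)
  keep <- prom >= min_prominence * wmax
  is_max <- is_max[keep]
  prom <- prom[keep]
  if (!length(is_max)) return(empty)
  pos <- vapply(is_max, function(i) {
    # parabolic apex refinement; degenerate curvature falls back to the grid point
    denom <- yw[i - 1] - 2 * yw[i] + yw[i + 1]
    delta <- if (denom < 0) 0.5 * (yw[i - 1] - yw[i + 1]) / denom else 0
    delta <- max(min(delta, 0.5), -0.5)
    gw[i] + delta * (gw[min(i + 1, n)] - gw[max(i - 1, 1)]) / 2
  }, 0)
  out <- data.frame(position = round(pos), height = yw[is_max],
                    prominence = prom)
  out[order(-out$height), , drop = FALSE]
}

#' Height of a named band
#'
#' Maximum intensity of the (baseline-corrected) spectrum inside the window
#' `center +/- halfwidth`.
#'
#' @inheritParams detect_peaks
#' @param center Nominal band center (cm^-1).
#' @param halfwidth Half-width of the measurement window (cm^-1); the default
#'   10 keeps 1444 distinct from 1460.
#' @return Scalar intensity.
#' @export
band_height <- function(x, grid = NULL, center, halfwidth = 10) {
  parts <- .spectrum_parts(x, grid)
  g <- parts$grid
  if (center - halfwidth < g[1] || center + halfwidth > g[length(g)]) {
    stop("band window [", center - halfwidth, ", ", center + halfwidth,
         "] lies outside the grid span")
  }
  idx <- which(abs(g - center) <= halfwidth)
  max(parts$y[idx])
}

#' Band-height intensity ratio
#'
#' Ratio of two named-band heights, e.g. the 1655/1444 cm^-1 lipid
#' unsaturation index (lower values indicate more saturated lipid).  The
#' ratio is invariant under positive rescaling of the spectrum, so it is
#' unaffected by unit-area normalization.
#'
#' @inheritParams band_height
#' @param numerator_center,denominator_center Band centers (cm^-1).
#' @return Dimensionless ratio.
#' @export
intensity_ratio <- function(x, grid = NULL, numerator_center = 1655,
                            denominator_center = 1444, halfwidth = 10) {
  num <- band_height(x, grid, numerator_center, halfwidth)
  den <- band_height(x, grid, denominator_center, halfwidth)
  if (den == 0) stop("zero denominator band height at ", denominator_center)
  num / den
}

#' Assign detected peaks to library bands
#'
#' Greedy one-to-one matching by nearest wavenumber distance: candidate
#' (peak, band) pairs within `tol` are ranked by distance and assigned in
#' order, each peak and each band at most once.
#'
#' @param peaks Data frame from [detect_peaks()].
#' @param library A [band_library()].
#' @param tol Maximum |peak - band center| distance (cm^-1, > 0).
#' @return `peaks` with added columns `assignment` (NA when unassigned) and
#'   `band_center`.
#' @export
assign_peaks <- function(peaks, library, tol = 5) {
  stopifnot(tol > 0, inherits(library, "band_library"))
  peaks$assignment <- NA_character_
  peaks$band_center <- NA_real_
  if (!nrow(peaks)) return(peaks)
  cand <- expand.grid(pi = seq_len(nrow(peaks)), bi = seq_len(nrow(library)))
  cand$dist <- abs(peaks$position[cand$pi] - library$center[cand$bi])
  cand <- cand[cand$dist <= tol, , drop = FALSE]
  cand <- cand[order(cand$dist, cand$pi, cand$bi), , drop = FALSE]
  used_p <- logical(nrow(peaks))
  used_b <- logical(nrow(library))
  for (k in seq_len(nrow(cand))) {
    p <- cand$pi[k]
    b <- cand$bi[k]
    if (used_p[p] || used_b[b]) next
    used_p[p] <- TRUE
    used_b[b] <- TRUE
    peaks$assignment[p] <- library$assignment[b]
    peaks$band_center[p] <- library$center[b]
  }
  peaks
}

#' Per-class peak report
#'
#' Convenience wrapper: detects peaks on a class average and assigns them
#' against the library; suitable for writing as a delimited table.
#'
#' @param avg An `average_spectrum`.
#' @param library A [band_library()].
#' @param window,min_prominence Passed to [detect_peaks()].
#' @param tol Passed to [assign_peaks()].
#' @return Data frame of assigned peaks.
#' @export
peak_table <- function(avg, library, window = NULL, min_prominence = 0.1,
                       tol = 5) {
  assign_peaks(detect_peaks(avg, window = window,
                            min_prominence = min_prominence),
               library, tol = tol)
}
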