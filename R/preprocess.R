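# Two-stage fluorescence correction and matrix conditioning:
#   1. iterative modified polynomial fitting (gross fluorescence),
#   2. penalized asymmetric least squares on a banded solver (residual
#      baseline + intrinsic smoothing),
# then region selection, unit-area normalization and mean centering.

.intensities <- function(x) {
  if (inherits(x, "raman_spectrum")) x$intensities else x
}

.orth_poly_basis <- function(grid, order) {
  u <- (grid - grid[1]) / (grid[length(grid)] - grid[1])
  qr.Q(qr(outer(u, 0:order, "^")))
}

#' Iterative modified polynomial baseline
#'
#' Fits a polynomial of the given order, replaces the working signal by the
#' elementwise minimum of signal and fit, and repeats until the fit changes
#' by less than `tol` (relative) or `max_iter` is reached.  The result lies
#' at or below the peaks, capturing the broad fluorescence background.
#'
#' @param x Intensity vector or `raman_spectrum`.
#' @param grid Wavenumber grid (ignored when `x` is a `raman_spectrum`).
#' @param order Polynomial order (default 5).
#' @param max_iter Maximum refit iterations.
#' @param tol Convergence threshold on the maximum relative fit change.
#' @param basis Optional precomputed orthonormal basis (internal reuse).
#' @return Baseline vector aligned with the grid.
#' @export
polyfit_baseline <- function(x, grid = NULL, order = 5, max_iter = 100,
                             tol = 1e-6, basis = NULL) {
  if (inherits(x, "raman_spectrum")) {
    grid <- x$grid
    x <- x$intensities
  }
  .check_grid(grid)
  stopifnot(order >= 0, length(grid) > order + 1, max_iter >= 1)
  if (any(!is.finite(x))) stop("input intensities must be finite")
  Q <- if (is.null(basis)) .orth_poly_basis(grid, order) else basis
  y_work <- x
  fit_prev <- NULL
  for (it in seq_len(max_iter)) {
    fit <- drop(Q %*% crossprod(Q, y_work))
    if (!is.null(fit_prev) &&
        max(abs(fit - fit_prev)) / (max(abs(fit_prev)) + 1e-300) < tol) {
      return(fit)
    }
    fit_prev <- fit
    y_work <- pmin(y_work, fit)
  }
  fit_prev
}

# Batch version: same arithmetic as the per-spectrum function, applied
# row-wise with a per-row convergence mask so results match the scalar path.
.polyfit_baseline_matrix <- function(Y, grid, order = 5, max_iter = 100,
                                     tol = 1e-6) {
  .check_grid(grid)
  if (any(!is.finite(Y))) stop("input intensities must be finite")
  Q <- .orth_poly_basis(grid, order)
  out <- matrix(NA_real_, nrow(Y), ncol(Y))
  active <- seq_len(nrow(Y))
  Yw <- Y
  Fprev <- NULL
  for (it in seq_len(max_iter)) {
    Fit <- (Yw[active, , drop = FALSE] %*% Q) %*% t(Q)
    if (!is.null(Fprev)) {
      delta <- apply(abs(Fit - Fprev), 1, max) /
        (apply(abs(Fprev), 1, max) + 1e-300)
      done <- delta < tol
      if (any(done)) {
        out[active[done], ] <- Fit[done, , drop = FALSE]
        Fit <- Fit[!done, , drop = FALSE]
        active <- active[!done]
        if (!length(active)) return(out)
      }
    }
    Fprev <- Fit
    Yw[active, ] <- pmin(Yw[active, , drop = FALSE], Fit)
  }
  out[active, ] <- Fprev
  out
}

#' Penalized asymmetric least-squares (AsLS) baseline
#'
#' Iteratively solves `(W + lam * t(D) %*% D) z = W y` with a
#' second-difference penalty `D` and asymmetric weights: `p` where the
#' residual `y - z` is positive (peaks), `1 - p` elsewhere.  The banded
#' system is factored in compiled code, so the cost is linear in the number
#' of channels.
#'
#' @param x Intensity vector or `raman_spectrum` (length >= 3).
#' @param lam Smoothness penalty weight (> 0); default 1e5.
#' @param p Asymmetry weight in (0, 0.5); default 0.001.
#' @param n_iter Reweighting iterations (>= 1); default 10.
#' @return Baseline vector `z`.
#' @export
asls_baseline <- function(x, lam = 1e5, p = 0.001, n_iter = 10) {
  y <- .intensities(x)
  if (length(y) < 3) stop("AsLS needs at least 3 channels")
  if (!is.numeric(lam) || lam <= 0) stop("lam must be > 0")
  if (!is.numeric(p) || p <= 0 || p >= 0.5) stop("p must lie in (0, 0.5)")
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (any(!is.finite(y))) stop("input intensities must be finite")
  asls_cpp(as.numeric(y), lam, p, as.integer(n_iter))
}

.asls_baseline_matrix <- function(Y, lam = 1e5, p = 0.001, n_iter = 10) {
  stopifnot(ncol(Y) >= 3, lam > 0, p > 0, p < 0.5, n_iter >= 1)
  asls_mat_cpp(Y, lam, p, as.integer(n_iter))
}

#' Subtract a baseline from a spectrum
#'
#' @param x Intensity vector or `raman_spectrum`.
#' @param baseline Baseline vector of identical length.
#' @return Same type as `x`, with intensities replaced by the elementwise
#'   difference (metadata preserved, no clipping).
#' @export
subtract_baseline <- function(x, baseline) {
  y <- .intensities(x)
  if (length(y) != length(baseline)) {
    stop("spectrum and baseline lengths differ (", length(y), " vs ",
         length(baseline), ")")
  }
  if (inherits(x, "raman_spectrum")) {
    x$intensities <- y - baseline
    x
  } else {
    y - baseline
  }
}

#' Analysis region set
#'
#' Closed wavenumber intervals retained for analysis.  The default keeps the
#' fingerprint region 500--1800 cm^-1 and the 2100--3100 cm^-1 range (high
#' wavenumbers plus part of the silent zone).
#'
#' @param intervals Two-column matrix (or list of length-2 vectors) of
#'   `lo < hi` interval bounds, non-overlapping and sorted.
#' @return Two-column numeric matrix of class `region_set`.
#' @export
region_set <- function(intervals) {
  if (is.list(intervals)) intervals <- do.call(rbind, intervals)
  intervals <- matrix(as.numeric(intervals), ncol = 2)
  if (any(intervals[, 1] >= intervals[, 2])) stop("regions need lo < hi")
  o <- order(intervals[, 1])
  intervals <- intervals[o, , drop = FALSE]
  if (nrow(intervals) > 1 &&
      any(intervals[-1, 1] <= intervals[-nrow(intervals), 2])) {
    stop("regions must be non-overlapping")
  }
  structure(intervals, dimnames = list(NULL, c("lo", "hi")),
            class = c("region_set", "matrix"))
}

#' @rdname region_set
#' @export
default_regions <- function() {
  region_set(rbind(c(500, 1800), c(2100, 3100)))
}

#' Crop a dataset to a set of wavenumber regions
#'
#' Retains channels whose wavenumber falls inside any closed interval
#' (inclusive at both ends), in grid order; the grid and the contiguous
#' segment bookkeeping are updated consistently.
#'
#' @param dataset A `spectral_dataset`.
#' @param regions A [region_set()].
#' @return Cropped `spectral_dataset`.
#' @export
select_regions <- function(dataset, regions = default_regions()) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  regions <- region_set(regions)
  keep <- rep(FALSE, length(dataset$grid))
  for (r in seq_len(nrow(regions))) {
    keep <- keep | (dataset$grid >= regions[r, 1] & dataset$grid <= regions[r, 2])
  }
  if (!any(keep)) stop("region selection retained no channels")
  idx <- which(keep)
  runs <- cumsum(c(1L, diff(idx) != 1L))
  segments <- lapply(split(seq_along(idx), runs),
                     function(ii) c(ii[1], ii[length(ii)]))
  names(segments) <- NULL
  dataset$grid <- dataset$grid[idx]
  dataset$intensities <- dataset$intensities[, idx, drop = FALSE]
  dataset$segments <- segments
  dataset
}

# Trapezoidal quadrature weights over a (possibly piecewise) grid: each
# contiguous segment is integrated separately; gaps contribute nothing.
.trapz_weights <- function(grid, segments = NULL) {
  if (is.null(segments)) segments <- list(c(1L, length(grid)))
  w <- numeric(length(grid))
  for (seg in segments) {
    ii <- seg[1]:seg[2]
    if (length(ii) < 2) next
    h <- diff(grid[ii])
    wseg <- numeric(length(ii))
    wseg[-length(ii)] <- h / 2
    wseg[-1] <- wseg[-1] + h / 2
    w[ii] <- wseg
  }
  w
}

#' Normalize spectra to unit area
#'
#' Divides intensities by the trapezoidal integral over the (possibly
#' region-cropped, piecewise) grid, so the post-normalization integral is 1.
#' A non-positive area signals an uncorrected or pathological spectrum and
#' raises an error.
#'
#' @param x A `spectral_dataset`, `raman_spectrum`, or intensity vector.
#' @param grid Wavenumber grid (vector input only).
#' @param segments Optional list of contiguous channel index ranges.
#' @return Same type as `x`, unit-area normalized.
#' @export
normalize_unit_area <- function(x, grid = NULL, segments = NULL) {
  if (inherits(x, "spectral_dataset")) {
    w <- .trapz_weights(x$grid, x$segments)
    areas <- drop(x$intensities %*% w)
    if (any(areas <= 0)) {
      stop(sum(areas <= 0), " spectra have non-positive area; ",
           "baseline-correct before normalizing")
    }
    x$intensities <- x$intensities / areas
    return(x)
  }
  if (inherits(x, "raman_spectrum")) {
    grid <- x$grid
    y <- x$intensities
  } else {
    y <- x
  }
  .check_grid(grid)
  area <- sum(.trapz_weights(grid, segments) * y)
  if (area <= 0) stop("non-positive spectral area (", signif(area, 4), ")")
  if (inherits(x, "raman_spectrum")) {
    x$intensities <- y / area
    x
  } else {
    y / area
  }
}

#' Mean-center datasets with training-set column means
#'
#' Column means are computed on the training rows only and subtracted from
#' the training set and from every additional dataset passed, avoiding
#' test-set leakage.  The centering vector is returned for persistence.
#'
#' @param train A `spectral_dataset` (or plain matrix).
#' @param ... Further datasets/matrices on the same grid to center with the
#'   training means.
#' @return List with `train`, `applied` (list of centered extra datasets) and
#'   `center` (the column-mean vector).
#' @export
mean_center <- function(train, ...) {
  others <- list(...)
  get_mat <- function(d) if (inherits(d, "spectral_dataset")) d$intensities else d
  set_mat <- function(d, m) {
    if (inherits(d, "spectral_dataset")) { d$intensities <- m; d } else m
  }
  ref_grid <- if (inherits(train, "spectral_dataset")) train$grid else NULL
  ctr <- colMeans(get_mat(train))
  centered_others <- lapply(others, function(d) {
    m <- get_mat(d)
    if (ncol(m) != length(ctr)) stop("channel count mismatch in mean_center")
    if (!is.null(ref_grid) && inherits(d, "spectral_dataset") &&
        !isTRUE(all.equal(d$grid, ref_grid))) {
      stop("grid mismatch in mean_center")
    }
    set_mat(d, sweep(m, 2, ctr))
  })
  list(train = set_mat(train, sweep(get_mat(train), 2, ctr)),
       applied = centered_others, center = ctr)
}

#' Assemble individual spectra into a dataset matrix
#'
#' All spectra must share an identical grid; rows are ordered by
#' (class, map_id, y, x) and provenance metadata is carried through.
#'
#' @param spectra Non-empty list of `raman_spectrum` objects.
#' @return A `spectral_dataset`.
#' @export
assemble_matrix <- function(spectra) {
  if (!length(spectra)) stop("cannot assemble an empty list of spectra")
  grid <- spectra[[1]]$grid
  for (s in spectra) {
    if (!isTRUE(all.equal(s$grid, grid))) {
      stop("grid mismatch for spectrum from map_id '",
           if (is.null(s$meta$map_id)) "<unknown>" else s$meta$map_id, "'")
    }
  }
  get_meta <- function(s, field, default = NA) {
    v <- s$meta[[field]]
    if (is.null(v)) default else v
  }
  meta <- data.frame(
    class = vapply(spectra, get_meta, "", field = "class_label",
                   default = NA_character_),
    animal_id = vapply(spectra, function(s)
      as.character(get_meta(s, "animal_id", NA_character_)), ""),
    map_id = vapply(spectra, function(s)
      as.character(get_meta(s, "map_id", NA_character_)), ""),
    x = vapply(spectra, function(s) as.numeric(get_meta(s, "x", NA_real_)), 0),
    y = vapply(spectra, function(s) as.numeric(get_meta(s, "y", NA_real_)), 0),
    stringsAsFactors = FALSE)
  o <- order(meta$class, meta$map_id, meta$y, meta$x)
  mat <- do.call(rbind, lapply(spectra[o], `[[`, "intensities"))
  meta <- meta[o, , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(grid = grid, intensities = mat, labels = meta$class,
                 meta = meta, segments = list(c(1L, length(grid)))),
            class = "spectral_dataset")
}

#' Full two-stage baseline correction of a dataset
#'
#' Applies the iterative modified polynomial fit and then AsLS to every
#' spectrum, returning the baseline-corrected dataset.
#'
#' @param dataset A `spectral_dataset`.
#' @param order,max_iter,tol Passed to [polyfit_baseline()].
#' @param lam,p,n_iter Passed to [asls_baseline()].
#' @return Baseline-corrected `spectral_dataset`.
#' @export
correct_baselines <- function(dataset, order = 5, max_iter = 100, tol = 1e-6,
                              lam = 1e5, p = 0.001, n_iter = 10) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  poly <- .polyfit_baseline_matrix(dataset$intensities, dataset$grid,
                                   order = order, max_iter = max_iter,
                                   tol = tol)
  resid <- dataset$intensities - poly
  asls <- .asls_baseline_matrix(resid, lam = lam, p = p, n_iter = n_iter)
  dataset$intensities <- resid - asls
  dataset
}
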