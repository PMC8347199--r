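#' Uniform wavenumber grid
#'
#' Builds the spectral axis used throughout the package.  The default mirrors
#' a full-range grating acquisition: 3180 uniformly spaced channels covering
#' 200--3400 cm^-1.
#'
#' @param start,end Grid limits in cm^-1.
#' @param n Number of channels (>= 2).
#' @return Numeric vector of strictly increasing wavenumbers.
#' @export
wavenumber_grid <- function(start = 200, end = 3400, n = 3180) {
  stopifnot(is.numeric(start), is.numeric(end), n >= 2, end > start)
  seq(start, end, length.out = n)
}

.check_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) < 2 || any(!is.finite(grid)) ||
      any(diff(grid) <= 0)) {
    stop("grid must be a finite, strictly increasing numeric vector of length >= 2")
  }
  invisible(grid)
}

#' Unit-height spectral line shape
#'
#' @param x Wavenumbers at which to evaluate (cm^-1).
#' @param center Band center (cm^-1).
#' @param fwhm Full width at half maximum (cm^-1, > 0).
#' @param shape `"lorentzian"` or `"gaussian"`.
#' @return Intensities with value 1 at the band center.
#' @export
line_shape <- function(x, center, fwhm, shape = c("lorentzian", "gaussian")) {
  shape <- match.arg(shape)
  stopifnot(fwhm > 0)
  if (shape == "lorentzian") {
    1 / (1 + (2 * (x - center) / fwhm)^2)
  } else {
    exp(-4 * log(2) * ((x - center) / fwhm)^2)
  }
}

#' Construct a band library
#'
#' A band library is a data frame with one row per band (columns `center`,
#' `fwhm`, `shape`, `assignment`, `base_amplitude`) plus one amplitude
#' multiplier column per class.  It is both the ground truth of the synthetic
#' generator and the lookup table for peak assignment.
#'
#' @param bands Data frame with the columns named above and one numeric,
#'   non-negative column per entry of `classes`.
#' @param classes Character vector of class labels.
#' @return Object of class `band_library`.
#' @export
band_library <- function(bands, classes) {
  stopifnot(is.data.frame(bands), is.character(classes), length(classes) >= 1)
  needed <- c("center", "fwhm", "shape", "assignment", "base_amplitude", classes)
  missing_cols <- setdiff(needed, names(bands))
  if (length(missing_cols)) {
    stop("band table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(bands$center)) stop("band centers must be unique")
  stopifnot(all(bands$fwhm > 0), all(bands$base_amplitude >= 0),
            all(bands$shape %in% c("lorentzian", "gaussian")))
  for (cl in classes) {
    if (any(bands[[cl]] < 0)) stop("class multipliers must be non-negative")
  }
  bands <- bands[order(bands$center), needed, drop = FALSE]
  rownames(bands) <- NULL
  structure(bands, classes = classes,
            class = c("band_library", "data.frame"))
}

#' Per-class band amplitude
#' @param library A [band_library()].
#' @param class_label One of the library's classes.
#' @return Numeric vector `base_amplitude * multiplier`, one entry per band.
#' @export
band_amplitudes <- function(library, class_label) {
  classes <- attr(library, "classes")
  if (!class_label %in% classes) {
    stop("unknown class label '", class_label, "'")
  }
  library$base_amplitude * library[[class_label]]
}

# Amplitudes of the two saturation-ratio bands are solved jointly: the
# 1444/1460 and 1655/1661 pairs overlap through their Lorentzian wings, so a
# naive assignment would not reproduce the target net heights at the nominal
# centers.  Fixing the net heights H(1444) and H(1655) = ratio * H(1444) per
# class gives a 2x2 linear system in the two free amplitudes, with every
# other band's wing contribution entering as a known offset.
.solve_ratio_amplitudes <- function(fixed, target_h1444, target_ratio, fwhm) {
  eval_at <- function(x) {
    sum(fixed$amp * line_shape(x, fixed$center, fwhm))
  }
  M <- rbind(c(1, line_shape(1444, 1655, fwhm)),
             c(line_shape(1655, 1444, fwhm), 1))
  rhs <- c(target_h1444 - eval_at(1444),
           target_ratio * target_h1444 - eval_at(1655))
  a <- solve(M, rhs)
  if (any(a <= 0)) stop("ratio-band amplitude solve produced non-positive values")
  c(a1444 = a[[1]], a1655 = a[[2]])
}

#' Default band library for the CTRL/HFD tissue contrast
#'
#' Encodes the biochemical band structure of the hypothalamic Arc-ME Raman
#' contrast between control (CTRL) and high-fat-diet (HFD) tissue: glycogen
#' bands (484, 858, 1460 cm^-1), collagen bands (747, 1007, 1105, 1127, 1172,
#' amide III at 1260, amide I at 1661 cm^-1), the triacylglycerol carbonyl
#' band at 1748 cm^-1 and the silent-zone cyanide band at 2248 cm^-1, all
#' more intense in HFD; the unsaturation marker at 3000 cm^-1 (=C-H), more
#' intense in CTRL; and class-invariant C-H stretches at 2850, 2878 and
#' 2930 cm^-1.  Amplitudes of the 1444 and 1655 cm^-1 bands are solved per
#' class so that the noiseless height ratio 1655/1444 equals 0.88 (CTRL) and
#' 0.55 (HFD) despite wing overlap with the 1460 and 1661 cm^-1 bands.
#'
#' @param fwhm Default full width at half maximum for every band (cm^-1).
#' @return A [band_library()] with classes `"CTRL"` and `"HFD"`.
#' @export
default_band_library <- function(fwhm = 12) {
  fixed <- data.frame(
    center = c(484, 747, 858, 1007, 1105, 1127, 1172, 1260, 1460, 1661,
               1748, 2248, 2850, 2878, 2930, 3000),
    assignment = c(
      "glycogen (C-C-C / C-O-C glycosidic bending)",
      "phenylalanine delta/omega-COO- (collagen)",
      "glycogen C(1)-H(alpha) bending / proline nu(CC) ring (collagen)",
      "phenylalanine ring breathing (collagen)",
      "proline nu(CC) skeletal (collagen I)",
      "proline delta-NCH (collagen I)",
      "tyrosine C-H (collagen shoulder)",
      "amide III (collagen, 1240-1280)",
      "C-C-C skeletal bending (glycogen) / nu_as COO- lysine (collagen)",
      "amide I (collagen I/III)",
      "C=O ester stretch (triacylglycerol)",
      "cyanide group (-CN)",
      "CH2 symmetric stretch",
      "CH2 antisymmetric stretch",
      "CH3 / aromatic C-H stretch (glucosides)",
      "=C-H stretch (unsaturated fatty acids)"),
    CTRL = c(0.30, 0.25, 0.40, 0.50, 0.25, 0.30, 0.20, 0.45, 0.35, 0.15,
             0.20, 0.05, 1.00, 0.90, 1.10, 0.35),
    HFD  = c(0.55, 0.40, 0.70, 0.75, 0.40, 0.50, 0.35, 0.65, 0.65, 0.25,
             0.60, 0.30, 1.00, 0.90, 1.10, 0.20),
    stringsAsFactors = FALSE)

  ratio_targets <- c(CTRL = 0.88, HFD = 0.55)
  h1444_targets <- c(CTRL = 0.90, HFD = 1.50)
  solved <- lapply(c("CTRL", "HFD"), function(cl) {
    .solve_ratio_amplitudes(
      data.frame(center = fixed$center, amp = fixed[[cl]]),
      h1444_targets[[cl]], ratio_targets[[cl]], fwhm)
  })
  names(solved) <- c("CTRL", "HFD")

  bands <- rbind(
    fixed,
    data.frame(center = 1444,
               assignment = "CH2 deformation (lipid, saturation reference)",
               CTRL = solved$CTRL[["a1444"]], HFD = solved$HFD[["a1444"]],
               stringsAsFactors = FALSE),
    data.frame(center = 1655,
               assignment = "amide I / C=C stretch (unsaturated lipid)",
               CTRL = solved$CTRL[["a1655"]], HFD = solved$HFD[["a1655"]],
               stringsAsFactors = FALSE))
  bands$fwhm <- fwhm
  bands$shape <- "lorentzian"
  bands$base_amplitude <- 1
  band_library(bands, classes = c("CTRL", "HFD"))
}

#' Noiseless class template
#'
#' Analytic sum of all library bands for one class evaluated on a grid
#' (no background, no noise).  Bands whose center falls outside the grid span
#' are skipped with a warning.
#'
#' @inheritParams band_amplitudes
#' @param grid Wavenumber grid.
#' @return Intensity vector aligned with `grid`.
#' @export
class_template <- function(grid, library, class_label) {
  .check_grid(grid)
  amps <- band_amplitudes(library, class_label)
  inside <- library$center >= grid[1] & library$center <= grid[length(grid)]
  if (any(!inside)) {
    warning("skipping band(s) outside the grid span: ",
            paste(library$center[!inside], collapse = ", "))
  }
  out <- numeric(length(grid))
  for (i in which(inside)) {
    if (amps[i] == 0) next
    out <- out + amps[i] *
      line_shape(grid, library$center[i], library$fwhm[i], library$shape[i])
  }
  out
}

# Fluorescence background evaluated on the normalized coordinate u in [0,1];
# coefs = c(c0, c1, ..., ck) for c0 + c1*u + ... + ck*u^k.
.eval_poly_baseline <- function(grid, coefs) {
  if (length(coefs) == 0) return(numeric(length(grid)))
  u <- (grid - grid[1]) / (grid[length(grid)] - grid[1])
  drop(outer(u, seq_along(coefs) - 1, "^") %*% coefs)
}

#' Synthesize a single Raman spectrum
#'
#' Intensities are the noiseless class template plus a polynomial
#' fluorescence background plus i.i.d. Gaussian noise whose standard
#' deviation is `noise_sd / sqrt(exposures)` (exposure averaging).
#'
#' @inheritParams class_template
#' @param baseline_coefs Polynomial coefficients `c(c0, c1, ...)` evaluated on
#'   the normalized grid coordinate in `[0, 1]`.
#' @param noise_sd Per-exposure noise standard deviation (intensity units).
#' @param exposures Number of averaged exposures (>= 1).
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   spectra.
#' @param meta Named list of provenance fields (`class_label`, `animal_id`,
#'   `map_id`, `x`, `y`); `class_label` is filled in automatically.
#' @return Object of class `raman_spectrum`: list with `grid`, `intensities`
#'   and `meta`.
#' @export
synth_spectrum <- function(grid, library, class_label,
                           baseline_coefs = 0, noise_sd = 0, exposures = 30,
                           seed = NULL, meta = list()) {
  stopifnot(noise_sd >= 0, exposures >= 1)
  template <- class_template(grid, library, class_label)
  y <- template + .eval_poly_baseline(grid, baseline_coefs)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + rnorm(length(grid), sd = noise_sd / sqrt(exposures))
  }
  meta$class_label <- class_label
  structure(list(grid = grid, intensities = y, meta = meta),
            class = "raman_spectrum")
}

#' Generator configuration
#'
#' Holds every knob of the synthetic-map generator.  Defaults emulate the
#' acquisition design the pipeline targets: 4 maps per class of ~1000 spectra
#' each (8 maps total), a 3180-channel 200--3400 cm^-1 grid, at least 30
#' averaged exposures, and a per-map random 5th-order fluorescence background
#' that dominates the band amplitudes by roughly 5--20x.
#'
#' @param n_maps_per_class Maps per class (>= 1).
#' @param spectra_per_map Spectra per map (>= 1).
#' @param grid_start,grid_end,grid_n Wavenumber grid definition.
#' @param fluor_amp_range Range of the leading background coefficient
#'   (uniform draw per map, intensity units).
#' @param fluor_coef_range Half-width of the uniform draw for the relative
#'   higher-order background coefficients; must stay below 1/`fluor_order`
#'   so backgrounds remain positive.
#' @param fluor_order Polynomial order of the fluorescence background.
#' @param noise_sd Per-exposure Gaussian noise SD (intensity units).
#' @param exposures Exposures averaged per spectrum.
#' @param roi_fraction Fraction of collected spectra retained as in-ROI
#'   (largest-remainder quota across maps; first `n` positions of each map).
#' @param seed Integer seed driving every random draw.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_maps_per_class = 4, spectra_per_map = 1000,
                             grid_start = 200, grid_end = 3400, grid_n = 3180,
                             fluor_amp_range = c(10, 25),
                             fluor_coef_range = 0.15, fluor_order = 5,
                             noise_sd = 0.3, exposures = 30,
                             roi_fraction = 1, seed = 1L) {
  stopifnot(n_maps_per_class >= 1, spectra_per_map >= 1, noise_sd >= 0,
            exposures >= 1, roi_fraction > 0, roi_fraction <= 1,
            length(fluor_amp_range) == 2, fluor_amp_range[1] <= fluor_amp_range[2],
            fluor_coef_range >= 0, fluor_coef_range * fluor_order < 1,
            grid_n >= 2, grid_end > grid_start)
  structure(list(n_maps_per_class = as.integer(n_maps_per_class),
                 spectra_per_map = as.integer(spectra_per_map),
                 grid_start = grid_start, grid_end = grid_end,
                 grid_n = as.integer(grid_n),
                 fluor_amp_range = fluor_amp_range,
                 fluor_coef_range = fluor_coef_range,
                 fluor_order = as.integer(fluor_order),
                 noise_sd = noise_sd, exposures = exposures,
                 roi_fraction = roi_fraction, seed = as.integer(seed)),
            class = "generator_config")
}

# Largest-remainder allocation of the ROI quota across maps (deterministic).
.roi_quota <- function(n_maps, spectra_per_map, roi_fraction) {
  total_keep <- round(roi_fraction * n_maps * spectra_per_map)
  base <- floor(roi_fraction * spectra_per_map)
  keep <- rep(base, n_maps)
  extra <- total_keep - sum(keep)
  if (extra > 0) keep[seq_len(extra)] <- keep[seq_len(extra)] + 1
  keep
}

#' Generate a synthetic hyperspectral dataset
#'
#' Draws one fluorescence polynomial per map (map-level correlation), lays
#' spectra on a square raster with 25 um steps, assigns maps round-robin to
#' 3 CTRL / 4 HFD animals, and adds exposure-averaged Gaussian noise.  Fully
#' deterministic given `config$seed`.
#'
#' @param config A [generator_config()].
#' @param library A [band_library()]; classes are taken from it.
#' @return Object of class `spectral_dataset`: list with `grid`,
#'   `intensities` (spectra x channels matrix), `labels` (character vector),
#'   `meta` (data frame with `class`, `animal_id`, `map_id`, `x`, `y`) and
#'   `segments` (list of contiguous channel index ranges).
#' @export
synth_dataset <- function(config = generator_config(),
                          library = default_band_library()) {
  stopifnot(inherits(config, "generator_config"),
            inherits(library, "band_library"))
  classes <- attr(library, "classes")
  grid <- wavenumber_grid(config$grid_start, config$grid_end, config$grid_n)
  set.seed(config$seed)

  n_animals <- c(3L, 4L)  # animals per class, recycled over classes
  templates <- lapply(classes, function(cl) class_template(grid, library, cl))
  names(templates) <- classes

  keep <- .roi_quota(config$n_maps_per_class * length(classes),
                     config$spectra_per_map, config$roi_fraction)
  nx <- ceiling(sqrt(config$spectra_per_map))
  noise_eff <- config$noise_sd / sqrt(config$exposures)

  blocks <- list()
  metas <- list()
  map_counter <- 0L
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    na <- n_animals[(ci - 1L) %% length(n_animals) + 1L]
    for (m in seq_len(config$n_maps_per_class)) {
      map_counter <- map_counter + 1L
      amp <- runif(1, config$fluor_amp_range[1], config$fluor_amp_range[2])
      rel <- runif(config$fluor_order, -config$fluor_coef_range,
                   config$fluor_coef_range)
      coefs <- c(amp, amp * rel)
      bg <- .eval_poly_baseline(grid, coefs)
      n_keep <- keep[map_counter]
      base_row <- templates[[cl]] + bg
      noise <- if (noise_eff > 0) {
        matrix(rnorm(config$spectra_per_map * length(grid), sd = noise_eff),
               nrow = config$spectra_per_map)
      } else {
        matrix(0, config$spectra_per_map, length(grid))
      }
      block <- sweep(noise, 2, base_row, "+")[seq_len(n_keep), , drop = FALSE]
      idx <- seq_len(n_keep) - 1L
      metas[[map_counter]] <- data.frame(
        class = cl,
        animal_id = sprintf("%s_animal%02d", cl, (m - 1L) %% na + 1L),
        map_id = sprintf("%s_map%02d", cl, m),
        x = (idx %% nx) * 25,
        y = (idx %/% nx) * 25,
        stringsAsFactors = FALSE)
      blocks[[map_counter]] <- block
    }
  }
  mat <- do.call(rbind, blocks)
  meta <- do.call(rbind, metas)
  rownames(mat) <- NULL
  rownames(meta) <- NULL
  structure(list(grid = grid, intensities = mat, labels = meta$class,
                 meta = meta, segments = list(c(1L, length(grid)))),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat("spectral_dataset:", nrow(x$intensities), "spectra x",
      ncol(x$intensities), "channels\n")
  cat("  grid:", round(x$grid[1], 2), "-",
      round(x$grid[length(x$grid)], 2), "cm^-1\n")
  print(table(x$labels))
  invisible(x)
}

#' @export
print.band_library <- function(x, ...) {
  cat("band_library with", nrow(x), "bands; classes:",
      paste(attr(x, "classes"), collapse = ", "), "\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Explode a dataset into individual spectra
#'
#' Inverse of [assemble_matrix()]: returns one `raman_spectrum` per row with
#' provenance metadata carried over.
#'
#' @param dataset A `spectral_dataset`.
#' @return List of `raman_spectrum` objects.
#' @export
dataset_to_spectra <- function(dataset) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  grid <- dataset$grid
  lapply(seq_len(nrow(dataset$intensities)), function(i) {
    structure(list(grid = grid,
                   intensities = dataset$intensities[i, ],
                   meta = list(class_label = dataset$meta$class[i],
                               animal_id = dataset$meta$animal_id[i],
                               map_id = dataset$meta$map_id[i],
                               x = dataset$meta$x[i],
                               y = dataset$meta$y[i])),
              class = "raman_spectrum")
  })
}

# ---- delimited-text and serialization interfaces ----------------------------

#' Write / read a spectral dataset as delimited text
#'
#' Matrix file: first row holds the wavenumbers, each subsequent row one
#' spectrum.  Side-car labels file: tab-delimited table with columns
#' `class`, `animal_id`, `map_id`, `x`, `y` (one row per spectrum).
#'
#' @param dataset A `spectral_dataset`.
#' @param file Path of the matrix file.
#' @param labels_file Path of the side-car labels file (optional on read).
#' @return `write_spectra` returns `file` invisibly; `read_spectra` a
#'   `spectral_dataset`.
#' @export
write_spectra <- function(dataset, file, labels_file = NULL) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  out <- rbind(dataset$grid, dataset$intensities)
  data.table::fwrite(data.table::as.data.table(out), file, sep = "\t",
                     col.names = FALSE)
  if (!is.null(labels_file)) {
    data.table::fwrite(dataset$meta, labels_file, sep = "\t")
  }
  invisible(file)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(file, labels_file = NULL) {
  raw <- as.matrix(data.table::fread(file, header = FALSE, sep = "\t"))
  dimnames(raw) <- NULL
  grid <- raw[1, ]
  .check_grid(grid)
  mat <- raw[-1, , drop = FALSE]
  if (!is.null(labels_file)) {
    meta <- as.data.frame(data.table::fread(labels_file, sep = "\t"))
    if (nrow(meta) != nrow(mat)) {
      stop("labels file has ", nrow(meta), " rows but matrix has ", nrow(mat))
    }
    labels <- meta$class
  } else {
    meta <- data.frame(class = rep(NA_character_, nrow(mat)))
    labels <- meta$class
  }
  structure(list(grid = grid, intensities = mat, labels = labels, meta = meta,
                 segments = list(c(1L, length(grid)))),
            class = "spectral_dataset")
}

#' Serialize a band library or generator config
#'
#' Band libraries go to JSON; generator configurations to YAML.
#'
#' @param library,config Objects to serialize.
#' @param file Destination / source path.
#' @return The read functions return the reconstructed object.
#' @export
write_band_library <- function(library, file) {
  stopifnot(inherits(library, "band_library"))
  payload <- list(classes = attr(library, "classes"),
                  bands = as.data.frame(library))
  jsonlite::write_json(payload, file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' @rdname write_band_library
#' @export
read_band_library <- function(file) {
  payload <- jsonlite::read_json(file, simplifyVector = TRUE)
  band_library(as.data.frame(payload$bands), payload$classes)
}

#' @rdname write_band_library
#' @export
write_generator_config <- function(config, file) {
  stopifnot(inherits(config, "generator_config"))
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

#' @rdname write_band_library
#' @export
read_generator_config <- function(file) {
  do.call(generator_config, yaml::read_yaml(file))
}
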