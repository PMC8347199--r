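# End-to-end orchestration: generate -> baseline-correct -> band analytics ->
# region crop -> unit-area normalize -> duplex split -> mean-center ->
# CV-select latent variables -> fit PLS-DA -> evaluate -> report.

#' Pipeline configuration
#'
#' Bundles every stage's parameters with full defaulting.  All randomness
#' flows from the two named seeds (`generator$seed`, `cv_seed`); a run with
#' both fixed is bitwise reproducible.
#'
#' @param generator A [generator_config()].
#' @param library A [band_library()].
#' @param polyfit_order,polyfit_max_iter,polyfit_tol Modified-polyfit stage.
#' @param asls_lam,asls_p,asls_n_iter AsLS stage.
#' @param regions A [region_set()] retained for classification.
#' @param train_fraction Per-class duplex training fraction.
#' @param A_max,k_folds,cv_seed Cross-validation stage.
#' @param ratio_bands Numerator/denominator centers of the saturation ratio.
#' @param halfwidth Band-height window half-width (cm^-1).
#' @param out_dir Output directory for artifacts (NULL = in-memory only).
#' @param verbose Emit one progress line per stage.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            library = default_band_library(),
                            polyfit_order = 5, polyfit_max_iter = 100,
                            polyfit_tol = 1e-6,
                            asls_lam = 1e5, asls_p = 0.001, asls_n_iter = 10,
                            regions = default_regions(),
                            train_fraction = 5600 / 7409,
                            A_max = 10, k_folds = 10, cv_seed = NULL,
                            ratio_bands = c(1655, 1444), halfwidth = 10,
                            out_dir = NULL, verbose = FALSE) {
  if (is.null(cv_seed)) cv_seed <- generator$seed
  structure(list(generator = generator, library = library,
                 polyfit_order = polyfit_order,
                 polyfit_max_iter = polyfit_max_iter,
                 polyfit_tol = polyfit_tol,
                 asls_lam = asls_lam, asls_p = asls_p,
                 asls_n_iter = asls_n_iter,
                 regions = region_set(regions),
                 train_fraction = train_fraction,
                 A_max = A_max, k_folds = k_folds,
                 cv_seed = as.integer(cv_seed),
                 ratio_bands = ratio_bands, halfwidth = halfwidth,
                 out_dir = out_dir, verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

.stage_log <- function(config, stage, ...) {
  if (config$verbose) {
    message(sprintf("[%s] %s", stage, paste0(..., collapse = "")))
  }
}

#' Run the full discrimination pipeline
#'
#' Executes the fixed stage order: generate, per-spectrum baseline
#' correction (modified polyfit then AsLS), band analytics on the corrected
#' full-grid spectra, region cropping, unit-area normalization, per-class
#' duplex splitting, training-set mean centering, 10-fold CV latent-variable
#' selection, final PLS-DA fit, evaluation and discriminant-region calling.
#' Identical configuration and seeds give an identical report.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `run_report`: list with `dataset_shape`,
#'   `split_counts`, `cv` (the [crossval_select()] curve), `chosen_A`,
#'   `train_accuracy`, `test_accuracy` (per class + overall, percent),
#'   `ratios` (per class), `peaks` (per-class peak tables),
#'   `discriminant` (the [discriminant_regions()] report) and `config_echo`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  ds <- synth_dataset(config$generator, config$library)
  .stage_log(config, "generate", nrow(ds$intensities), " spectra x ",
             ncol(ds$intensities), " channels")

  corrected <- correct_baselines(ds, order = config$polyfit_order,
                                 max_iter = config$polyfit_max_iter,
                                 tol = config$polyfit_tol,
                                 lam = config$asls_lam, p = config$asls_p,
                                 n_iter = config$asls_n_iter)
  .stage_log(config, "baseline", "two-stage correction done")

  classes <- attr(config$library, "classes")
  averages <- lapply(classes, function(cl) class_average(corrected, cl))
  names(averages) <- classes
  ratios <- vapply(averages, function(av) {
    intensity_ratio(av, numerator_center = config$ratio_bands[1],
                    denominator_center = config$ratio_bands[2],
                    halfwidth = config$halfwidth)
  }, 0)
  peaks <- lapply(averages, function(av) {
    peak_table(av, config$library, min_prominence = 0.1,
               tol = config$halfwidth / 2)
  })
  .stage_log(config, "bands", "ratios: ",
             paste(names(ratios), round(ratios, 3), sep = "=",
                   collapse = ", "))

  cropped <- select_regions(corrected, config$regions)
  normalized <- normalize_unit_area(cropped)
  .stage_log(config, "regions", ncol(normalized$intensities),
             " channels retained")

  split <- stratified_duplex(normalized, config$train_fraction)
  X_train <- normalized$intensities[split$train, , drop = FALSE]
  X_test <- normalized$intensities[split$test, , drop = FALSE]
  y_train <- normalized$labels[split$train]
  y_test <- normalized$labels[split$test]
  .stage_log(config, "split", length(split$train), " train / ",
             length(split$test), " test")

  cv <- crossval_select(X_train, y_train, A_max = config$A_max,
                        k = config$k_folds, seed = config$cv_seed)
  model <- plsda_train(X_train, y_train, A = cv$chosen)
  train_acc <- evaluate(model, X_train, y_train)
  test_acc <- evaluate(model, X_test, y_test)
  disc <- discriminant_regions(model, normalized$grid)
  .stage_log(config, "plsda", "A=", cv$chosen, "; test per-class: ",
             paste(names(test_acc$per_class),
                   round(test_acc$per_class, 1), sep = "=", collapse = ", "))

  report <- structure(
    list(dataset_shape = dim(ds$intensities),
         class_counts = as.list(table(ds$labels)),
         split_counts = list(train = length(split$train),
                             test = length(split$test),
                             per_class = split$per_class),
         cv = cv, chosen_A = cv$chosen,
         train_accuracy = train_acc, test_accuracy = test_acc,
         ratios = as.list(ratios), peaks = peaks,
         discriminant = disc,
         config_echo = .echo_config(config)),
    class = "run_report")

  if (!is.null(config$out_dir)) {
    .write_run_artifacts(config, ds, normalized, split, model, report)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report\n")
  cat("  dataset:", x$dataset_shape[1], "x", x$dataset_shape[2], "\n")
  cat("  split:", x$split_counts$train, "train /", x$split_counts$test,
      "test\n")
  cat("  chosen latent variables:", x$chosen_A, "\n")
  cat("  test accuracy (%):",
      paste(names(x$test_accuracy$per_class),
            round(x$test_accuracy$per_class, 1), sep = " = ",
            collapse = ", "), "\n")
  cat("  1655/1444 ratios:",
      paste(names(x$ratios), round(unlist(x$ratios), 3), sep = " = ",
            collapse = ", "), "\n")
  invisible(x)
}

.echo_config <- function(config) {
  list(generator = unclass(config$generator),
       polyfit = list(order = config$polyfit_order,
                      max_iter = config$polyfit_max_iter,
                      tol = config$polyfit_tol),
       asls = list(lam = config$asls_lam, p = config$asls_p,
                   n_iter = config$asls_n_iter),
       regions = apply(unclass(config$regions), 1, identity, simplify = FALSE),
       train_fraction = config$train_fraction,
       A_max = config$A_max, k_folds = config$k_folds,
       cv_seed = config$cv_seed,
       ratio_bands = config$ratio_bands, halfwidth = config$halfwidth)
}

.write_run_artifacts <- function(config, ds, normalized, split, model,
                                 report) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_spectra(ds, file.path(out, "spectra_raw.tsv"),
                file.path(out, "labels.tsv"))
  write_spectra(normalized, file.path(out, "spectra_preprocessed.tsv"))
  write_split(split, file.path(out, "split.json"))
  write_plsda(model, file.path(out, "model.json"))
  disc <- report$discriminant
  grid <- normalized$grid
  data.table::fwrite(
    data.frame(wavenumber = grid, vip = disc$vip,
               coefficient = disc$coefficients,
               significant = disc$significant),
    file.path(out, "discriminant_channels.tsv"), sep = "\t")
  for (cl in names(report$peaks)) {
    data.table::fwrite(report$peaks[[cl]],
                       file.path(out, paste0("peaks_", cl, ".tsv")),
                       sep = "\t")
  }
  json_report <- report
  json_report$cv <- unclass(json_report$cv)
  json_report$discriminant <-
    list(regions = disc$regions, n_significant = sum(disc$significant))
  jsonlite::write_json(unclass(json_report),
                       file.path(out, "report.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  invisible(out)
}
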