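# Deterministic duplex representative subset selection.  The two mutually
# farthest samples seed the training set, the two farthest remaining seed
# the test set, and the remaining samples are assigned alternately to each
# set by the max-min-distance criterion until the test quota is reached,
# after which the training set absorbs the remainder.  No randomness; ties
# are broken by lowest row index.

# Farthest pair in a distance matrix, ties resolved to the lexicographically
# smallest (i, j) with i < j.
.farthest_pair <- function(D, pool) {
  Dp <- D[pool, pool, drop = FALSE]
  m <- max(Dp)
  hits <- which(Dp == m, arr.ind = TRUE)
  hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  c(pool[hits[1, 1]], pool[hits[1, 2]])
}

#' Duplex train/test split
#'
#' Classic duplex selection on a sample matrix: deterministic, and designed
#' so both subsets span the data cloud representatively.
#'
#' @param X Numeric matrix, one sample per row (>= 4 rows).
#' @param n_train Number of training samples (`2 <= n_train <= nrow(X) - 2`).
#' @param metric Distance metric (only `"euclidean"`).
#' @return Object of class `split_assignment`: list with sorted integer
#'   vectors `train` and `test` and a `per_class` count table (NULL here;
#'   filled by [stratified_duplex()]).
#' @export
duplex <- function(X, n_train, metric = c("euclidean")) {
  metric <- match.arg(metric)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop("duplex needs at least 4 rows")
  if (n_train < 2 || n_train > n - 2) {
    stop("n_train must lie in [2, nrow(X) - 2]")
  }
  n_test <- n - n_train
  D <- as.matrix(stats::dist(X, method = metric))
  pool <- seq_len(n)

  seed_tr <- .farthest_pair(D, pool)
  pool <- setdiff(pool, seed_tr)
  seed_te <- .farthest_pair(D, pool)
  pool <- setdiff(pool, seed_te)

  train <- seed_tr
  test <- seed_te
  # min distance from every sample to the current members of each set
  dtr <- pmin(D[, seed_tr[1]], D[, seed_tr[2]])
  dte <- pmin(D[, seed_te[1]], D[, seed_te[2]])

  take <- function(dset, pool) {
    # farthest-from-set point; which.max returns the lowest index on ties
    pool[which.max(dset[pool])]
  }
  while (length(pool)) {
    if (length(train) < n_train) {
      i <- take(dtr, pool)
      train <- c(train, i)
      pool <- setdiff(pool, i)
      dtr <- pmin(dtr, D[, i])
    }
    if (length(test) >= n_test) {
      train <- c(train, pool)
      break
    }
    if (length(pool)) {
      i <- take(dte, pool)
      test <- c(test, i)
      pool <- setdiff(pool, i)
      dte <- pmin(dte, D[, i])
    }
    if (length(train) >= n_train && length(pool)) {
      test <- c(test, pool)
      break
    }
  }
  structure(list(train = sort(as.integer(train)),
                 test = sort(as.integer(test)),
                 per_class = NULL),
            class = "split_assignment")
}

#' Per-class (stratified) duplex split
#'
#' Runs [duplex()] independently inside each class with
#' `n_train = round(train_fraction * class size)` and merges the
#' assignments, preserving original row indices.  The default fraction,
#' 5600/7409, reproduces a 5600-spectrum training set on a 7409-spectrum
#' two-class dataset.
#'
#' @param dataset A `spectral_dataset` (or a list with `intensities` and
#'   `labels`).
#' @param train_fraction Fraction of each class assigned to training
#'   (0 < f < 1); every class needs at least 4 rows.
#' @return A `split_assignment` with `per_class` counts.
#' @export
stratified_duplex <- function(dataset, train_fraction = 5600 / 7409) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  X <- dataset$intensities
  labels <- dataset$labels
  stopifnot(nrow(X) == length(labels))
  train <- integer(0)
  test <- integer(0)
  classes <- unique(labels)
  per_class <- matrix(0L, nrow = length(classes), ncol = 2,
                      dimnames = list(classes, c("n_train", "n_test")))
  for (cl in classes) {
    rows <- which(labels == cl)
    if (length(rows) < 4) {
      stop("class '", cl, "' has fewer than 4 rows; cannot duplex-split")
    }
    n_tr <- round(train_fraction * length(rows))
    n_tr <- max(2L, min(as.integer(n_tr), length(rows) - 2L))
    a <- duplex(X[rows, , drop = FALSE], n_tr)
    train <- c(train, rows[a$train])
    test <- c(test, rows[a$test])
    per_class[cl, ] <- c(length(a$train), length(a$test))
  }
  structure(list(train = sort(train), test = sort(test),
                 per_class = per_class),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat("split_assignment:", length(x$train), "train /", length(x$test),
      "test rows\n")
  if (!is.null(x$per_class)) print(x$per_class)
  invisible(x)
}

#' Persist / restore a split assignment as JSON
#'
#' @param assignment A `split_assignment`.
#' @param file Path of the JSON file.
#' @return `read_split` returns the reconstructed `split_assignment`.
#' @export
write_split <- function(assignment, file) {
  stopifnot(inherits(assignment, "split_assignment"))
  payload <- list(train = assignment$train, test = assignment$test)
  if (!is.null(assignment$per_class)) {
    payload$per_class <- as.data.frame(assignment$per_class)
    payload$classes <- rownames(assignment$per_class)
  }
  jsonlite::write_json(payload, file, digits = NA)
  invisible(file)
}

#' @rdname write_split
#' @export
read_split <- function(file) {
  payload <- jsonlite::read_json(file, simplifyVector = TRUE)
  per_class <- NULL
  if (!is.null(payload$per_class)) {
    per_class <- as.matrix(payload$per_class)
    rownames(per_class) <- payload$classes
  }
  structure(list(train = as.integer(payload$train),
                 test = as.integer(payload$test),
                 per_class = per_class),
            class = "split_assignment")
}
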