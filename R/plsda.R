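# PLS-DA on a hand-implemented NIPALS PLS1 core: dummy-coded regression,
# 0.5-threshold classification, 10-fold cross-validated latent-variable
# selection, VIP scores and signed-coefficient discriminant-region calling.

#' NIPALS PLS1 core
#'
#' Fits partial least squares regression with a single response by NIPALS:
#' per component `w = t(X) y / ||t(X) y||`, `t = X w`, `p = t(X) t / (t't)`,
#' `q = y't / (t't)`, then rank-one deflation `X <- X - t p'`.  The response
#' is not deflated (predictions are mathematically unchanged for PLS1).
#' Regression coefficients are assembled as `b = W (P'W)^-1 q`.
#'
#' @param X Centered predictor matrix (rows x channels).
#' @param y Centered response vector.
#' @param A Number of latent variables
#'   (`1 <= A <= min(nrow(X) - 1, ncol(X))`).
#' @return List with `W`, `P` (channels x A), `q` (length A), `T`
#'   (rows x A), `b` (channels), `n_lv`.
#' @export
fit_pls1 <- function(X, y, A) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (A < 1 || A > min(nrow(X) - 1, ncol(X))) {
    stop("A must lie in [1, min(nrow(X) - 1, ncol(X))]")
  }
  if (stats::var(y) == 0) stop("response has zero variance")
  n <- nrow(X)
  J <- ncol(X)
  W <- matrix(0, J, A)
  P <- matrix(0, J, A)
  Tm <- matrix(0, n, A)
  q <- numeric(A)
  Xd <- X
  a_done <- 0L
  for (a in seq_len(A)) {
    wv <- crossprod(Xd, y)
    nw <- sqrt(sum(wv^2))
    if (nw < 1e-12) {
      warning("X deflated to zero covariance after ", a_done,
              " components; truncating")
      break
    }
    w <- wv / nw
    t_a <- drop(Xd %*% w)
    tt <- sum(t_a^2)
    p_a <- drop(crossprod(Xd, t_a)) / tt
    q[a] <- sum(y * t_a) / tt
    W[, a] <- w
    P[, a] <- p_a
    Tm[, a] <- t_a
    Xd <- Xd - tcrossprod(t_a, p_a)
    a_done <- a
  }
  if (a_done < A) {
    W <- W[, seq_len(a_done), drop = FALSE]
    P <- P[, seq_len(a_done), drop = FALSE]
    Tm <- Tm[, seq_len(a_done), drop = FALSE]
    q <- q[seq_len(a_done)]
  }
  b <- .pls1_coef(W, P, q, a_done)
  list(W = W, P = P, q = q, T = Tm, b = b, n_lv = a_done)
}

.pls1_coef <- function(W, P, q, A) {
  Wa <- W[, seq_len(A), drop = FALSE]
  Pa <- P[, seq_len(A), drop = FALSE]
  drop(Wa %*% solve(crossprod(Pa, Wa), q[seq_len(A)]))
}

#' Train a two-class PLS-DA model
#'
#' Dummy-codes the positive class as y = 1 and the other as y = 0, mean
#' centers predictors and response on the training rows, and fits the
#' NIPALS PLS1 core.  A sample is classified as the positive class when its
#' predicted response exceeds the 0.5 threshold (strict inequality).
#'
#' @param X Predictor matrix (rows x channels), not pre-centered.
#' @param labels Class label per row (exactly two distinct values).
#' @param A Number of latent variables.
#' @param positive Label coded as 1; with the default, positive regression
#'   coefficients mark channels that are on average more intense in HFD.
#' @return Object of class `plsda`.
#' @export
plsda_train <- function(X, labels, A, positive = "HFD") {
  X <- as.matrix(X)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("plsda_train needs exactly two classes")
  if (!positive %in% classes) stop("positive class '", positive,
                                   "' not found in labels")
  negative <- setdiff(classes, positive)
  y <- as.numeric(labels == positive)
  if (stats::var(y) == 0) stop("response has zero variance")
  x_center <- colMeans(X)
  y_mean <- mean(y)
  core <- fit_pls1(sweep(X, 2, x_center), y - y_mean, A)
  structure(c(core,
              list(x_center = x_center, y_mean = y_mean,
                   class_code = stats::setNames(c(0, 1), c(negative, positive)),
                   threshold = 0.5)),
            class = "plsda")
}

#' @export
print.plsda <- function(x, ...) {
  cat("PLS-DA model:", x$n_lv, "latent variables,", length(x$b),
      "channels\n  coding:",
      paste(names(x$class_code), x$class_code, sep = " = ", collapse = ", "),
      "(threshold", x$threshold, ")\n")
  invisible(x)
}

#' Predict continuous responses from a PLS-DA model
#'
#' `yhat = (X_new - centering) b + intercept`, the intercept restoring the
#' 0/1 dummy-code scale.
#'
#' @param object A `plsda` model.
#' @param newdata Matrix (or vector) of spectra on the training channels.
#' @param ncomp Optional number of latent variables to use (default: all
#'   fitted).
#' @param ... Unused.
#' @return Numeric vector of continuous class scores.
#' @export
predict.plsda <- function(object, newdata, ncomp = NULL, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (ncol(X) != length(object$x_center)) {
    stop("newdata has ", ncol(X), " channels; model expects ",
         length(object$x_center))
  }
  b <- if (is.null(ncomp) || ncomp == object$n_lv) {
    object$b
  } else {
    stopifnot(ncomp >= 1, ncomp <= object$n_lv)
    .pls1_coef(object$W, object$P, object$q, ncomp)
  }
  drop(sweep(X, 2, object$x_center) %*% b) + object$y_mean
}

#' Threshold continuous scores into class labels
#'
#' @param yhat Continuous scores from [predict.plsda()].
#' @param model The `plsda` model (provides coding and threshold).
#' @return Character vector of class labels; scores strictly greater than
#'   the threshold map to the class coded 1, everything else (including
#'   exactly 0.5) to the class coded 0.
#' @export
classify <- function(yhat, model) {
  pos <- names(model$class_code)[model$class_code == 1]
  neg <- names(model$class_code)[model$class_code == 0]
  ifelse(yhat > model$threshold, pos, neg)
}

# Predictions for every component count 1..A in one pass:
# yhat_A = y_mean + Xc W (P'W)^-1 diag over cumulative q.  Using the
# orthogonal-scores identity, scores S = Xc R with R = W (P'W)^-1, and the
# response accumulates as cumsum_a S[, a] * q[a].
.predict_all_lv <- function(model, newdata) {
  X <- as.matrix(newdata)
  R <- model$W %*% solve(crossprod(model$P, model$W))
  S <- sweep(X, 2, model$x_center) %*% R
  contrib <- sweep(S, 2, model$q, "*")
  cum <- if (ncol(contrib) == 1) contrib else t(apply(contrib, 1, cumsum))
  model$y_mean + cum
}

#' Cross-validated latent-variable selection
#'
#' Shuffles rows once (stratified by class) into `k` near-equal folds, and
#' for each fold refits the model on the remaining folds (recentering inside
#' the fold to avoid leakage), recording held-out accuracy for every number
#' of latent variables up to `A_max`.  The chosen complexity maximizes the
#' overall cross-validated accuracy, ties going to the smallest model.
#'
#' @param X Predictor matrix.
#' @param labels Class label per row.
#' @param A_max Largest number of latent variables to evaluate.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the single fold shuffle.
#' @param positive Class coded 1.
#' @return Object of class `cv_curve`: list with `A` (evaluated counts),
#'   `accuracy` (overall CV accuracy per A, percent), `per_class` (matrix,
#'   percent), `chosen`.
#' @export
crossval_select <- function(X, labels, A_max = 10, k = 10, seed = 1,
                            positive = "HFD") {
  X <- as.matrix(X)
  labels <- as.character(labels)
  stopifnot(k >= 2, A_max >= 1)
  if (length(unique(labels)) < 2) stop("response has zero variance")
  set.seed(seed)
  fold <- integer(nrow(X))
  for (cl in unique(labels)) {
    rows <- which(labels == cl)
    fold[rows] <- rep_len(seq_len(k), length(rows))[sample.int(length(rows))]
  }
  if (min(table(fold)) < 2) stop("fold with fewer than 2 rows")
  A_max <- min(A_max, ncol(X))
  pred <- matrix(NA_real_, nrow(X), A_max)
  for (f in seq_len(k)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    m <- plsda_train(X[tr, , drop = FALSE], labels[tr],
                     A = min(A_max, length(tr) - 1), positive = positive)
    ph <- .predict_all_lv(m, X[te, , drop = FALSE])
    pred[te, seq_len(ncol(ph))] <- ph
  }
  pos <- positive
  neg <- setdiff(unique(labels), positive)
  classes <- c(neg, pos)
  acc <- numeric(A_max)
  per_class <- matrix(NA_real_, A_max, 2, dimnames = list(NULL, classes))
  for (a in seq_len(A_max)) {
    hat <- ifelse(pred[, a] > 0.5, pos, neg)
    acc[a] <- 100 * mean(hat == labels)
    for (cl in classes) {
      rows <- labels == cl
      per_class[a, cl] <- 100 * mean(hat[rows] == labels[rows])
    }
  }
  chosen <- which.max(acc)  # ties -> smallest A
  structure(list(A = seq_len(A_max), accuracy = acc, per_class = per_class,
                 chosen = chosen),
            class = "cv_curve")
}

#' @export
print.cv_curve <- function(x, ...) {
  cat("cv_curve: chosen A =", x$chosen, "\n")
  print(data.frame(A = x$A, accuracy = round(x$accuracy, 2)))
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt(J * sum_a SSY_a (w_ja / ||w_a||)^2 / sum_a SSY_a)` with
#' `SSY_a = q_a^2 t_a' t_a`; the mean of the squared VIP scores over
#' channels is exactly 1.
#'
#' @param model A `plsda` model (or `fit_pls1` result).
#' @return Numeric vector of per-channel VIP scores.
#' @export
vip <- function(model) {
  W <- model$W
  J <- nrow(W)
  ssy <- model$q^2 * colSums(model$T^2)
  Wn <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  sqrt(J * drop(Wn^2 %*% ssy) / sum(ssy))
}

#' Discriminant spectral regions from VIP scores
#'
#' Channels with VIP > 1 are significant; contiguous significant channels
#' are merged into regions, each labeled by the sign of the mean regression
#' coefficient inside it (positive = more intense in the class coded 1).
#'
#' @param model A `plsda` model.
#' @param grid Wavenumber grid aligned with the model channels.
#' @return Object of class `discriminant_report`: list with `vip`,
#'   `coefficients`, `significant` (logical mask) and `regions` (data frame
#'   with `lo`, `hi`, `start`, `end`, `direction`).
#' @export
discriminant_regions <- function(model, grid) {
  stopifnot(length(grid) == length(model$b))
  v <- vip(model)
  mask <- v > 1
  pos_cl <- names(model$class_code)[model$class_code == 1]
  neg_cl <- names(model$class_code)[model$class_code == 0]
  regions <- data.frame(lo = numeric(0), hi = numeric(0),
                        start = integer(0), end = integer(0),
                        direction = character(0))
  if (any(mask)) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sig <- which(r$values)
    regions <- do.call(rbind, lapply(sig, function(s) {
      ii <- starts[s]:ends[s]
      data.frame(lo = grid[starts[s]], hi = grid[ends[s]],
                 start = starts[s], end = ends[s],
                 direction = if (mean(model$b[ii]) > 0) {
                   paste0(pos_cl, "-higher")
                 } else {
                   paste0(neg_cl, "-higher")
                 },
                 stringsAsFactors = FALSE)
    }))
    rownames(regions) <- NULL
  }
  structure(list(vip = v, coefficients = model$b, significant = mask,
                 regions = regions),
            class = "discriminant_report")
}

#' @export
print.discriminant_report <- function(x, ...) {
  cat("discriminant_report:", sum(x$significant), "of",
      length(x$significant), "channels with VIP > 1 in",
      nrow(x$regions), "regions\n")
  if (nrow(x$regions)) {
    print(data.frame(lo = round(x$regions$lo, 1), hi = round(x$regions$hi, 1),
                     direction = x$regions$direction))
  }
  invisible(x)
}

#' Evaluate classification accuracy
#'
#' @param model A `plsda` model.
#' @param X_test Test predictor matrix.
#' @param labels_test Test labels.
#' @return List with `per_class` (named vector of per-class accuracies, in
#'   percent) and `overall` (percent, weighted by class size).
#' @export
evaluate <- function(model, X_test, labels_test) {
  labels_test <- as.character(labels_test)
  stopifnot(nrow(as.matrix(X_test)) == length(labels_test))
  hat <- classify(predict(model, X_test), model)
  classes <- names(model$class_code)
  per_class <- vapply(classes, function(cl) {
    rows <- labels_test == cl
    if (!any(rows)) stop("no test rows for class '", cl, "'")
    100 * mean(hat[rows] == cl)
  }, 0)
  list(per_class = per_class, overall = 100 * mean(hat == labels_test))
}

#' Persist / restore a PLS-DA model as JSON
#'
#' @param model A `plsda` model.
#' @param file Path of the JSON file.
#' @return `read_plsda` returns the reconstructed model (scores `T` are not
#'   persisted; VIP scores are, so reports remain reproducible).
#' @export
write_plsda <- function(model, file) {
  stopifnot(inherits(model, "plsda"))
  payload <- list(W = model$W, P = model$P, q = model$q, b = model$b,
                  n_lv = model$n_lv, x_center = model$x_center,
                  y_mean = model$y_mean,
                  class_code = as.list(model$class_code),
                  threshold = model$threshold, vip = vip(model))
  jsonlite::write_json(payload, file, digits = NA)
  invisible(file)
}

#' @rdname write_plsda
#' @export
read_plsda <- function(file) {
  p <- jsonlite::read_json(file, simplifyVector = TRUE)
  structure(list(W = as.matrix(p$W), P = as.matrix(p$P), q = p$q,
                 T = NULL, b = p$b, n_lv = p$n_lv, x_center = p$x_center,
                 y_mean = p$y_mean,
                 class_code = unlist(p$class_code),
                 threshold = p$threshold, vip_scores = p$vip),
            class = "plsda")
}
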