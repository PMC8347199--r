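centered <- function(M) sweep(as.matrix(M), 2, colMeans(as.matrix(M)))

test_that("PLS1 with a single predictor reduces to univariate least squares", {
  set.seed(1)
  x <- rnorm(15)
  y <- 2 * x + rnorm(15, sd = 0.3)
  xc <- x - mean(x)
  yc <- y - mean(y)
  fit <- fit_pls1(matrix(xc, ncol = 1), yc, A = 1)
  yhat <- drop(matrix(xc, ncol = 1) %*% fit$b)
  ols <- xc * sum(xc * yc) / sum(xc^2)
  expect_equal(yhat, ols, tolerance = 1e-10)
})

test_that("NIPALS at full rank equals the least-squares projection", {
  for (seed in c(3, 4, 5)) {
    set.seed(seed)
    X <- centered(matrix(rnorm(8 * 5), 8, 5))
    y <- drop(centered(matrix(rnorm(8), ncol = 1)))
    fit <- fit_pls1(X, y, A = 5)
    yhat <- drop(X %*% fit$b)
    ols <- drop(X %*% qr.coef(qr(X), y))
    expect_equal(yhat, ols, tolerance = 1e-8)
    # scores are mutually orthogonal
    G <- crossprod(fit$T)
    expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  }
})

test_that("training residual sum of squares is non-increasing in A", {
  set.seed(6)
  X <- centered(matrix(rnorm(20 * 10), 20, 10))
  y <- drop(centered(matrix(rnorm(20), ncol = 1)))
  rss <- vapply(1:8, function(a) {
    fit <- fit_pls1(X, y, a)
    sum((y - drop(X %*% fit$b))^2)
  }, 0)
  expect_true(all(diff(rss) <= 1e-10))
})

test_that("fit_pls1 validates the component count and response variance", {
  X <- centered(matrix(rnorm(12), 4, 3))
  expect_error(fit_pls1(X, rnorm(4), A = 4), "A must lie")
  expect_error(fit_pls1(X, rep(0, 4), A = 1), "zero variance")
})

test_that("predict matches score-space accumulation and restores the scale", {
  set.seed(9)
  X <- matrix(rnorm(30 * 6), 30, 6)
  labels <- rep(c("CTRL", "HFD"), 15)
  X[labels == "HFD", 1] <- X[labels == "HFD", 1] + 3
  m <- plsda_train(X, labels, A = 3)
  yhat <- predict(m, X)
  # two-route equivalence: coefficient route vs cumulative t_a q_a route
  via_scores <- drop(ramanclass:::.predict_all_lv(m, X)[, 3])
  expect_equal(yhat, via_scores, tolerance = 1e-10)
  # zero spectrum predicts the intercept
  expect_equal(unname(predict(m, m$x_center)), m$y_mean, tolerance = 1e-10)
  expect_error(predict(m, X[, 1:3]), "channels")
})

test_that("perfectly collinear toy data is reproduced exactly", {
  y01 <- rep(c(0, 1), each = 6)
  X <- cbind(y01, y01, y01) + 0  # predictors identical to the dummy code
  m <- plsda_train(X, ifelse(y01 == 1, "HFD", "CTRL"), A = 1)
  expect_equal(unname(predict(m, X)), y01, tolerance = 1e-10)
})

test_that("classification threshold is strict at 0.5", {
  m <- structure(list(class_code = c(CTRL = 0, HFD = 1), threshold = 0.5),
                 class = "plsda")
  expect_equal(classify(c(0.7, 0.3, 0.5, 0.5000001), m),
               c("HFD", "CTRL", "CTRL", "HFD"))
})

test_that("swapping the dummy coding mirrors predictions and classes", {
  set.seed(10)
  X <- matrix(rnorm(40 * 5), 40, 5)
  labels <- rep(c("CTRL", "HFD"), 20)
  X[labels == "HFD", 2] <- X[labels == "HFD", 2] + 2
  m_hfd <- plsda_train(X, labels, A = 2, positive = "HFD")
  m_ctrl <- plsda_train(X, labels, A = 2, positive = "CTRL")
  y1 <- predict(m_hfd, X)
  y2 <- predict(m_ctrl, X)
  expect_equal(y2, 1 - y1, tolerance = 1e-8)
  keep <- abs(y1 - 0.5) > 1e-6
  expect_equal(classify(y1, m_hfd)[keep], classify(y2, m_ctrl)[keep])
})

test_that("cross-validation separates seeded Gaussian blobs and is reproducible", {
  set.seed(14)
  n <- 60
  X <- rbind(matrix(rnorm(n * 4), n, 4),
             matrix(rnorm(n * 4, mean = 2.5), n, 4))
  labels <- rep(c("CTRL", "HFD"), each = n)
  cv <- crossval_select(X, labels, A_max = 4, k = 10, seed = 5)
  expect_equal(cv$accuracy[cv$chosen], 100)
  expect_lte(cv$chosen, 2)

  cv2 <- crossval_select(X, labels, A_max = 4, k = 10, seed = 5)
  expect_identical(cv, cv2)

  expect_error(crossval_select(X, rep("CTRL", 2 * n), A_max = 2, k = 10,
                               seed = 1), "zero variance")
})

test_that("VIP obeys its algebraic identities and the straight-loop formula", {
  set.seed(16)
  X <- centered(matrix(rnorm(20 * 6), 20, 6))
  y <- drop(centered(matrix(rnorm(20), ncol = 1)))
  fit <- fit_pls1(X, y, A = 3)
  v <- vip(fit)
  expect_equal(mean(v^2), 1, tolerance = 1e-8)
  expect_equal(v, vip_oracle(fit$W, fit$q, fit$T), tolerance = 1e-10)

  one <- fit_pls1(X, y, A = 1)
  expect_equal(vip(one),
               sqrt(ncol(X)) * abs(one$W[, 1]) / sqrt(sum(one$W[, 1]^2)),
               tolerance = 1e-10)
})

test_that("discriminant regions follow the VIP mask and coefficient signs", {
  set.seed(17)
  X <- matrix(rnorm(40 * 8), 40, 8)
  labels <- rep(c("CTRL", "HFD"), 20)
  X[labels == "HFD", 3] <- X[labels == "HFD", 3] + 2
  X[labels == "CTRL", 6] <- X[labels == "CTRL", 6] + 2
  grid <- seq(100, 800, by = 100)
  m <- plsda_train(X, labels, A = 2)
  rep1 <- discriminant_regions(m, grid)
  expect_equal(rep1$significant, vip(m) > 1)
  ch3 <- rep1$regions[rep1$regions$start <= 3 & rep1$regions$end >= 3, ]
  ch6 <- rep1$regions[rep1$regions$start <= 6 & rep1$regions$end >= 6, ]
  expect_equal(ch3$direction, "HFD-higher")
  expect_equal(ch6$direction, "CTRL-higher")

  # recoding the response flips directions but not the mask
  m_flip <- plsda_train(X, labels, A = 2, positive = "CTRL")
  rep2 <- discriminant_regions(m_flip, grid)
  expect_equal(rep2$significant, rep1$significant)
  ch3f <- rep2$regions[rep2$regions$start <= 3 & rep2$regions$end >= 3, ]
  expect_equal(ch3f$direction, "HFD-higher")  # direction names track classes

  # uniform weights give VIP exactly 1 everywhere: no channel passes VIP > 1
  flat <- list(W = matrix(0.5, 4, 1), q = 0.8, T = matrix(c(1, 2, -1, 3)),
               b = rep(0.1, 4), class_code = c(CTRL = 0, HFD = 1))
  expect_equal(vip(flat), rep(1, 4))
  expect_equal(nrow(discriminant_regions(flat, 1:4)$regions), 0)
})

test_that("evaluate reports per-class accuracies in percent", {
  set.seed(18)
  X <- matrix(rnorm(20 * 3), 20, 3)
  labels <- rep(c("CTRL", "HFD"), each = 10)
  X[labels == "HFD", 1] <- X[labels == "HFD", 1] + 50
  m <- plsda_train(X, labels, A = 1)
  perfect <- evaluate(m, X, labels)
  expect_equal(unname(perfect$per_class), c(100, 100))
  expect_equal(perfect$overall, 100)
  # complementary labels invert every decision
  flipped <- evaluate(m, X, ifelse(labels == "HFD", "CTRL", "HFD"))
  expect_equal(unname(flipped$per_class), c(0, 0))

  # hand-counted confusion fixture: 3 of 10 CTRL wrong, 1 of 10 HFD wrong
  Xc <- X
  Xc[c(1, 2, 3), 1] <- Xc[c(1, 2, 3), 1] + 50   # push 3 CTRL over the boundary
  Xc[11, 1] <- Xc[11, 1] - 50                   # pull 1 HFD under it
  conf <- evaluate(m, Xc, labels)
  expect_equal(unname(conf$per_class["CTRL"]), 70)
  expect_equal(unname(conf$per_class["HFD"]), 90)
  expect_equal(conf$overall, 80)
})

test_that("models persist to JSON with coefficients and VIP intact", {
  set.seed(19)
  X <- matrix(rnorm(24 * 4), 24, 4)
  labels <- rep(c("CTRL", "HFD"), 12)
  X[labels == "HFD", 1] <- X[labels == "HFD", 1] + 2
  m <- plsda_train(X, labels, A = 2)
  f <- withr::local_tempfile(fileext = ".json")
  write_plsda(m, f)
  m2 <- read_plsda(f)
  expect_equal(m2$b, m$b, tolerance = 1e-12)
  expect_equal(predict(m2, X), predict(m, X), tolerance = 1e-12)
  expect_equal(m2$vip_scores, unname(vip(m)), tolerance = 1e-12)
})
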