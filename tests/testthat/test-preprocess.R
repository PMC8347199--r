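test_that("modified polyfit reproduces pure polynomials and constants", {
  grid <- wavenumber_grid(200, 3400, 400)
  u <- (grid - 200) / 3200
  poly5 <- 3 + 2 * u - 5 * u^2 + u^3 + 0.5 * u^4 - 2 * u^5
  base <- polyfit_baseline(poly5, grid, order = 5)
  expect_lt(max(abs(base - poly5)) / max(abs(poly5)), 1e-8)

  const <- rep(4.2, length(grid))
  expect_equal(polyfit_baseline(const, grid, order = 0), const,
               tolerance = 1e-10)

  expect_error(polyfit_baseline(c(1, NA, 3, 4, 5, 6, 7, 8), grid[1:8],
                                order = 2), "finite")
})

test_that("modified polyfit baseline descends monotonically in the mean", {
  # the basis contains the constant, so the fit mean equals the mean of the
  # min-clipped working signal, which can only decrease across iterations
  set.seed(8)
  grid <- wavenumber_grid(200, 3400, 300)
  u <- (grid - 200) / 3200
  y <- 10 * (1 + 0.3 * u - 0.5 * u^2) +
    3 * line_shape(grid, 1200, 30) + rnorm(length(grid), sd = 0.05)
  fits <- lapply(1:6, function(k) {
    polyfit_baseline(y, grid, order = 5, max_iter = k, tol = 0)
  })
  fit_means <- vapply(fits, mean, 0)
  expect_true(all(diff(fit_means) <= 1e-10))
  # and the converged baseline sits at or below the data almost everywhere
  final <- polyfit_baseline(y, grid, order = 5)
  expect_gt(mean(final <= y + 1e-8), 0.5)
})

test_that("polyfit strips a polynomial background from under a Lorentzian", {
  grid <- wavenumber_grid(200, 3400, 3180)
  u <- (grid - 200) / 3200
  bg <- 15 * (1 + 0.1 * u - 0.12 * u^2 + 0.05 * u^3)
  amp <- 1.3
  y <- bg + amp * line_shape(grid, 1007, 12)
  corrected <- y - polyfit_baseline(y, grid, order = 5)
  got <- max(corrected[abs(grid - 1007) <= 10])
  expect_lt(abs(got - amp) / amp, 0.05)
})

test_that("batch and per-spectrum polyfit agree", {
  set.seed(31)
  grid <- wavenumber_grid(200, 3400, 250)
  Y <- t(replicate(4, 5 + 2 * line_shape(grid, 1500, 40) +
                     rnorm(length(grid), sd = 0.1)))
  batch <- ramanclass:::.polyfit_baseline_matrix(Y, grid, order = 4)
  for (i in 1:4) {
    expect_equal(batch[i, ], polyfit_baseline(Y[i, ], grid, order = 4),
                 tolerance = 1e-10)
  }
})

test_that("AsLS solves the penalized system exactly on flat input", {
  y <- rep(3.7, 60)
  expect_equal(asls_baseline(y, lam = 1e5, p = 0.01), y, tolerance = 1e-8)
})

test_that("AsLS banded solver matches a dense direct solve", {
  set.seed(99)
  for (n in c(50, 120, 200)) {
    y <- 2 + sin(seq(0, 4 * pi, length.out = n)) +
      3 * exp(-((seq_len(n) - n / 2)^2) / 8) + rnorm(n, sd = 0.05)
    for (lam in c(1e1, 1e4)) {
      z_band <- asls_baseline(y, lam = lam, p = 0.001, n_iter = 6)
      z_dense <- dense_asls_oracle(y, lam = lam, p = 0.001, n_iter = 6)
      expect_lt(max(abs(z_band - z_dense)), 1e-8)
    }
  }
})

test_that("AsLS tracks smooth signals as the penalty vanishes", {
  x <- seq(0, 2 * pi, length.out = 80)
  y <- 5 + sin(x)
  dev <- vapply(c(1e0, 1e-2, 1e-4), function(lam) {
    max(abs(asls_baseline(y, lam = lam, p = 0.2, n_iter = 4) - y))
  }, 0)
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[3], 1e-3)
})

test_that("AsLS with small p stays below peaked signals almost everywhere", {
  set.seed(12)
  n <- 400
  y <- 2 * exp(-((seq_len(n) - 180)^2) / 50) + rnorm(n, sd = 0.01)
  z <- asls_baseline(y, lam = 1e4, p = 0.001)
  expect_lte(mean(z > y + 3 * 0.01), 0.05)
})

test_that("AsLS rejects invalid parameters", {
  y <- rnorm(20)
  expect_error(asls_baseline(y, lam = 0), "lam")
  expect_error(asls_baseline(y, lam = -5), "lam")
  expect_error(asls_baseline(y, p = 0), "p must")
  expect_error(asls_baseline(y, p = 0.5), "p must")
  expect_error(asls_baseline(y[1:2]), "at least 3")
})

test_that("subtract_baseline is elementwise, additive and length-checked", {
  y <- c(1, 4, 9, 16)
  expect_equal(subtract_baseline(y, rep(0, 4)), y)
  expect_equal(subtract_baseline(y, y), rep(0, 4))
  a <- c(1, 1, 1, 1)
  b <- c(0.5, 0.25, 0, -0.25)
  expect_equal(subtract_baseline(y, a + b),
               subtract_baseline(subtract_baseline(y, a), b))
  expect_error(subtract_baseline(y, 1:3), "lengths differ")
})

test_that("select_regions keeps exactly the channels inside the intervals", {
  ds <- small_dataset(seed = 41, maps = 1, per_map = 3)
  regions <- default_regions()
  cropped <- select_regions(ds, regions)

  # independent brute-force channel scan
  keep <- vapply(ds$grid, function(w) {
    any(w >= regions[, 1] & w <= regions[, 2])
  }, TRUE)
  expect_equal(ncol(cropped$intensities), sum(keep))
  expect_equal(cropped$grid, ds$grid[keep])
  expect_equal(length(cropped$segments), 2)

  # full-span region is the identity
  full <- select_regions(ds, region_set(rbind(range(ds$grid))))
  expect_equal(full$intensities, ds$intensities)

  # degenerate single-channel interval
  w17 <- ds$grid[17]
  one <- select_regions(ds, region_set(rbind(c(w17, w17 + 1e-9))))
  expect_equal(ncol(one$intensities), 1)
  expect_equal(one$grid, w17)

  expect_error(select_regions(ds, region_set(rbind(c(5000, 6000)))),
               "no channels")
})

test_that("unit-area normalization has integral one and is idempotent", {
  grid <- seq(0, 10, length.out = 11)
  expect_equal(normalize_unit_area(rep(2, 11), grid), rep(0.1, 11))

  set.seed(7)
  y <- abs(rnorm(11)) + 0.5
  z <- normalize_unit_area(y, grid)
  w <- ramanclass:::.trapz_weights(grid)
  expect_lt(abs(sum(w * z) - 1), 1e-9)
  expect_equal(normalize_unit_area(z, grid), z, tolerance = 1e-12)

  expect_error(normalize_unit_area(rep(0, 11), grid), "non-positive")
  expect_error(normalize_unit_area(-y, grid), "non-positive")
})

test_that("normalization integrates piecewise over cropped segments", {
  ds <- small_dataset(seed = 43, maps = 1, per_map = 4)
  ds <- correct_baselines(ds)
  cropped <- select_regions(ds)
  norm <- normalize_unit_area(cropped)
  w <- ramanclass:::.trapz_weights(cropped$grid, cropped$segments)
  areas <- drop(norm$intensities %*% w)
  expect_true(all(abs(areas - 1) < 1e-9))
  # gap between the fingerprint and high-wavenumber blocks carries no weight
  expect_lt(max(w), 2 * stats::median(diff(ds$grid)))
})

test_that("mean centering uses training means only", {
  set.seed(13)
  train <- matrix(rnorm(60), 10, 6)
  test <- matrix(rnorm(30, mean = 2), 5, 6)
  out <- mean_center(train, test)
  expect_true(all(abs(colMeans(out$train)) < 1e-10))
  expect_true(all(abs(colMeans(out$applied[[1]])) > 0.5))
  expect_equal(out$center, colMeans(train))

  two <- matrix(rep(c(1, 5, 3), each = 2), 2, 3)
  expect_true(all(mean_center(two)$train == 0))
})

test_that("assemble_matrix orders rows and validates grids", {
  grid <- wavenumber_grid(400, 600, 50)
  lib <- default_band_library()
  mk <- function(cl, map, x) {
    suppressWarnings(synth_spectrum(grid, lib, cl,
                                    meta = list(map_id = map, x = x, y = 0)))
  }
  sp <- list(mk("HFD", "m2", 0), mk("CTRL", "m1", 25), mk("CTRL", "m1", 0))
  ds <- assemble_matrix(sp)
  expect_equal(dim(ds$intensities), c(3, 50))
  expect_equal(ds$labels, c("CTRL", "CTRL", "HFD"))
  expect_equal(ds$meta$x, c(0, 25, 0))

  one <- assemble_matrix(sp[1])
  expect_equal(dim(one$intensities), c(1, 50))

  expect_error(assemble_matrix(list()), "empty")

  bad <- mk("HFD", "weird_map", 0)
  bad$grid <- wavenumber_grid(400, 600, 49)
  bad$intensities <- bad$intensities[1:49]
  expect_error(assemble_matrix(c(sp, list(bad))), "weird_map")
})
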