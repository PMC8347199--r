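# Independent reference implementations used as oracles.  These deliberately
# favour clarity over speed and do not share code with the package internals.

# Dense direct solve of the AsLS penalized system, one reweighting loop.
dense_asls_oracle <- function(y, lam, p, n_iter) {
  n <- length(y)
  D <- diff(diag(n), differences = 2)
  P <- lam * crossprod(D)
  w <- rep(1, n)
  z <- NULL
  for (it in seq_len(n_iter)) {
    z <- solve(diag(w) + P, w * y)
    w <- ifelse(y > z, p, 1 - p)
  }
  z
}

# Literal step-by-step execution of the duplex selection rules.
duplex_oracle <- function(X, n_train) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  farthest_pair <- function(pool) {
    best <- NULL
    best_d <- -1
    for (i in pool) {
      for (j in pool) {
        if (i < j && D[i, j] > best_d) {
          best_d <- D[i, j]
          best <- c(i, j)
        }
      }
    }
    best
  }
  pool <- seq_len(n)
  train <- farthest_pair(pool)
  pool <- setdiff(pool, train)
  test <- farthest_pair(pool)
  pool <- setdiff(pool, test)
  n_test <- n - n_train
  farthest_from <- function(set, pool) {
    d <- vapply(pool, function(i) min(D[i, set]), 0)
    pool[which.max(d)]
  }
  while (length(pool)) {
    if (length(train) < n_train) {
      i <- farthest_from(train, pool)
      train <- c(train, i)
      pool <- setdiff(pool, i)
    }
    if (length(test) >= n_test) {
      train <- c(train, pool)
      break
    }
    if (length(pool)) {
      i <- farthest_from(test, pool)
      test <- c(test, i)
      pool <- setdiff(pool, i)
    }
    if (length(train) >= n_train && length(pool)) {
      test <- c(test, pool)
      break
    }
  }
  list(train = sort(train), test = sort(test))
}

# Straight-loop evaluation of the VIP formula.
vip_oracle <- function(W, q, Tm) {
  J <- nrow(W)
  A <- ncol(W)
  ssy <- numeric(A)
  for (a in seq_len(A)) ssy[a] <- q[a]^2 * sum(Tm[, a]^2)
  out <- numeric(J)
  for (j in seq_len(J)) {
    acc <- 0
    for (a in seq_len(A)) {
      acc <- acc + ssy[a] * (W[j, a] / sqrt(sum(W[, a]^2)))^2
    }
    out[j] <- sqrt(J * acc / sum(ssy))
  }
  out
}

# Small noisy two-class dataset used across tests (fast: few spectra).
small_dataset <- function(seed = 11, maps = 2, per_map = 40, noise_sd = 0.3) {
  synth_dataset(generator_config(n_maps_per_class = maps,
                                 spectra_per_map = per_map,
                                 noise_sd = noise_sd, seed = seed),
                default_band_library())
}
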