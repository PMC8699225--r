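# Independent brute-force oracles and small-panel builders shared across
# the suite. The oracles deliberately use naive element-by-element loops of
# the printed formulas, never the package's matrix code paths.

random_panel <- function(n, m, ploidy = 4L, seed, freq = c(0.1, 0.9)) {
  withr::with_seed(seed, {
    repeat {
      p <- runif(m, freq[1], freq[2])
      v <- sapply(p, function(pi) rbinom(n, ploidy, pi))
      d <- dosage_matrix(matrix(v, n, m), ploidy = ploidy)
      pp <- allele_freq(d)
      if (all(pp > 0 & pp < 1)) return(d)
    }
  })
}

# VanRaden / weighted G, element by element: entries of the centered
# dosage cross-product with an optional diagonal weight, over the
# explicit per-marker sum.
oracle_vanraden <- function(d, w = NULL, denominator = "ploidy_scaled") {
  W <- d$values; n <- nrow(W); m <- ncol(W)
  p <- colMeans(W) / d$ploidy
  if (is.null(w)) w <- rep(1, m)
  mult <- if (denominator == "ploidy_scaled") d$ploidy else 2
  cs <- mult * sum(p * (1 - p))
  G <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    s <- 0
    for (i in seq_len(m))
      s <- s + w[i] * (W[j, i] - d$ploidy * p[i]) * (W[k, i] - d$ploidy * p[i])
    G[j, k] <- s / cs
  }
  G
}

oracle_yang <- function(d) {
  W <- d$values; n <- nrow(W); N <- ncol(W)
  p <- colMeans(W) / 2
  G <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    s <- 0
    for (i in seq_len(N)) {
      den <- 2 * p[i] * (1 - p[i])
      s <- s + if (j != k)
        (W[j, i] - 2 * p[i]) * (W[k, i] - 2 * p[i]) / den
      else (W[j, i]^2 - (1 + 2 * p[i]) * W[j, i] + 2 * p[i]^2) / den
    }
    G[j, k] <- if (j != k) s / N else 1 + s / N
  }
  G
}

# Full-autotetraploid G over the 5m indicator columns with class
# frequencies strictly inside (0, 1).
oracle_slater <- function(d) {
  V <- round(d$values); n <- nrow(V); m <- ncol(V)
  cols <- list()
  for (mk in seq_len(m)) for (cl in 0:4) {
    x <- as.numeric(V[, mk] == cl)
    f <- mean(x)
    if (f > 0 && f < 1) cols[[length(cols) + 1L]] <- list(x = x, f = f)
  }
  M <- 5 * m
  G <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    s <- 0
    for (cc in cols)
      s <- s + (cc$x[j] - cc$f) * (cc$x[k] - cc$f) / (cc$f * (1 - cc$f))
    G[j, k] <- 1 + s / M
  }
  G
}

# dense-grid REML oracle: direct determinant-based restricted-likelihood
# criterion evaluated by brute force over log(delta)
oracle_reml_grid <- function(y, K, X = NULL, grid = seq(-6, 6, by = 0.001)) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  q <- ncol(X)
  crit <- vapply(grid, function(logd) {
    H <- K + exp(logd) * diag(n)
    Hi <- solve(H)
    XtHiX <- crossprod(X, Hi %*% X)
    P <- Hi - Hi %*% X %*% solve(XtHiX, crossprod(X, Hi))
    yPy <- as.numeric(crossprod(y, P %*% y))
    -((n - q) * log(yPy) + determinant(H)$modulus + determinant(XtHiX)$modulus)
  }, 0)
  grid[which.max(crit)]
}
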