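# Independent oracles, coded directly from the defining formulas with
# plain double loops / dense solves. They deliberately share no code
# path with the package implementations they check.

oracle_lee <- function(x, y, V) {
  V <- as.matrix(V)
  n <- length(x)
  xbar <- sum(x) / n
  ybar <- sum(y) / n
  num <- 0
  for (i in seq_len(n)) {
    lx <- 0
    ly <- 0
    for (j in seq_len(n)) {
      lx <- lx + V[i, j] * (x[j] - xbar)
      ly <- ly + V[i, j] * (y[j] - ybar)
    }
    num <- num + lx * ly
  }
  S <- 0
  for (i in seq_len(n)) S <- S + sum(V[i, ])^2
  (n / S) * num / (sqrt(sum((x - xbar)^2)) * sqrt(sum((y - ybar)^2)))
}

oracle_moran <- function(x, V) {
  V <- as.matrix(V)
  n <- length(x)
  xbar <- sum(x) / n
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + V[i, j] * (x[i] - xbar) * (x[j] - xbar)
    }
  }
  (n / sum(V)) * num / sum((x - xbar)^2)
}

# Closed-form weighted least squares via explicit normal equations.
oracle_wls <- function(X, y, w) {
  XtWX <- t(X) %*% diag(w) %*% X
  coefs <- solve(XtWX, t(X) %*% (w * y))
  res <- y - X %*% coefs
  sigma2 <- sum(w * res^2) / (nrow(X) - ncol(X))
  list(coef = drop(coefs), se = sqrt(diag(solve(XtWX)) * sigma2))
}

# Random spatial weight matrix: symmetric binary contiguity from random
# points thresholded at a radius, optionally row-standardized; isolated
# units are connected to their nearest neighbour so rows are nonzero.
random_weights <- function(n, row_standardize = TRUE) {
  pts <- cbind(runif(n), runif(n))
  d <- as.matrix(dist(pts))
  thr <- quantile(d[upper.tri(d)], 0.15)
  A <- (d <= thr) * 1
  diag(A) <- 0
  for (i in which(rowSums(A) == 0)) {
    j <- order(d[i, ])[2]
    A[i, j] <- A[j, i] <- 1
  }
  if (row_standardize) A / rowSums(A) else A
}

# Row-standardized weights for a path graph 1-2-...-n.
path_weights <- function(n, row_standardize = TRUE) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  if (row_standardize) A / rowSums(A) else A
}

# Small deterministic cohort for model-fitting tests.
toy_cohort <- function(n = 60, seed = 1) {
  set.seed(seed)
  data.frame(
    id = seq_len(n),
    x = runif(n, 0, 1000), y = runif(n, 0, 1000),
    trait = rnorm(n), pgs = rnorm(n),
    sex = rbinom(n, 1, 0.5), age = rnorm(n, 10.7, 0.12)
  )
}
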