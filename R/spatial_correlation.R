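#' Contiguity spatial weights for an analysis grid
#'
#' Binary first-order contiguity on the hexagonal lattice (`v_ij = 1` for
#' nodes sharing a hexagon edge, else 0, zero diagonal), optionally
#' row-standardized so each nonzero row sums to one. This is the
#' canonical neighbour definition for values observed on a regular grid
#' and is the default weight matrix for all map comparisons.
#'
#' @param grid An `analysis_grid` from [build_hex_grid()].
#' @param row_standardize Divide each row by its sum (default `TRUE`).
#' @return A sparse `dgCMatrix` (n x n) with attribute
#'   `row_standardized`. Isolated nodes keep an all-zero row, with a
#'   warning.
#' @export
contiguity_weights <- function(grid, row_standardize = TRUE) {
  stopifnot(inherits(grid, "analysis_grid"))
  adj <- grid$adjacency
  n <- length(adj)
  deg <- lengths(adj)
  if (any(deg == 0)) {
    warning(sprintf("%d isolated grid node(s) have all-zero weight rows: %s",
                    sum(deg == 0), paste(which(deg == 0), collapse = ", ")))
  }
  i <- rep.int(seq_len(n), deg)
  j <- unlist(adj, use.names = FALSE)
  x <- if (row_standardize) 1 / deg[i] else rep(1, length(i))
  W <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
  attr(W, "row_standardized") <- row_standardize
  W
}

# Internal: shared validation for the spatial statistics.
.check_spatial_inputs <- function(x, y = NULL, W) {
  n <- length(x)
  if (!is.null(y) && length(y) != n) {
    pgsmap_error("x and y must have the same length", "pgsmap_dimension_error")
  }
  if (nrow(W) != n || ncol(W) != n) {
    pgsmap_error("weight matrix dimensions do not match the value vectors",
                 "pgsmap_dimension_error")
  }
  if (stats::sd(x) == 0 || (!is.null(y) && stats::sd(y) == 0)) {
    pgsmap_error("input vector is constant; spatial correlation undefined",
                 "pgsmap_zero_variance")
  }
  if (all(W == 0)) {
    pgsmap_error("weight matrix is identically zero", "pgsmap_degenerate_weights")
  }
  invisible(TRUE)
}

#' Lee's L bivariate spatial association statistic
#'
#' Lee's L integrates Pearson's correlation with Moran-type spatial
#' smoothing: with spatial lags `lag(x)_i = sum_j v_ij (x_j - xbar)`,
#'
#' \deqn{L = \frac{n}{\sum_i (\sum_j v_{ij})^2}
#'   \cdot \frac{\sum_i \mathrm{lag}(x)_i \, \mathrm{lag}(y)_i}
#'   {\sqrt{\sum_i (x_i-\bar x)^2}\sqrt{\sum_i (y_i-\bar y)^2}}.}
#'
#' It measures spatial co-patterning: the extent to which the two
#' surfaces are correlated *and* that correlation is spatially clustered.
#' With the degenerate "self-only" weight matrix (identity), the lag is
#' the value itself and L reduces exactly to Pearson's r. L is symmetric
#' in `x` and `y`.
#'
#' @param x,y Numeric vectors of values at the n spatial units.
#' @param W n x n non-negative weight matrix (base or Matrix), typically
#'   from [contiguity_weights()].
#' @return The scalar L.
#' @examples
#' W <- diag(4)
#' lee_statistic(1:4, c(2, 1, 4, 3), W)  # equals cor(x, y)
#' @export
lee_statistic <- function(x, y, W) {
  .check_spatial_inputs(x, y, W)
  xc <- x - mean(x)
  yc <- y - mean(y)
  lagx <- as.numeric(W %*% xc)
  lagy <- as.numeric(W %*% yc)
  S <- sum(Matrix::rowSums(W)^2)
  (length(x) / S) * sum(lagx * lagy) / sqrt(sum(xc^2) * sum(yc^2))
}

#' Moran's I global spatial autocorrelation statistic
#'
#' \deqn{I = \frac{n}{\sum_{ij} v_{ij}} \cdot
#'   \frac{\sum_{ij} v_{ij}(x_i-\bar x)(x_j-\bar x)}{\sum_i (x_i-\bar x)^2}.}
#'
#' Under random permutation of `x` across units, `E[I] = -1/(n-1)`.
#'
#' @inheritParams lee_statistic
#' @return The scalar I.
#' @export
moran_i <- function(x, W) {
  .check_spatial_inputs(x, NULL, W)
  xc <- x - mean(x)
  (length(x) / sum(W)) * sum(xc * as.numeric(W %*% xc)) / sum(xc^2)
}

#' Monte-Carlo permutation test for Lee's L
#'
#' Computes the observed L, then recomputes it under `M` random
#' rearrangements of the values across spatial units. Two permutation
#' schemes are available:
#'
#' * `"joint"` (default): the pairs `(x_i, y_i)` are permuted together,
#'   preserving the aspatial (Pearson) correlation while destroying the
#'   spatial arrangement. The null is "no spatial co-patterning beyond
#'   what the aspatial correlation implies under random arrangement".
#'   This matches the convention of classical spatial-statistics software
#'   for the bivariate L.
#' * `"one"`: only `y` is permuted, leaving `x` in place. Under the null
#'   that `y` is independent of `x` and spatially unstructured, this test
#'   is exact regardless of any autocorrelation in `x`; it is the
#'   appropriate choice for testing whether a surface with no residual
#'   spatial structure of its own aligns with an autocorrelated map.
#'
#' The two-tailed p-value doubles the smaller one-sided Monte-Carlo tail,
#' `p = 2 min(Phat[L* >= L_obs], Phat[L* <= L_obs])` with
#' `Phat = (1 + count)/(M + 1)` (ties count as exceedances), capped at 1.
#' With `M = 10000` the smallest attainable p is `2/10001`, about
#' 2.0e-4.
#'
#' @inheritParams lee_statistic
#' @param M Number of permutations, at least 99.
#' @param seed Integer seed for reproducibility (optional).
#' @param scheme Permutation scheme, `"joint"` or `"one"`.
#' @return A `lee_test` object: list with `L`, `M`, `p`, `perm_mean`,
#'   `perm_sd`, `scheme`, `seed`.
#' @export
lee_permutation_test <- function(x, y, W, M = 10000, seed = NULL,
                                 scheme = c("joint", "one")) {
  scheme <- match.arg(scheme)
  if (M < 99) pgsmap_error("need at least 99 permutations", "pgsmap_config_error")
  .check_spatial_inputs(x, y, W)
  if (!is.null(seed)) set.seed(as.integer(seed))

  n <- length(x)
  xc <- x - mean(x)
  yc <- y - mean(y)
  denom <- sqrt(sum(xc^2) * sum(yc^2))
  S <- sum(Matrix::rowSums(W)^2)
  cfac <- n / (S * denom)

  lagx0 <- as.numeric(W %*% xc)
  L_obs <- cfac * sum(lagx0 * as.numeric(W %*% yc))

  Lstar <- numeric(M)
  for (m in seq_len(M)) {
    p_ <- sample.int(n)
    lagy <- as.numeric(W %*% yc[p_])
    lagx <- if (scheme == "joint") as.numeric(W %*% xc[p_]) else lagx0
    Lstar[m] <- cfac * sum(lagx * lagy)
  }
  p_hi <- (1 + sum(Lstar >= L_obs)) / (M + 1)
  p_lo <- (1 + sum(Lstar <= L_obs)) / (M + 1)
  structure(
    list(L = L_obs, M = M, p = min(1, 2 * min(p_hi, p_lo)),
         perm_mean = mean(Lstar), perm_sd = stats::sd(Lstar),
         scheme = scheme, seed = seed),
    class = "lee_test"
  )
}

#' @export
print.lee_test <- function(x, ...) {
  cat(sprintf("Lee's L Monte-Carlo permutation test (%s scheme)\n", x$scheme))
  if (!is.null(x$pair)) cat(sprintf("  maps: %s vs %s\n", x$pair[1], x$pair[2]))
  if (!is.null(x$transforms)) {
    cat(sprintf("  transforms: %s / %s\n", x$transforms[1], x$transforms[2]))
  }
  cat(sprintf("  L = %.4g, M = %d permutations, two-tailed p = %.4g\n",
              x$L, x$M, x$p))
  cat(sprintf("  permutation null: mean %.4g, sd %.4g\n", x$perm_mean, x$perm_sd))
  invisible(x)
}

#' Compare two aligned maps with the Lee permutation test
#'
#' Takes two per-node value tables (fitted `local_fit_map`s or
#' environmental surfaces), aligns them on the grid node index, applies
#' the stated transforms, and runs [lee_permutation_test()]. Used both
#' for across-threshold comparisons of genetic-influence maps and for
#' comparing genetic-influence maps with environmental surfaces.
#'
#' @param map_a,map_b Data frames with a `node` column and the value
#'   column named by `value_a`/`value_b` (default `"beta"`, the fitted
#'   map column; give e.g. `"value"` for an environmental surface).
#' @param W Spatial weight matrix over the common grid.
#' @param M,seed,scheme Passed to [lee_permutation_test()].
#' @param value_a,value_b Value column names.
#' @param transform_a,transform_b `"identity"` or `"log"`, applied via
#'   [env_transform()] before testing (positively skewed environmental
#'   measures are log-transformed).
#' @return A `lee_test` with added `pair` (the two map labels) and
#'   `transforms` provenance fields.
#' @export
compare_maps <- function(map_a, map_b, W, M = 10000, seed = NULL,
                         value_a = "beta", value_b = "beta",
                         transform_a = "identity", transform_b = "identity",
                         scheme = c("joint", "one")) {
  la <- .map_label(map_a, value_a)
  lb <- .map_label(map_b, value_b)
  map_a <- as.data.frame(map_a)
  map_b <- as.data.frame(map_b)
  if (!("node" %in% names(map_a)) || !("node" %in% names(map_b))) {
    pgsmap_error("both maps need a `node` index column", "pgsmap_alignment_error")
  }
  if (!(value_a %in% names(map_a)) || !(value_b %in% names(map_b))) {
    pgsmap_error(sprintf("value column missing: need `%s` in map_a and `%s` in map_b",
                         value_a, value_b), "pgsmap_config_error")
  }
  map_a <- map_a[order(map_a$node), , drop = FALSE]
  map_b <- map_b[order(map_b$node), , drop = FALSE]
  if (!identical(as.integer(map_a$node), as.integer(map_b$node))) {
    bad <- union(setdiff(map_a$node, map_b$node), setdiff(map_b$node, map_a$node))
    pgsmap_error(paste0("maps are not aligned on the same grid nodes; unmatched: ",
                        paste(utils::head(bad, 10), collapse = ", ")),
                 "pgsmap_alignment_error")
  }
  x <- env_transform(map_a[[value_a]], transform_a)
  y <- env_transform(map_b[[value_b]], transform_b)
  res <- lee_permutation_test(x, y, W, M = M, seed = seed, scheme = scheme)
  res$pair <- c(la, lb)
  res$transforms <- c(transform_a, transform_b)
  res
}

.map_label <- function(map, value_col) {
  sp <- attr(map, "spec")
  if (!is.null(sp)) paste0(sp$trait, "~", sp$pgs) else value_col
}

#' Transform environmental surface values
#'
#' @param values Numeric vector.
#' @param kind `"identity"` or `"log"` (natural log; requires strictly
#'   positive values).
#' @return Transformed vector.
#' @export
env_transform <- function(values, kind = c("identity", "log")) {
  kind <- match.arg(kind)
  if (kind == "identity") return(values)
  bad <- which(!is.na(values) & values <= 0)
  if (length(bad)) {
    pgsmap_error(paste0("log transform requires positive values; offending nodes: ",
                        paste(utils::head(bad, 10), collapse = ", ")),
                 "pgsmap_transform_error")
  }
  log(values)
}

#' Bonferroni strong-evidence flags
#'
#' Flags p-values below `alpha / k`. With the conventional `alpha = .05`
#' and `k = 15` comparisons (five environmental surfaces by three
#' traits), the threshold is .05/15 = .0033, i.e. the "p < .003" strong
#' evidence rule.
#'
#' @param p_values Numeric vector of p-values.
#' @param alpha Family-wise error rate.
#' @param k Number of tests in the family, at least 1.
#' @return Logical vector.
#' @export
bonferroni_flag <- function(p_values, alpha = 0.05, k) {
  if (k < 1) pgsmap_error("k must be >= 1", "pgsmap_config_error")
  p_values < alpha / k
}
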