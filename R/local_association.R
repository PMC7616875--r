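#' Inverse-distance weight kernel
#'
#' Participants contribute to the regression at an analysis location with
#' weight `w_i = 1 / max(d_i, min_distance)^power`, where `d_i` is the
#' Euclidean distance from participant `i` to the location. Every
#' participant contributes to every local analysis; closer participants
#' simply count more. The default power of 0.5 gives a deliberately flat
#' kernel, trading spatial resolution for estimation stability so local
#' estimates are smoothed towards the population mean. The `min_distance`
#' floor (default 50 m, about the radius of a small residential postcode
#' zone) keeps weights finite when a participant sits exactly on a node.
#'
#' @param power Positive exponent of the inverse-distance weight.
#' @param min_distance Positive distance floor in metres.
#' @return A `weight_kernel` object.
#' @export
weight_kernel <- function(power = 0.5, min_distance = 50) {
  if (!is.numeric(power) || length(power) != 1 || !is.finite(power) || power <= 0) {
    pgsmap_error("kernel power must be a positive number", "pgsmap_config_error")
  }
  if (!is.numeric(min_distance) || length(min_distance) != 1 ||
      !is.finite(min_distance) || min_distance <= 0) {
    pgsmap_error("kernel min_distance must be a positive length", "pgsmap_config_error")
  }
  structure(list(power = power, min_distance = min_distance), class = "weight_kernel")
}

#' Distance weights of participants for one analysis location
#'
#' @param coords Two-column matrix (or data.frame) of participant
#'   coordinates, same planar units as `node`.
#' @param node Numeric length-2 vector, the analysis location.
#' @param kernel A [weight_kernel()].
#' @return Positive finite weight vector, one entry per participant.
#' @examples
#' kernel_weights(cbind(c(0, 0), c(1, 4)), c(0, 0), weight_kernel(power = 0.5))
#' @export
kernel_weights <- function(coords, node, kernel = weight_kernel()) {
  coords <- as.matrix(rbind(coords))
  d <- sqrt((coords[, 1] - node[1])^2 + (coords[, 2] - node[2])^2)
  1 / pmax(d, kernel$min_distance)^kernel$power
}

#' Model specification for local association fits
#'
#' Names the trait, the PGS column whose coefficient is mapped, and the
#' adjustment covariates. Sex is a covariate in all analyses; age is
#' included unless the trait is a cross-age composite; ancestry principal
#' component columns may be appended for sensitivity analyses.
#'
#' @param trait Trait column name.
#' @param pgs PGS column name.
#' @param covariates Character vector of covariate column names.
#' @return A `model_spec` object.
#' @export
model_spec <- function(trait, pgs, covariates = c("sex", "age")) {
  if (trait == pgs) {
    pgsmap_error("trait and pgs columns must be distinct", "pgsmap_config_error")
  }
  if (any(covariates %in% c(trait, pgs))) {
    pgsmap_error("covariates must not include the trait or pgs column",
                 "pgsmap_config_error")
  }
  structure(list(trait = trait, pgs = pgs, covariates = covariates),
            class = "model_spec")
}

# Internal: design matrix + response from a cohort data.frame.
.model_frame <- function(cohort, spec) {
  need <- c(spec$trait, spec$pgs, spec$covariates)
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    pgsmap_error(paste0("cohort is missing model columns: ",
                        paste(miss, collapse = ", ")), "pgsmap_config_error")
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(cohort[, c(spec$pgs, spec$covariates), drop = FALSE]))
  list(X = X, y = as.numeric(cohort[[spec$trait]]))
}

#' Weighted least-squares fit of the local association model
#'
#' Fits `trait ~ pgs + covariates` with an intercept by weighted least
#' squares, coefficients `(X'WX)^{-1} X'W y`. Weights are treated as
#' precision weights: standard errors use the weighted residual variance
#' `sum(w e^2) / (n - p)`, so rescaling all weights by a constant changes
#' neither coefficients nor standard errors. The per-node map entry is the
#' PGS coefficient ("genetic influence", in trait units per SD of PGS).
#'
#' @param cohort Data frame with the model columns.
#' @param spec A [model_spec()].
#' @param weights Positive weight vector, one per row of `cohort`.
#' @return List with `coefficients`, `se` (named vectors), `beta`, `se_beta`
#'   (the PGS entries), `n`, `n_effective` (`sum(w)^2 / sum(w^2)`), and
#'   `sigma2`.
#' @export
fit_weighted_model <- function(cohort, spec, weights) {
  mf <- .model_frame(cohort, spec)
  if (length(weights) != length(mf$y)) {
    pgsmap_error("weights length does not match number of rows", "pgsmap_dimension_error")
  }
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    pgsmap_error("weights must be positive and finite", "pgsmap_config_error")
  }
  if (nrow(mf$X) < ncol(mf$X) + 2) {
    pgsmap_error("too few rows for the number of coefficients", "pgsmap_dimension_error")
  }
  fit <- .wls(mf$X, mf$y, weights)
  if (!is.null(fit$singular)) {
    pgsmap_error(paste0("design matrix is rank-deficient; collinear columns: ",
                        paste(fit$singular, collapse = ", ")), "pgsmap_singular_design")
  }
  k <- match(spec$pgs, colnames(mf$X))
  list(
    coefficients = fit$coef, se = fit$se,
    beta = unname(fit$coef[k]), se_beta = unname(fit$se[k]),
    n = length(mf$y),
    n_effective = sum(weights)^2 / sum(weights^2),
    sigma2 = fit$sigma2
  )
}

# Internal WLS via the scaled-QR route: solve with sqrt(w)-scaled design.
.wls <- function(X, y, w) {
  sw <- sqrt(w)
  Xw <- X * sw
  qr_ <- qr(Xw)
  p <- ncol(X)
  if (qr_$rank < p) {
    bad <- colnames(X)[qr_$pivot[(qr_$rank + 1):p]]
    return(list(singular = bad))
  }
  coefs <- qr.coef(qr_, y * sw)
  res <- y - drop(X %*% coefs)
  df <- nrow(X) - p
  sigma2 <- sum(w * res^2) / df
  # chol2inv(R) inverts X'WX in pivoted column order; map back
  dinv <- diag(chol2inv(qr.R(qr_)))[order(qr_$pivot)]
  se <- sqrt(pmax(dinv * sigma2, 0))
  names(se) <- names(coefs) <- colnames(X)
  list(coef = coefs, se = se, sigma2 = sigma2)
}

#' Map the local PGS-trait association over an analysis grid
#'
#' At every grid node, participants are weighted by [kernel_weights()] and
#' the covariate-adjusted model is fitted by [fit_weighted_model()]. Rows
#' with missing trait, PGS, covariate or coordinate values are dropped
#' once, globally, before mapping (complete-case), so every node sees the
#' same participants. Nodes where the fit fails are flagged
#' `converged = FALSE` and retained, never silently dropped.
#'
#' @param cohort Data frame with `x`, `y`, trait, PGS and covariate columns.
#' @param grid An `analysis_grid` from [build_hex_grid()].
#' @param kernel A [weight_kernel()].
#' @param spec A [model_spec()].
#' @param verbose Log progress every 200 nodes.
#' @return A `local_fit_map`: data.frame with one row per node — `node`,
#'   `x`, `y`, `beta`, `se`, `n_effective`, `converged` — plus attributes
#'   `spec`, `kernel`, and `n_used`.
#' @export
map_associations <- function(cohort, grid, kernel = weight_kernel(),
                             spec, verbose = FALSE) {
  stopifnot(inherits(grid, "analysis_grid"), inherits(spec, "model_spec"))
  need <- c("x", "y", spec$trait, spec$pgs, spec$covariates)
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    pgsmap_error(paste0("cohort is missing columns: ", paste(miss, collapse = ", ")),
                 "pgsmap_config_error")
  }
  cc <- complete.cases(cohort[, need, drop = FALSE])
  if (sum(cc) < length(need) + 2) {
    pgsmap_error("too few complete cases to fit the local model",
                 "pgsmap_dimension_error")
  }
  dat <- cohort[cc, , drop = FALSE]
  mf <- .model_frame(dat, spec)
  coords <- as.matrix(dat[, c("x", "y")])
  p <- ncol(mf$X)
  k <- match(spec$pgs, colnames(mf$X))

  nodes <- grid$nodes
  n_nodes <- nrow(nodes)
  beta <- se <- neff <- rep(NA_real_, n_nodes)
  conv <- rep(FALSE, n_nodes)
  for (i in seq_len(n_nodes)) {
    w <- kernel_weights(coords, c(nodes$x[i], nodes$y[i]), kernel)
    fit <- tryCatch(.wls(mf$X, mf$y, w), error = function(e) NULL)
    if (!is.null(fit) && is.null(fit$singular)) {
      beta[i] <- fit$coef[k]
      se[i] <- fit$se[k]
      neff[i] <- sum(w)^2 / sum(w^2)
      conv[i] <- TRUE
    }
    if (verbose && i %% 200 == 0) {
      message(sprintf("map_associations: %d/%d nodes", i, n_nodes))
    }
  }
  if (!any(conv)) {
    pgsmap_error("model fitting failed at every grid node", "pgsmap_empty_map")
  }
  out <- data.frame(node = nodes$node, x = nodes$x, y = nodes$y,
                    beta = beta, se = se, n_effective = neff, converged = conv)
  structure(out, class = c("local_fit_map", "data.frame"),
            spec = spec, kernel = kernel, n_used = nrow(dat))
}

#' @export
print.local_fit_map <- function(x, ...) {
  cat(sprintf(
    "<local_fit_map> %d nodes (%d converged), n = %d participants\n",
    nrow(x), sum(x$converged), attr(x, "n_used")
  ))
  cat(sprintf("  beta: median %.4g, range [%.4g, %.4g]\n",
              stats::median(x$beta, na.rm = TRUE),
              min(x$beta, na.rm = TRUE), max(x$beta, na.rm = TRUE)))
  cat("  note: per-node SEs are classical precision-weight WLS standard errors\n")
  invisible(x)
}

#' Write a fitted map as delimited text or GeoJSON points
#'
#' @param map A `local_fit_map`.
#' @param path Output path; extension `.geojson`/`.json` selects GeoJSON,
#'   anything else tab-delimited text.
#' @export
write_fit_map <- function(map, path) {
  df <- as.data.frame(map)
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    write_geojson_points(df, path)
  } else {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a fitted map written by [write_fit_map()]
#'
#' @param path File path.
#' @return Data frame with at least `node` and `beta` columns.
#' @export
read_fit_map <- function(path) {
  df <- if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    read_geojson_points(path)
  } else {
    read.delim(path)
  }
  if (!all(c("node", "beta") %in% names(df))) {
    pgsmap_error("file does not look like a fitted map (need node, beta columns)",
                 "pgsmap_io_error")
  }
  df[order(df$node), , drop = FALSE]
}
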