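#' Validate GWAS summary statistics
#'
#' A summary-statistics table needs one row per SNP with columns `snp`
#' (unique id), `effect_allele` (A/C/G/T), `beta` (finite discovery
#' effect size for the effect allele) and `p` (discovery p-value in
#' (0, 1]).
#'
#' @param gwas Data frame.
#' @return The validated data frame (invisibly usable downstream).
#' @export
validate_gwas <- function(gwas) {
  need <- c("snp", "effect_allele", "beta", "p")
  miss <- setdiff(need, names(gwas))
  if (length(miss)) {
    pgsmap_error(paste0("GWAS table is missing columns: ", paste(miss, collapse = ", ")),
                 "pgsmap_config_error")
  }
  if (anyDuplicated(gwas$snp)) {
    pgsmap_error("GWAS table has duplicated SNP ids", "pgsmap_config_error")
  }
  if (any(!is.finite(gwas$beta))) {
    pgsmap_error("GWAS effect sizes must be finite", "pgsmap_config_error")
  }
  if (any(gwas$p <= 0 | gwas$p > 1)) {
    pgsmap_error("GWAS p-values must lie in (0, 1]", "pgsmap_config_error")
  }
  if (!all(gwas$effect_allele %in% c("A", "C", "G", "T"))) {
    pgsmap_error("effect_allele must be one of A, C, G, T", "pgsmap_config_error")
  }
  gwas
}

#' A set of p-value thresholds for score construction
#'
#' The default set is genome-wide significance, a suggestive threshold,
#' and a permissive threshold: 5e-8, 1e-5 and 0.5. A denser set (e.g.
#' adding 0.1) can be supplied; thresholds must be strictly increasing in
#' (0, 1]. SNP inclusion uses the strict inequality `p < threshold`, so
#' the SNP set at a smaller threshold is nested in that of any larger
#' one.
#'
#' @param thresholds Numeric vector.
#' @return Validated numeric vector of class `threshold_set`.
#' @export
threshold_set <- function(thresholds = c(5e-8, 1e-5, 0.5)) {
  if (length(thresholds) == 0 || any(thresholds <= 0 | thresholds > 1)) {
    pgsmap_error("thresholds must be a nonempty vector with values in (0, 1]",
                 "pgsmap_config_error")
  }
  if (any(diff(thresholds) <= 0)) {
    pgsmap_error("thresholds must be strictly increasing", "pgsmap_config_error")
  }
  structure(as.numeric(thresholds), class = "threshold_set")
}

#' Column label for a threshold's PGS
#'
#' Cohort tables store one standardized score column per threshold, named
#' `pgs_<threshold>` with the threshold formatted compactly (e.g.
#' `pgs_5e-08`, `pgs_0.5`).
#'
#' @param threshold Numeric threshold.
#' @return Character column name.
#' @export
pgs_column <- function(threshold) {
  paste0("pgs_", format(threshold, scientific = threshold < 1e-4, trim = TRUE))
}

#' Raw weighted allele-count polygenic scores
#'
#' For each participant, sums the dosage of the effect allele (0, 1 or 2)
#' over the SNPs whose discovery p-value is strictly below `threshold`,
#' each weighted by its discovery effect size:
#' `score_i = sum_{j : p_j < t} beta_j * dosage_ij`.
#'
#' SNPs present in only one of the dosage matrix and the GWAS table are
#' dropped, with a message giving the count. Dosages are assumed already
#' aligned to the GWAS effect allele (see [reconcile_alleles()] for
#' real-data harmonisation).
#'
#' @param dosages Numeric matrix, participants x SNPs, values in
#'   \[0, 2\], with SNP ids as column names.
#' @param gwas GWAS summary table (see [validate_gwas()]).
#' @param threshold Single p-value threshold in (0, 1].
#' @return Numeric vector of raw scores, one per participant, with the
#'   number of SNPs used as attribute `n_snps`.
#' @export
score_participants <- function(dosages, gwas, threshold) {
  gwas <- validate_gwas(gwas)
  if (length(threshold) != 1 || threshold <= 0 || threshold > 1) {
    pgsmap_error("threshold must be a single value in (0, 1]", "pgsmap_config_error")
  }
  if (is.null(colnames(dosages))) {
    pgsmap_error("dosage matrix must have SNP ids as column names",
                 "pgsmap_config_error")
  }
  shared <- intersect(colnames(dosages), gwas$snp)
  dropped <- (ncol(dosages) - length(shared)) + (nrow(gwas) - length(shared))
  if (dropped > 0) {
    message(sprintf("score_participants: %d SNP(s) not shared between dosages and GWAS were dropped",
                    dropped))
  }
  if (length(shared) == 0) {
    pgsmap_error("no SNPs shared between dosage matrix and GWAS table",
                 "pgsmap_config_error")
  }
  g <- gwas[match(shared, gwas$snp), ]
  keep <- g$p < threshold
  if (!any(keep)) {
    pgsmap_error(sprintf("no SNPs pass the p < %g threshold", threshold),
                 "pgsmap_empty_score")
  }
  sel <- shared[keep]
  score <- drop(dosages[, sel, drop = FALSE] %*% g$beta[keep])
  attr(score, "n_snps") <- length(sel)
  score
}

#' Standardize scores to z-scores
#'
#' Centres and scales by the sample standard deviation (n-1 denominator),
#' so results read as trait change per SD of PGS. Invariant under
#' positive affine transforms of the input.
#'
#' @param raw_scores Numeric vector with at least two distinct values.
#' @return z-score vector (mean 0, SD 1).
#' @export
standardize <- function(raw_scores) {
  if (length(raw_scores) < 2 || stats::sd(raw_scores) == 0) {
    pgsmap_error("cannot standardize a constant score vector",
                 "pgsmap_zero_variance")
  }
  as.numeric((raw_scores - mean(raw_scores)) / stats::sd(raw_scores))
}

#' Build the participant x threshold PGS matrix
#'
#' Scores and standardizes at every threshold; thresholds at which no SNP
#' passes are skipped with a warning rather than failing the whole
#' matrix.
#'
#' @inheritParams score_participants
#' @param thresholds A [threshold_set()].
#' @return Data frame with one `pgs_<threshold>` z-score column per
#'   usable threshold; attribute `n_snps` records SNPs used per column.
#' @export
build_pgs_matrix <- function(dosages, gwas, thresholds = threshold_set()) {
  cols <- list()
  nsnps <- integer(0)
  for (t in thresholds) {
    sc <- tryCatch(score_participants(dosages, gwas, t),
                   pgsmap_empty_score = function(e) NULL)
    if (is.null(sc)) {
      warning(sprintf("no SNPs pass p < %g; threshold skipped", t))
      next
    }
    z <- tryCatch(standardize(sc), pgsmap_zero_variance = function(e) NULL)
    if (is.null(z)) {
      warning(sprintf("scores constant at p < %g; threshold skipped", t))
      next
    }
    cols[[pgs_column(t)]] <- z
    nsnps[pgs_column(t)] <- attr(sc, "n_snps")
  }
  if (!length(cols)) {
    pgsmap_error("no threshold produced a usable score", "pgsmap_empty_score")
  }
  out <- as.data.frame(cols, check.names = FALSE, optional = TRUE)
  attr(out, "n_snps") <- nsnps
  out
}

#' Select the best-fitting p-value threshold
#'
#' Fits the unweighted covariate-adjusted linear model
#' `trait ~ pgs_t + covariates` for every threshold on the full sample
#' and returns the threshold whose model has the largest adjusted R^2,
#' together with the per-threshold fit table. Both the full-model
#' adjusted R^2 and the increment over the covariates-only model are
#' reported; the full-model value decides. Ties (within 1e-12) break
#' toward the smaller, more stringent threshold, with a warning.
#'
#' @param cohort Data frame with the trait, covariates and one
#'   `pgs_<threshold>` column per candidate threshold.
#' @param thresholds A [threshold_set()] (thresholds without a PGS column
#'   are skipped).
#' @param spec A [model_spec()]; its `pgs` field is ignored here (each
#'   threshold's own column is used).
#' @return List with `best` (numeric threshold), `best_column`, and
#'   `table`: data.frame of threshold, n, r2, adj_r2, delta_adj_r2.
#' @export
select_best_threshold <- function(cohort, thresholds, spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (stats::sd(cohort[[spec$trait]], na.rm = TRUE) == 0) {
    pgsmap_error("trait is constant; threshold selection undefined",
                 "pgsmap_zero_variance")
  }
  have <- thresholds[vapply(thresholds, function(t) pgs_column(t) %in% names(cohort),
                            logical(1))]
  if (!length(have)) {
    pgsmap_error("no PGS columns found for any candidate threshold",
                 "pgsmap_config_error")
  }
  rows <- lapply(have, function(t) {
    col <- pgs_column(t)
    use <- complete.cases(cohort[, c(spec$trait, col, spec$covariates), drop = FALSE])
    dat <- cohort[use, , drop = FALSE]
    fml <- stats::reformulate(c(sprintf("`%s`", col), spec$covariates),
                              response = sprintf("`%s`", spec$trait))
    fit <- stats::lm(fml, data = dat)
    sm <- summary(fit)
    # covariates-only reference for the incremental R^2
    adj0 <- if (length(spec$covariates)) {
      f0 <- stats::reformulate(spec$covariates, response = sprintf("`%s`", spec$trait))
      summary(stats::lm(f0, data = dat))$adj.r.squared
    } else 0
    data.frame(threshold = t, n = nrow(dat),
               r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
               delta_adj_r2 = sm$adj.r.squared - adj0)
  })
  tab <- do.call(rbind, rows)
  best_val <- max(tab$adj_r2)
  cand <- which(tab$adj_r2 >= best_val - 1e-12)
  if (length(cand) > 1) {
    warning(sprintf("adjusted R^2 tied across thresholds {%s}; selecting the smallest",
                    paste(format(tab$threshold[cand]), collapse = ", ")))
  }
  best <- tab$threshold[min(cand)]
  if (all(tab$delta_adj_r2 < 1e-4)) {
    message("select_best_threshold: no threshold improves on the covariates-only model (all delta adj R^2 ~ 0)")
  }
  list(best = best, best_column = pgs_column(best), table = tab)
}

#' Harmonise dosage alleles with the GWAS effect allele
#'
#' Real-data helper (the simulator emits pre-aligned dosages and bypasses
#' this). Given the genotype panel's allele pair per SNP, effect sizes
#' are kept when the panel's counted allele matches the GWAS effect
#' allele, flipped in sign (and the counted allele swapped) when the
#' alleles are reversed, and the SNP is dropped when strand-ambiguous
#' (A/T or C/G pairs) or when the allele pairs cannot be reconciled.
#'
#' @param gwas GWAS summary table.
#' @param panel Data frame with `snp`, `counted` (allele the dosage
#'   counts) and `other`.
#' @param drop_ambiguous Drop A/T and C/G SNPs (default `TRUE`).
#' @return The GWAS table restricted to reconcilable SNPs with `beta`
#'   flipped where needed; attribute `n_flipped` / `n_dropped` record the
#'   actions taken.
#' @export
reconcile_alleles <- function(gwas, panel, drop_ambiguous = TRUE) {
  gwas <- validate_gwas(gwas)
  m <- match(gwas$snp, panel$snp)
  keep <- !is.na(m)
  g <- gwas[keep, ]
  pn <- panel[m[keep], ]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ambiguous <- pn$counted == comp[pn$other]
  same <- g$effect_allele == pn$counted
  flipped <- g$effect_allele == pn$other
  ok <- (same | flipped) & !(drop_ambiguous & ambiguous)
  g$beta[flipped] <- -g$beta[flipped]
  g$effect_allele[flipped] <- pn$counted[flipped]
  out <- g[ok, ]
  attr(out, "n_flipped") <- sum(flipped & ok)
  attr(out, "n_dropped") <- nrow(gwas) - nrow(out)
  out
}
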