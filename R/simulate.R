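#' Configuration for the synthetic cohort generator
#'
#' Describes the study conditions the generator emulates: a
#' geo-clustered birth cohort of several thousand children around a city
#' region, genotyped at independent SNPs, with a trait whose PGS
#' association varies smoothly over space, plus environmental surfaces
#' spatially correlated with that coefficient surface and an optional
#' PGS-linked participation (attrition) mechanism.
#'
#' Defaults describe a 30 km x 30 km region with six settlement
#' clusters, 5,000 participants, 200 independent SNPs of which 10% carry
#' true effects, a west-to-east linear gradient in the PGS coefficient,
#' and five environmental surfaces (two log-normal, two continuous, one
#' 3-level categorical) at moderate correlations with the coefficient
#' surface. See the package vignette for the rationale behind each
#' default.
#'
#' @param n_participants Cohort size before attrition (>= 50).
#' @param region A `study_region` (see [region_rectangle()]).
#' @param n_clusters Number of settlement centres.
#' @param cluster_sd Gaussian spread of each settlement (metres, > 0).
#' @param cluster_weights Mixture weights (default equal).
#' @param n_snps Number of independent SNPs.
#' @param effect_fraction Fraction of SNPs with true effects, in \[0, 1\].
#' @param effect_size_sd SD of true per-allele effect sizes.
#' @param snp_effects Optional explicit vector of true effects (length
#'   `n_snps`), overriding random assignment.
#' @param gwas_n Discovery-GWAS sample size governing p-value noise.
#' @param beta_surface The true local PGS coefficient surface: one of
#'   `list(type = "constant", value)`,
#'   `list(type = "linear", b0, bx, by)` (per-metre gradients), or
#'   `list(type = "radial", centre, scale, range)`.
#' @param trait_intercept,trait_noise_sd Trait model intercept and
#'   residual SD (> 0).
#' @param covariate_effects Named vector with `sex` and `age` effects.
#' @param discretize_trait `NULL`, or `c(min, max)` to round and clamp
#'   the trait to a bounded integer questionnaire scale (off by default;
#'   the fitted model is linear either way).
#' @param env_surfaces Named list of surfaces, each
#'   `list(transform, rho)` with transform in
#'   `{"identity", "lognormal", "categorical3"}` and `|rho| <= 1` the
#'   target correlation with the coefficient surface.
#' @param attrition_gamma Log-odds of retention per SD of PGS (0 = no
#'   PGS-linked attrition).
#' @param retention_target Expected retention rate in (0, 1].
#' @param thresholds A [threshold_set()] for score construction.
#' @param seed Integer seed; every generator stage derives its own
#'   stream from it, so each operation is individually reproducible.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_participants = 5000,
                              region = region_rectangle(0, 0, 30000, 30000),
                              n_clusters = 6,
                              cluster_sd = 2500,
                              cluster_weights = NULL,
                              n_snps = 200,
                              effect_fraction = 0.1,
                              effect_size_sd = 0.06,
                              snp_effects = NULL,
                              gwas_n = 20000,
                              beta_surface = list(type = "linear",
                                                  b0 = 0.1, bx = 2e-5, by = 0),
                              trait_intercept = 3,
                              trait_noise_sd = 2,
                              covariate_effects = c(sex = 0.5, age = 0.2),
                              discretize_trait = NULL,
                              env_surfaces = list(
                                population_density  = list(transform = "lognormal",
                                                           rho = -0.3),
                                qualification_level = list(transform = "identity",
                                                           rho = 0.3),
                                imd                 = list(transform = "lognormal",
                                                           rho = -0.3),
                                urbanicity          = list(transform = "categorical3",
                                                           rho = -0.2),
                                sunshine_hours      = list(transform = "identity",
                                                           rho = 0.5)
                              ),
                              attrition_gamma = 0,
                              retention_target = 1,
                              thresholds = threshold_set(),
                              seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants), region = region,
    n_clusters = as.integer(n_clusters), cluster_sd = cluster_sd,
    cluster_weights = cluster_weights, n_snps = as.integer(n_snps),
    effect_fraction = effect_fraction, effect_size_sd = effect_size_sd,
    snp_effects = snp_effects, gwas_n = gwas_n, beta_surface = beta_surface,
    trait_intercept = trait_intercept, trait_noise_sd = trait_noise_sd,
    covariate_effects = covariate_effects, discretize_trait = discretize_trait,
    env_surfaces = env_surfaces, attrition_gamma = attrition_gamma,
    retention_target = retention_target, thresholds = thresholds,
    seed = as.integer(seed)
  )
  .validate_sim_config(cfg)
  structure(cfg, class = "simulation_config")
}

.validate_sim_config <- function(cfg) {
  if (!inherits(cfg$region, "study_region")) {
    pgsmap_error("region must be a study_region object", "pgsmap_invalid_region")
  }
  if (cfg$n_participants < 50) {
    pgsmap_error("n_participants must be >= 50", "pgsmap_config_error")
  }
  if (!is.finite(cfg$cluster_sd) || cfg$cluster_sd < 0) {
    pgsmap_error("cluster_sd must be non-negative", "pgsmap_config_error")
  }
  if (cfg$effect_fraction < 0 || cfg$effect_fraction > 1) {
    pgsmap_error("effect_fraction must lie in [0, 1]", "pgsmap_config_error")
  }
  if (!is.finite(cfg$trait_noise_sd) || cfg$trait_noise_sd < 0) {
    pgsmap_error("trait_noise_sd must be non-negative", "pgsmap_config_error")
  }
  if (cfg$retention_target <= 0 || cfg$retention_target > 1) {
    pgsmap_error("retention_target must lie in (0, 1]", "pgsmap_config_error")
  }
  if (!is.finite(cfg$attrition_gamma)) {
    pgsmap_error("attrition_gamma must be finite", "pgsmap_config_error")
  }
  for (nm in names(cfg$env_surfaces)) {
    s <- cfg$env_surfaces[[nm]]
    if (!s$transform %in% c("identity", "lognormal", "categorical3")) {
      pgsmap_error(sprintf("unknown env transform '%s' for surface '%s'",
                           s$transform, nm), "pgsmap_config_error")
    }
    if (abs(s$rho) > 1) {
      pgsmap_error(sprintf("|rho| must be <= 1 (surface '%s')", nm),
                   "pgsmap_config_error")
    }
  }
  if (!is.null(cfg$cluster_weights)) {
    if (length(cfg$cluster_weights) != cfg$n_clusters ||
        any(cfg$cluster_weights < 0) || sum(cfg$cluster_weights) <= 0) {
      pgsmap_error("cluster_weights must be n_clusters non-negative values",
                   "pgsmap_config_error")
    }
  }
  invisible(cfg)
}

#' Evaluate the true local PGS coefficient surface
#'
#' @param spec A `beta_surface` specification (see [simulation_config()]).
#' @param x,y Coordinates (metres).
#' @return Numeric vector of true coefficients beta(s).
#' @export
beta_surface_at <- function(spec, x, y) {
  switch(spec$type,
    constant = rep(spec$value, length(x)),
    linear = spec$b0 + spec$bx * x + spec$by * y,
    radial = {
      d2 <- (x - spec$centre[1])^2 + (y - spec$centre[2])^2
      spec$scale * exp(-0.5 * d2 / spec$range^2)
    },
    pgsmap_error(sprintf("unknown beta surface type '%s'", spec$type),
                 "pgsmap_config_error")
  )
}

#' Ground truth of a synthetic cohort
#'
#' Deterministic handle on the planted structure: `beta_at(x, y)`
#' evaluates the true coefficient surface; `retained_ids` is filled in by
#' [simulate_cohort()] after attrition.
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_truth` object.
#' @export
synthetic_truth <- function(config) {
  structure(
    list(
      beta_surface = config$beta_surface,
      beta_at = function(x, y) beta_surface_at(config$beta_surface, x, y),
      retained_ids = NULL
    ),
    class = "synthetic_truth"
  )
}

#' Simulate geo-clustered participant locations
#'
#' Participants are placed by a mixture of `n_clusters` isotropic
#' Gaussian settlements, truncated to the study region by rejection
#' sampling; cluster centres are drawn uniformly inside the region. This
#' emulates residences recorded at postcode-zone centroids around a city
#' and its satellite towns.
#'
#' @param config A [simulation_config()].
#' @return Data frame `id`, `x`, `y`, `cluster`, with cluster centres as
#'   attribute `centres`.
#' @export
simulate_locations <- function(config) {
  .validate_sim_config(config)
  set.seed(.op_seed(config$seed, "locations"))
  n <- config$n_participants
  k <- config$n_clusters
  centres <- .runif_in_region(config$region, k)
  wts <- config$cluster_weights %||% rep(1, k)
  assign <- sample.int(k, n, replace = TRUE, prob = wts / sum(wts))
  x <- centres[assign, 1] + rnorm(n, 0, config$cluster_sd)
  y <- centres[assign, 2] + rnorm(n, 0, config$cluster_sd)
  for (it in seq_len(1000)) {
    out <- !region_contains(config$region, cbind(x, y))
    if (!any(out)) break
    m <- sum(out)
    x[out] <- centres[assign[out], 1] + rnorm(m, 0, config$cluster_sd)
    y[out] <- centres[assign[out], 2] + rnorm(m, 0, config$cluster_sd)
  }
  structure(
    data.frame(id = seq_len(n), x = x, y = y, cluster = assign),
    centres = centres
  )
}

# Internal: uniform points inside a polygon region (rejection from bbox).
.runif_in_region <- function(region, k) {
  bb <- region$bbox
  pts <- matrix(NA_real_, 0, 2)
  while (nrow(pts) < k) {
    cand <- cbind(runif(4 * k, bb["xmin"], bb["xmax"]),
                  runif(4 * k, bb["ymin"], bb["ymax"]))
    pts <- rbind(pts, cand[region_contains(region, cand), , drop = FALSE])
  }
  unname(pts[seq_len(k), , drop = FALSE])
}

#' Simulate genotype dosages and discovery-GWAS summary statistics
#'
#' SNPs are independent (no LD), with allele frequencies uniform on
#' (0.05, 0.5) and dosages Binomial(2, MAF). A fraction
#' `effect_fraction` of SNPs carries true effects (Normal(0,
#' `effect_size_sd`) per allele, or `snp_effects` if given). The summary
#' table reports the generative effect size for each SNP; the sampling
#' noise of a finite discovery GWAS of size `gwas_n` enters through the
#' p-value, computed from `z = beta/se(MAF, gwas_n) + Normal(0, 1)` —
#' null SNPs thus get effect 0 and uniform p-values, and p decreases in
#' the magnitude of a true effect.
#'
#' @param config A [simulation_config()].
#' @return List with `dosages` (n x n_snps matrix, SNP-id colnames),
#'   `gwas` (data.frame `snp`, `effect_allele`, `beta`, `p`), `maf`, and
#'   `causal` (indices of SNPs with nonzero true effects).
#' @export
simulate_genotypes_and_gwas <- function(config) {
  .validate_sim_config(config)
  if (config$n_snps < 1) pgsmap_error("n_snps must be >= 1", "pgsmap_config_error")
  set.seed(.op_seed(config$seed, "genotypes"))
  m <- config$n_snps
  n <- config$n_participants
  snp_ids <- sprintf("snp_%04d", seq_len(m))
  maf <- runif(m, 0.05, 0.5)
  dosages <- vapply(seq_len(m), function(j) rbinom(n, 2, maf[j]), numeric(n))
  colnames(dosages) <- snp_ids

  if (!is.null(config$snp_effects)) {
    if (length(config$snp_effects) != m) {
      pgsmap_error("snp_effects must have length n_snps", "pgsmap_dimension_error")
    }
    beta <- as.numeric(config$snp_effects)
  } else {
    beta <- numeric(m)
    n_causal <- round(config$effect_fraction * m)
    if (n_causal > 0) {
      causal_idx <- sample.int(m, n_causal)
      beta[causal_idx] <- rnorm(n_causal, 0, config$effect_size_sd)
    }
  }
  se <- 1 / sqrt(2 * maf * (1 - maf) * config$gwas_n)
  z <- beta / se + rnorm(m)
  p <- pmax(2 * pnorm(-abs(z)), .Machine$double.xmin)
  gwas <- data.frame(
    snp = snp_ids,
    effect_allele = sample(c("A", "C", "G", "T"), m, replace = TRUE),
    beta = beta, p = p
  )
  list(dosages = dosages, gwas = gwas, maf = maf, causal = which(beta != 0))
}

#' Simulate trait values under the planted local-coefficient model
#'
#' `y_i = alpha + beta(s_i) * PGS_i + gamma_sex * sex_i +
#' gamma_age * age_i + eps_i` with `eps ~ Normal(0, trait_noise_sd^2)`
#' and `beta(s)` evaluated from the configured coefficient surface at
#' each participant's location. This is the generative counterpart of
#' the model the mapping stage fits at each grid node.
#'
#' @param locations Data frame with `x`, `y` (from
#'   [simulate_locations()]).
#' @param pgs Standardized PGS vector driving the genetic effect.
#' @param covariates Data frame with `sex` (0/1) and `age` columns.
#' @param truth A [synthetic_truth()] (supplies `beta_at`).
#' @param config A [simulation_config()].
#' @return Numeric trait vector (rounded and clamped when
#'   `discretize_trait` is set).
#' @export
simulate_traits <- function(locations, pgs, covariates, truth, config) {
  n <- nrow(locations)
  if (length(pgs) != n || nrow(covariates) != n) {
    pgsmap_error("locations, pgs and covariates must describe the same participants",
                 "pgsmap_dimension_error")
  }
  set.seed(.op_seed(config$seed, "traits"))
  beta <- truth$beta_at(locations$x, locations$y)
  g <- config$covariate_effects
  y <- config$trait_intercept + beta * pgs +
    g[["sex"]] * covariates$sex + g[["age"]] * covariates$age +
    rnorm(n, 0, config$trait_noise_sd)
  if (!is.null(config$discretize_trait)) {
    r <- config$discretize_trait
    y <- pmin(pmax(round(y), r[1]), r[2])
  }
  y
}

#' Simulate environmental surfaces at grid nodes
#'
#' Each surface is a stated transform of a Gaussian mixture
#' `z = rho * z_beta + sqrt(1 - rho^2) * g`, where `z_beta` is the
#' standardized true coefficient surface at the grid nodes and `g` is
#' independent node-level Gaussian noise; `rho` is the target
#' correlation with the coefficient surface. Transforms: `identity`
#' (smooth continuous measure), `lognormal` (`exp(z)`, positively
#' skewed, as for population density or deprivation indices), and
#' `categorical3` (tertile cut into an ordinal 1/2/3 settlement-type
#' classification; trichotomisation attenuates the realized correlation
#' by roughly a factor 0.89).
#'
#' @param grid An `analysis_grid`.
#' @param truth A [synthetic_truth()].
#' @param config A [simulation_config()] (supplies `env_surfaces`).
#' @return Data frame `node`, `x`, `y`, plus one column per surface;
#'   transforms recorded in attribute `transforms`.
#' @export
simulate_env_surfaces <- function(grid, truth, config) {
  stopifnot(inherits(grid, "analysis_grid"))
  if (nrow(grid$nodes) == 0) pgsmap_error("grid is empty", "pgsmap_empty_grid")
  .validate_sim_config(config)
  set.seed(.op_seed(config$seed, "env"))
  nodes <- grid$nodes
  b <- truth$beta_at(nodes$x, nodes$y)
  zb <- if (stats::sd(b) > 0) (b - mean(b)) / stats::sd(b) else rep(0, nrow(nodes))
  out <- nodes[, c("node", "x", "y")]
  transforms <- character(0)
  for (nm in names(config$env_surfaces)) {
    s <- config$env_surfaces[[nm]]
    gnoise <- rnorm(nrow(nodes))
    z <- s$rho * zb + sqrt(1 - s$rho^2) * gnoise
    out[[nm]] <- switch(s$transform,
      identity = z,
      lognormal = exp(z),
      categorical3 = as.integer(cut(z, breaks = quantile(z, c(0, 1/3, 2/3, 1)),
                                    labels = FALSE, include.lowest = TRUE))
    )
    transforms[nm] <- s$transform
  }
  attr(out, "transforms") <- transforms
  out
}

#' PGS-linked participation attrition
#'
#' Each participant is retained with probability
#' `plogis(lambda0 + attrition_gamma * PGS)`, where `lambda0` is solved
#' so the expected retention equals `retention_target`. With
#' `attrition_gamma < 0`, higher-PGS participants drop out more — the
#' loss-to-follow-up pattern reported for hyperactivity-related scores
#' in birth cohorts.
#'
#' @param pgs Standardized PGS vector.
#' @param config A [simulation_config()].
#' @return Integer vector of retained participant indices.
#' @export
apply_attrition <- function(pgs, config) {
  .validate_sim_config(config)
  set.seed(.op_seed(config$seed, "attrition"))
  n <- length(pgs)
  if (config$retention_target == 1) return(seq_len(n))
  gam <- config$attrition_gamma
  f <- function(l0) mean(plogis(l0 + gam * pgs)) - config$retention_target
  l0 <- uniroot(f, c(-50, 50))$root
  which(runif(n) < plogis(l0 + gam * pgs))
}

#' Simulate a complete synthetic cohort
#'
#' Orchestrates the full generator: clustered locations, sex and age
#' covariates (sex Bernoulli(0.5); age Normal(10.7, 0.12), the age-10
#' assessment window), genotypes and discovery summary statistics,
#' polygenic scores at the configured thresholds (built with the same
#' scoring code the analysis uses), traits driven by the standardized
#' true genetic value (`pgs_true`, the score over causal SNPs), and
#' optional PGS-linked attrition. After attrition the `pgs_*` columns
#' are re-standardized over the retained (analysed) sample; `pgs_true`
#' keeps its generative scale.
#'
#' @param config A [simulation_config()].
#' @return A `pgs_sim` object: list with `cohort` (retained
#'   participants: `id`, `x`, `y`, `cluster`, `sex`, `age`, `trait`,
#'   `pgs_true`, `pgs_<threshold>` columns), `cohort_full`, `genotypes`,
#'   `gwas`, `truth`, `retained_ids`, and `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  .validate_sim_config(config)
  loc <- simulate_locations(config)
  set.seed(.op_seed(config$seed, "covariates"))
  n <- config$n_participants
  covars <- data.frame(sex = rbinom(n, 1, 0.5), age = rnorm(n, 10.7, 0.12))
  gen <- simulate_genotypes_and_gwas(config)

  gv <- drop(gen$dosages[, gen$causal, drop = FALSE] %*%
               gen$gwas$beta[gen$causal])
  pgs_true <- if (length(gen$causal) && stats::sd(gv) > 0) {
    standardize(gv)
  } else {
    rep(0, n)
  }

  truth <- synthetic_truth(config)
  trait <- simulate_traits(loc, pgs_true, covars, truth, config)
  pgs_mat <- suppressWarnings(
    build_pgs_matrix(gen$dosages, gen$gwas, config$thresholds)
  )

  cohort <- cbind(
    loc[, c("id", "x", "y", "cluster")],
    covars,
    data.frame(trait = trait, pgs_true = pgs_true),
    pgs_mat
  )

  retained <- apply_attrition(pgs_true, config)
  truth$retained_ids <- cohort$id[retained]
  analysed <- cohort[retained, , drop = FALSE]
  for (cl in names(pgs_mat)) analysed[[cl]] <- standardize(analysed[[cl]])

  structure(
    list(cohort = analysed, cohort_full = cohort, genotypes = gen$dosages,
         gwas = gen$gwas, truth = truth, retained_ids = truth$retained_ids,
         config = config),
    class = "pgs_sim"
  )
}

#' @export
print.pgs_sim <- function(x, ...) {
  cat(sprintf(
    "<pgs_sim> %d participants (%d retained), %d SNPs (%d causal), seed %d\n",
    x$config$n_participants, nrow(x$cohort), x$config$n_snps,
    length(unique(x$gwas$snp[x$gwas$beta != 0])), x$config$seed
  ))
  cat(sprintf("  beta surface: %s; PGS columns: %s\n",
              x$config$beta_surface$type,
              paste(grep("^pgs_", names(x$cohort), value = TRUE), collapse = ", ")))
  invisible(x)
}
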