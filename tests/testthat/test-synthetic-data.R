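test_that("every generator stage is deterministic under a fixed seed", {
  cfg <- simulation_config(n_participants = 200, n_snps = 30, seed = 17,
                           attrition_gamma = -0.3, retention_target = 0.8)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$gwas, s2$gwas)
  expect_identical(s1$retained_ids, s2$retained_ids)

  loc1 <- simulate_locations(cfg)
  loc2 <- simulate_locations(cfg)
  expect_identical(loc1, loc2)
})

test_that("degenerate mixture collapses to the cluster centres", {
  cfg <- simulation_config(n_participants = 100, n_clusters = 1,
                           cluster_sd = 1e-9, seed = 2)
  loc <- simulate_locations(cfg)
  centres <- attr(loc, "centres")
  expect_lt(max(abs(loc$x - centres[1, 1])), 1e-6)
  expect_lt(max(abs(loc$y - centres[1, 2])), 1e-6)
})

test_that("cluster assignment proportions match the mixture weights", {
  w <- c(0.5, 0.3, 0.2)
  cfg <- simulation_config(n_participants = 2000, n_clusters = 3,
                           cluster_sd = 500, cluster_weights = w, seed = 8)
  loc <- simulate_locations(cfg)
  counts <- tabulate(loc$cluster, 3)
  # binomial 99% bounds per component (multinomial marginal oracle)
  for (k in 1:3) {
    bound <- 2.576 * sqrt(w[k] * (1 - w[k]) / 2000)
    expect_lt(abs(counts[k] / 2000 - w[k]), bound + 1e-9)
  }
})

test_that("config validation rejects degenerate inputs", {
  expect_error(region_polygon(cbind(c(0, 0, 0), c(0, 1, 2))),
               class = "pgsmap_invalid_region")
  expect_error(simulation_config(n_participants = 10), class = "pgsmap_config_error")
  expect_error(simulation_config(effect_fraction = 1.2), class = "pgsmap_config_error")
  expect_error(simulation_config(retention_target = 0), class = "pgsmap_config_error")
  expect_error(
    simulation_config(env_surfaces = list(a = list(transform = "sqrt", rho = 0))),
    class = "pgsmap_config_error"
  )
  expect_error(
    simulation_config(env_surfaces = list(a = list(transform = "identity", rho = 1.5))),
    class = "pgsmap_config_error"
  )
})

test_that("null GWAS has zero effects and uniform p-values", {
  cfg <- simulation_config(n_participants = 100, n_snps = 400,
                           effect_fraction = 0, seed = 12)
  gen <- simulate_genotypes_and_gwas(cfg)
  expect_true(all(gen$gwas$beta == 0))
  expect_length(gen$causal, 0)
  expect_gt(ks.test(gen$gwas$p, "punif")$p.value, 0.01)
})

test_that("dosage means match the binomial oracle at each SNP", {
  cfg <- simulation_config(n_participants = 10000, n_snps = 25, seed = 14)
  gen <- simulate_genotypes_and_gwas(cfg)
  mu <- colMeans(gen$dosages)
  for (j in seq_along(gen$maf)) {
    se <- sqrt(2 * gen$maf[j] * (1 - gen$maf[j]) / 10000)
    expect_lt(abs(mu[j] - 2 * gen$maf[j]), 2.576 * se + 1e-9)
  }
})

test_that("a strong true effect earns the smallest p-value among null SNPs", {
  wins <- 0L
  reps <- 200
  for (r in seq_len(reps)) {
    cfg <- simulation_config(n_participants = 50, n_snps = 101,
                             snp_effects = c(0.3, rep(0, 100)),
                             gwas_n = 20000, seed = 3000 + r)
    gen <- simulate_genotypes_and_gwas(cfg)
    wins <- wins + (which.min(gen$gwas$p) == 1L)
  }
  expect_gte(wins / reps, 0.95)
})

test_that("trait generation follows the planted local-coefficient model", {
  # noiseless constant-beta limit: y is exactly c * PGS
  cfg <- simulation_config(
    n_participants = 120, n_snps = 20, trait_noise_sd = 1e-12,
    trait_intercept = 0, covariate_effects = c(sex = 0, age = 0),
    beta_surface = list(type = "constant", value = 0.7), seed = 5
  )
  loc <- simulate_locations(cfg)
  pgs <- standardize(rnorm(120))
  covars <- data.frame(sex = rbinom(120, 1, 0.5), age = rnorm(120, 10.7, 0.12))
  y <- simulate_traits(loc, pgs, covars, synthetic_truth(cfg), cfg)
  expect_equal(y, 0.7 * pgs, tolerance = 1e-8)

  # linear gradient formula: 1 per km along x gives beta = 2 at x = 2 km
  spec <- list(type = "linear", b0 = 0, bx = 1e-3, by = 0)
  expect_equal(beta_surface_at(spec, 2000, 123456), 2)
  expect_error(
    simulate_traits(loc, pgs[-1], covars, synthetic_truth(cfg), cfg),
    class = "pgsmap_dimension_error"
  )
})

test_that("global OLS recovers a constant planted beta (oracle consistency)", {
  ok <- 0L
  reps <- 100
  for (r in seq_len(reps)) {
    cfg <- simulation_config(
      n_participants = 2000, n_snps = 50, trait_noise_sd = 1,
      beta_surface = list(type = "constant", value = 0.1), seed = 5000 + r
    )
    sim <- simulate_cohort(cfg)
    fit <- summary(lm(trait ~ pgs_true + sex + age, data = sim$cohort))
    est <- fit$coefficients["pgs_true", ]
    ok <- ok + (abs(est["Estimate"] - 0.1) < 3 * est["Std. Error"])
  }
  expect_gte(ok / reps, 0.95)
})

test_that("environmental surfaces honour their transforms and correlations", {
  cfg <- simulation_config(seed = 6)
  grid <- build_hex_grid(cfg$region, target_n = 1000)
  truth <- synthetic_truth(cfg)

  # rho = 1 identity surface is an affine image of the beta surface
  cfg1 <- simulation_config(
    env_surfaces = list(e = list(transform = "identity", rho = 1)), seed = 6
  )
  env1 <- simulate_env_surfaces(grid, truth, cfg1)
  b <- truth$beta_at(grid$nodes$x, grid$nodes$y)
  expect_equal(cor(env1$e, b), 1, tolerance = 1e-12)

  # rho = 0 surface is uncorrelated with beta on a 1000-node grid
  cfg0 <- simulation_config(
    env_surfaces = list(e = list(transform = "identity", rho = 0)), seed = 6
  )
  env0 <- simulate_env_surfaces(grid, truth, cfg0)
  expect_lt(abs(cor(env0$e, b, method = "spearman")), 0.15)

  # lognormal surfaces are positive and right-skewed
  cfgl <- simulation_config(
    env_surfaces = list(e = list(transform = "lognormal", rho = 0.3)), seed = 6
  )
  envl <- simulate_env_surfaces(grid, truth, cfgl)
  expect_true(all(envl$e > 0))
  v <- envl$e
  skew <- mean((v - mean(v))^3) / sd(v)^3
  expect_gt(skew, 0)

  # categorical surface takes exactly the three levels
  cfgc <- simulation_config(
    env_surfaces = list(e = list(transform = "categorical3", rho = -0.2)), seed = 6
  )
  envc <- simulate_env_surfaces(grid, truth, cfgc)
  expect_setequal(unique(envc$e), 1:3)
})

test_that("realized env correlation tracks rho within 0.15 on a 300-node grid", {
  cfg <- simulation_config(seed = 10)
  grid <- build_hex_grid(cfg$region, target_n = 300)
  truth <- synthetic_truth(cfg)
  b <- truth$beta_at(grid$nodes$x, grid$nodes$y)
  for (rho in c(-0.8, -0.3, 0.3, 0.8)) {
    cfgr <- simulation_config(
      env_surfaces = list(e = list(transform = "identity", rho = rho)), seed = 10
    )
    env <- simulate_env_surfaces(grid, truth, cfgr)
    expect_lt(abs(cor(env$e, b, method = "spearman") - rho), 0.15)
  }
})

test_that("attrition retains everyone at target 1 and selects on PGS otherwise", {
  cfg <- simulation_config(n_participants = 5000, n_snps = 30, seed = 13)
  pgs <- standardize(rnorm(5000))
  expect_identical(apply_attrition(pgs, cfg), 1:5000)

  cfg2 <- simulation_config(n_participants = 5000, n_snps = 30, seed = 13,
                            attrition_gamma = -0.3, retention_target = 0.7)
  kept <- apply_attrition(pgs, cfg2)
  expect_identical(kept, apply_attrition(pgs, cfg2))
  expect_lt(abs(length(kept) / 5000 - 0.7), 0.05)
  expect_lt(mean(pgs[kept]), mean(pgs[-kept]))
})
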