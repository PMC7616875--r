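test_that("kernel weights follow the inverse-distance power rule with a floor", {
  k <- weight_kernel(power = 0.5, min_distance = 50)
  coords <- rbind(c(1, 0), c(4, 0), c(0, 0), c(0.5, 0))
  w <- kernel_weights(coords, node = c(0, 0), kernel = weight_kernel(0.5, 0.25))
  # d = 1 gives w = 1 for any power; d = 4 gives 1/sqrt(4) = 0.5
  expect_equal(w[1], 1)
  expect_equal(w[2], 0.5)
  # at d = 0 the floor applies: w = 1/sqrt(min_distance)
  w0 <- kernel_weights(rbind(c(0, 0)), c(0, 0), k)
  expect_equal(w0, 1 / sqrt(50))
  expect_true(all(is.finite(kernel_weights(coords, c(0, 0), k))))
  expect_error(weight_kernel(power = 0), class = "pgsmap_config_error")
  expect_error(weight_kernel(min_distance = -1), class = "pgsmap_config_error")
})

test_that("uniform weights reduce WLS to OLS", {
  dat <- toy_cohort(n = 80, seed = 3)
  spec <- model_spec("trait", "pgs")
  fit <- fit_weighted_model(dat, spec, rep(2.5, 80))
  ols <- lm(trait ~ pgs + sex + age, data = dat)
  expect_equal(unname(fit$coefficients), unname(coef(ols)), tolerance = 1e-8)
  expect_equal(unname(fit$se), unname(summary(ols)$coefficients[, 2]),
               tolerance = 1e-8)
  expect_equal(fit$n_effective, 80)
})

test_that("noise-free linear data is recovered exactly under any weights", {
  set.seed(7)
  dat <- toy_cohort(n = 50, seed = 7)
  dat$trait <- 2 * dat$pgs
  spec <- model_spec("trait", "pgs")
  w <- runif(50, 0.1, 5)
  fit <- fit_weighted_model(dat, spec, w)
  expect_equal(fit$beta, 2, tolerance = 1e-10)
  expect_lt(fit$sigma2, 1e-18)
})

test_that("WLS matches the closed-form normal-equations oracle", {
  # 5-row worked example with unequal weights
  dat5 <- data.frame(trait = c(1.2, 0.3, -0.5, 2.2, 0.9),
                     pgs = c(0.5, -1.1, 0.2, 1.4, -0.3),
                     sex = c(0, 1, 1, 0, 1),
                     age = c(10.6, 10.8, 10.7, 10.5, 10.9))
  w5 <- c(2, 1, 0.5, 3, 1.5)
  X5 <- cbind(1, dat5$pgs, dat5$sex, dat5$age)
  # 5 rows fit 4 coefficients exactly at the spec minimum margin is not
  # met, so use the coefficient-only oracle with a taller replicate
  dat <- rbind(dat5, dat5 + 0.1)
  w <- c(w5, rev(w5))
  X <- cbind(1, dat$pgs, dat$sex, dat$age)
  spec <- model_spec("trait", "pgs")
  fit <- fit_weighted_model(dat, spec, w)
  orc <- oracle_wls(X, dat$trait, w)
  expect_equal(unname(fit$coefficients), unname(orc$coef), tolerance = 1e-10)
  expect_equal(unname(fit$se), unname(orc$se), tolerance = 1e-10)

  # random instances
  set.seed(42)
  for (r in 1:100) {
    n <- sample(12:60, 1)
    dat <- data.frame(trait = rnorm(n), pgs = rnorm(n),
                      sex = rbinom(n, 1, 0.5), age = rnorm(n, 10.7, 0.2))
    w <- runif(n, 0.05, 10)
    X <- cbind(1, dat$pgs, dat$sex, dat$age)
    fit <- fit_weighted_model(dat, spec, w)
    orc <- oracle_wls(X, dat$trait, w)
    expect_equal(unname(fit$coefficients), unname(orc$coef), tolerance = 1e-8)
    expect_equal(unname(fit$se), unname(orc$se), tolerance = 1e-8)
  }
})

test_that("coefficients and SEs are invariant to weight rescaling", {
  dat <- toy_cohort(n = 70, seed = 9)
  spec <- model_spec("trait", "pgs")
  w <- runif(70, 0.5, 2)
  f1 <- fit_weighted_model(dat, spec, w)
  f2 <- fit_weighted_model(dat, spec, w * 1234.5)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f1$se, f2$se, tolerance = 1e-10)
})

test_that("rank-deficient designs fail loudly, naming the collinear column", {
  dat <- toy_cohort(n = 40, seed = 11)
  dat$age2 <- dat$age  # exact duplicate
  spec <- model_spec("trait", "pgs", covariates = c("sex", "age", "age2"))
  err <- tryCatch(fit_weighted_model(dat, spec, rep(1, 40)), error = identity)
  expect_s3_class(err, "pgsmap_singular_design")
  expect_match(conditionMessage(err), "age2")
})

test_that("map_associations recovers constant and gradient beta surfaces", {
  cfg <- simulation_config(n_participants = 3000, n_snps = 60,
                           beta_surface = list(type = "constant", value = 0.3),
                           seed = 19)
  sim <- simulate_cohort(cfg)
  grid <- build_hex_grid(cfg$region, target_n = 120)
  spec <- model_spec("trait", "pgs_true")
  map <- map_associations(sim$cohort, grid, weight_kernel(), spec)
  expect_true(all(map$converged))
  expect_equal(nrow(map), nrow(grid$nodes))

  glob <- fit_weighted_model(sim$cohort, spec, rep(1, nrow(sim$cohort)))
  # smoothing towards the population mean: map centred on the global fit
  expect_lt(abs(mean(map$beta) - glob$beta), 3 * glob$se_beta)
  expect_lt(sd(map$beta), glob$se_beta * sqrt(nrow(map)))

  # gradient surface: fitted map increases along x
  cfg2 <- simulation_config(n_participants = 3000, n_snps = 60, seed = 19)
  sim2 <- simulate_cohort(cfg2)
  map2 <- map_associations(sim2$cohort, grid, weight_kernel(), spec)
  sl <- summary(lm(map2$beta ~ grid$nodes$x))$coefficients[2, ]
  expect_gt(sl["Estimate"], 0)
  expect_lt(sl["Pr(>|t|)"], 0.01)

  # destroying the spatial arrangement of participants flattens the map
  sim3 <- sim2
  set.seed(77)
  perm <- sample(nrow(sim3$cohort))
  sim3$cohort$x <- sim3$cohort$x[perm]
  sim3$cohort$y <- sim3$cohort$y[perm]
  map3 <- map_associations(sim3$cohort, grid, weight_kernel(), spec)
  sl3 <- coef(lm(map3$beta ~ grid$nodes$x))[2]
  expect_lt(abs(sl3), 0.5 * abs(sl["Estimate"]))
})

test_that("noise-free planted data is recovered exactly at every node", {
  cfg <- simulation_config(
    n_participants = 400, n_snps = 30, trait_noise_sd = 1e-12,
    beta_surface = list(type = "constant", value = 1.25), seed = 23
  )
  sim <- simulate_cohort(cfg)
  grid <- build_hex_grid(cfg$region, target_n = 60)
  map <- map_associations(sim$cohort, grid, weight_kernel(),
                          model_spec("trait", "pgs_true"))
  expect_lt(max(abs(map$beta - 1.25)), 1e-8)
})

test_that("stronger kernel powers localize two planted cluster effects more", {
  # two settlements with different true betas; the gap between the fitted
  # betas at the two centres grows with the kernel power
  reps <- 20
  powers <- c(0.25, 0.5, 1, 2)
  gaps <- matrix(NA_real_, reps, length(powers))
  for (r in seq_len(reps)) {
    set.seed(400 + r)
    n <- 1000
    cl <- rbinom(n, 1, 0.5)
    x <- ifelse(cl == 1, 25000, 5000) + rnorm(n, 0, 1500)
    y <- 15000 + rnorm(n, 0, 1500)
    pgs <- standardize(rnorm(n))
    beta_true <- ifelse(cl == 1, 0.8, 0.1)
    dat <- data.frame(
      x = x, y = y, pgs = pgs,
      sex = rbinom(n, 1, 0.5), age = rnorm(n, 10.7, 0.12)
    )
    dat$trait <- 1 + beta_true * pgs + 0.3 * dat$sex + rnorm(n)
    spec <- model_spec("trait", "pgs")
    for (pi in seq_along(powers)) {
      k <- weight_kernel(power = powers[pi], min_distance = 50)
      b1 <- fit_weighted_model(dat, spec, kernel_weights(cbind(x, y), c(5000, 15000), k))$beta
      b2 <- fit_weighted_model(dat, spec, kernel_weights(cbind(x, y), c(25000, 15000), k))$beta
      gaps[r, pi] <- abs(b2 - b1)
    }
  }
  avg <- colMeans(gaps)
  expect_true(all(diff(avg) >= 0))
})

test_that("mapping validates inputs and reports missing columns", {
  cfg <- simulation_config(n_participants = 200, n_snps = 20, seed = 29)
  sim <- simulate_cohort(cfg)
  grid <- build_hex_grid(cfg$region, target_n = 40)
  expect_error(
    map_associations(sim$cohort, grid, weight_kernel(),
                     model_spec("nope", "pgs_true")),
    class = "pgsmap_config_error"
  )
  expect_error(model_spec("trait", "trait"), class = "pgsmap_config_error")
  expect_error(model_spec("trait", "pgs", covariates = c("sex", "pgs")),
               class = "pgsmap_config_error")
})
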