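test_that("chains have the planned length, SPD covariances, determinism", {
  fit <- small_fit()
  ch <- fit$chain
  expect_equal(ch$n_retained, 200L)      # floor((2500-500)/10)
  expect_equal(nrow(ch$beta), 200L)
  # SPD invariant on a systematic subsample of stored covariance draws
  idx <- seq(1L, 200L, by = 20L)
  for (s in idx) {
    expect_gt(min(eigen(ch$cov$genotype[s, , ])$values), 0)
    for (e in ch$labels$environments) {
      expect_gt(min(eigen(ch$cov$gxe[[e]][s, , ])$values), 0)
      expect_gt(min(eigen(ch$cov$residual[[e]][s, , ])$values), 0)
    }
  }
  # bit-identical reproduction under the same seed/config/data
  sc <- small_scenario()
  ph <- simulate_phenotypes(sc$design, sc$truth, seed = 7L)
  fit2 <- mtme(ph, model = "full", n_iter = 2500, burn_in = 500, thin = 10,
               seed = 7L, store_effects = TRUE)
  expect_identical(fit2$chain$beta, ch$beta)
  expect_identical(fit2$chain$deviance, ch$deviance)
  expect_identical(fit2$chain$cov$genotype, ch$cov$genotype)
})

test_that("residual-variance marginal matches its conjugate closed form", {
  # fixed-effects-only single-trait model: exact inverse-gamma marginal
  g <- rep(sprintf("g%02d", 1:15), each = 2)
  b <- rep(c("b1", "b2"), 15)
  set.seed(3)
  yv <- rnorm(30, mean = 10, sd = 2)
  tab <- data.frame(genotype = g, environment = "E1", block = b,
                    trait = "t", value = yv, stringsAsFactors = FALSE)
  m <- assemble(tab, build_model_spec("fixed", "t"))
  pr <- prior_spec(nu0 = 4, V0 = 3)
  ch <- run_gibbs(m, run_config(n_iter = 7000, burn_in = 1000, thin = 1,
                                seed = 5, prior = pr))
  se2 <- ch$cov$residual[["E1"]][, 1, 1]
  # marginal over the flat cell mean: IW1(nu0 + n - 1, V0 + S)
  S <- sum((yv - mean(yv))^2)
  nu_n <- 4 + 30 - 1
  s_n <- 3 + S
  mcse <- sd(se2) / sqrt(effective_size(se2))
  expect_lt(abs(mean(se2) - s_n / (nu_n - 2)), 3 * mcse)
  or_var <- 2 * s_n^2 / ((nu_n - 2)^2 * (nu_n - 4))
  expect_lt(abs(var(se2) - or_var), 0.2 * or_var)
})

test_that("with known residual variance, beta matches its Gaussian posterior", {
  g <- rep(sprintf("g%02d", 1:15), each = 2)
  b <- rep(c("b1", "b2"), 15)
  set.seed(4)
  yv <- rnorm(30, mean = -3, sd = 1.5)
  tab <- data.frame(genotype = g, environment = "E1", block = b,
                    trait = "t", value = yv, stringsAsFactors = FALSE)
  m <- assemble(tab, build_model_spec("fixed", "t"))
  ch <- run_gibbs(m, run_config(n_iter = 6000, burn_in = 1000, thin = 1,
                                seed = 6, prior = prior_spec(nu0 = 4, V0 = 3)),
                  fixed_residual = 2.5)
  bs <- ch$beta[, 1]
  mcse <- sd(bs) / sqrt(effective_size(bs))
  expect_lt(abs(mean(bs) - mean(yv)), 3 * mcse)
  expect_lt(abs(sd(bs) - sqrt(2.5 / 30)), 0.1 * sqrt(2.5 / 30))
  # residual covariance stays fixed
  expect_equal(unique(ch$cov$residual[["E1"]][, 1, 1]), 2.5)
})

test_that("zero true interaction concentrates the interaction variance near 0", {
  des <- trial_design(20, c("E1", "E2"), 3, "t")
  tr <- generative_truth(des, matrix(c(10, 12), 2, 1), sigma_g = 9,
                         sigma_int = 0, sigma_r = 1, sigma_e = 4)
  ph <- simulate_phenotypes(des, tr, seed = 21)
  fit <- mtme(ph, model = "full", n_iter = 4000, burn_in = 1000, thin = 3,
              seed = 21)
  for (e in c("E1", "E2")) {
    med_int <- median(fit$chain$cov$gxe[[e]][, 1, 1])
    expect_lt(med_int, 9)   # below the true main-effect variance
    expect_lt(med_int, median(fit$chain$cov$genotype[, 1, 1]))
  }
})

test_that("the conditional deviance matches its closed forms", {
  expect_equal(gaussian_deviance(0, 1 / (2 * pi)), 0)
  expect_equal(gaussian_deviance(0, 1), log(2 * pi), tolerance = 1e-12)
  expect_equal(gaussian_deviance(0, 1), 1.8379, tolerance = 1e-4)
  # determinism on one state
  r <- matrix(rnorm(10), 5, 2)
  sig <- correlation_to_covariance(c(1, 2), 0.3)
  expect_identical(gaussian_deviance(r, sig), gaussian_deviance(r, sig))
  expect_error(gaussian_deviance(0, 0), "positive definite")
  # full-model conditional deviance equals the sum of per-plot densities
  fit <- small_fit()
  m <- fit$model
  pm <- fit$chain$post_mean
  st <- list(beta = pm$beta, block = pm$block, genotype = pm$genotype,
             gxe = pm$gxe, residual = pm$residual)
  D <- conditional_deviance(m, st)
  resid <- m$Y - (pm$beta[m$env_idx, ] + pm$block[m$blk_idx, ] +
                    pm$genotype[m$geno_idx, ] + pm$gxe[m$ge_idx, ])
  D2 <- sum(vapply(seq_along(m$labels$environments), function(ei) {
    gaussian_deviance(resid[m$rows_e[[ei]], , drop = FALSE],
                      pm$residual[[ei]])
  }, numeric(1)))
  expect_equal(D, D2, tolerance = 1e-10)
})

test_that("posterior summaries are invariant to trait rescaling", {
  # scaling one trait by c with a correspondingly scaled prior leaves
  # heritability and genetic correlation distributions unchanged
  sc <- small_scenario()
  ph <- simulate_phenotypes(sc$design, sc$truth, seed = 13)
  ph2 <- ph
  cc <- 100
  ph2$value[ph2$trait == "A"] <- ph2$value[ph2$trait == "A"] * cc
  f1 <- mtme(ph, model = "full", n_iter = 2000, burn_in = 500, thin = 5,
             seed = 3)
  f2 <- mtme(ph2, model = "full", n_iter = 2000, burn_in = 500, thin = 5,
             seed = 3)
  h1 <- heritability_samples(f1, "A", "E1")
  h2 <- heritability_samples(f2, "A", "E1")
  expect_equal(h1, h2, tolerance = 1e-8)
  r1 <- genetic_correlation_samples(f1, "A", "B", "E2")
  r2 <- genetic_correlation_samples(f2, "A", "B", "E2")
  expect_equal(as.numeric(r1), as.numeric(r2), tolerance = 1e-8)
})
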