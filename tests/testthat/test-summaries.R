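test_that("heritability samples follow the variance-ratio definition", {
  ch <- fake_chain(sg = 2, sr = 1, se = 1)
  expect_true(all(heritability_samples(ch, "t", "E1") == 0.5))
  ch0 <- fake_chain(sg = 0, sr = 1, se = 1)
  expect_true(all(heritability_samples(ch0, "t", "E1") == 0))
  # full model: interaction variance adds to the genetic variance
  chf <- fake_chain(sg = 2, sr = 1, se = 1, sint = 2)
  expect_true(all(heritability_samples(chf, "t", "E1") == 2 / 3))
  expect_error(heritability_samples(ch, "bogus", "E1"), "unknown trait")
  expect_error(heritability_samples(ch, "t", "E9"), "unknown environment")
})

test_that("genetic correlations come from the genetic covariance entries", {
  Sg <- matrix(c(4, 3, 3, 9), 2, 2, dimnames = list(c("a", "b"),
                                                    c("a", "b")))
  ch <- fake_chain(sg = NULL, sg_cov = Sg, sr = diag(2), se = diag(2))
  rho <- genetic_correlation_samples(ch, "a", "b", "E1")
  expect_true(all(rho == 0.5))
  expect_equal(attr(rho, "n_excluded"), 0L)
  Sd <- diag(c(4, 9)); dimnames(Sd) <- dimnames(Sg)
  chd <- fake_chain(sg = NULL, sg_cov = Sd, sr = diag(2), se = diag(2))
  expect_true(all(genetic_correlation_samples(chd, "a", "b", "E1") == 0))
  expect_error(genetic_correlation_samples(ch, "a", "a", "E1"), "differ")
})

test_that("the relative variation index is the CV ratio", {
  expect_equal(relative_variation_index(3, 3), 1)
  expect_equal(relative_variation_index(2, 4), 0.5)
  expect_error(relative_variation_index(1, 0), "nonzero")
  expect_error(relative_variation_index(-1, 2), "non-negative")
})

test_that("DIC obeys its algebraic identity and point-mass degenerate case", {
  fit <- small_fit()
  ic <- dic(fit)
  expect_equal(ic$DIC, mean(fit$chain$deviance) + ic$pD, tolerance = 1e-12)
  expect_equal(ic$pD, ic$D_bar - ic$D_at_mean, tolerance = 1e-12)
  # a point-mass chain has pD = 0 and DIC = D
  chp <- fake_chain(sg = 1, sr = 1, se = 1, deviance = 123.4,
                    dev_at_mean = 123.4)
  icp <- dic(chp)
  expect_equal(icp$pD, 0)
  expect_equal(icp$DIC, 123.4)
})

test_that("model comparison applies the |delta| <= 2 decision rule", {
  mk <- function(d) fake_chain(sg = 1, sr = 1, se = 1, deviance = d,
                               dev_at_mean = d)
  expect_equal(compare_models(mk(100), mk(110))$preferred, "full")
  expect_equal(compare_models(mk(100), mk(110))$delta, 10)
  expect_equal(compare_models(mk(100), mk(101))$preferred,
               "indistinguishable")
  expect_equal(compare_models(mk(110), mk(100))$preferred, "null")
  same <- mk(100)
  cmp <- compare_models(same, same)
  expect_equal(cmp$delta, 0)
  expect_equal(cmp$preferred, "indistinguishable")
})

test_that("model comparison refuses fits on different data", {
  sc <- small_scenario()
  p1 <- simulate_phenotypes(sc$design, sc$truth, seed = 1)
  p2 <- simulate_phenotypes(sc$design, sc$truth, seed = 2)
  f1 <- mtme(p1, model = "full", n_iter = 400, burn_in = 100, thin = 1,
             seed = 1)
  f2 <- mtme(p2, model = "null", n_iter = 400, burn_in = 100, thin = 1,
             seed = 1)
  expect_error(compare_models(f1, f2), "same data")
})

test_that("genotype rankings recover the truth in the near-noiseless limit", {
  des <- trial_design(10, c("E1", "E2"), 3, "t")
  tr <- generative_truth(des, matrix(c(0, 0), 2, 1), sigma_g = 25,
                         sigma_int = 1e-4, sigma_r = 1e-4, sigma_e = 1e-4)
  ph <- simulate_phenotypes(des, tr, seed = 31, return_effects = TRUE)
  eff <- attr(ph, "effects")
  fit <- mtme(ph, model = "full", n_iter = 1500, burn_in = 500, thin = 5,
              seed = 31, store_effects = TRUE)
  for (e in c("E1", "E2")) {
    gv <- genotype_values(fit, e, "t")
    true_val <- eff$genotype[, 1] + eff$gxe[[e]][, 1]
    true_rank <- names(sort(true_val, decreasing = TRUE))
    expect_identical(gv$genotype, true_rank)
  }
  # without stored effects the error is informative
  fit2 <- mtme(ph, model = "full", n_iter = 300, burn_in = 100, thin = 1,
               seed = 1)
  expect_error(genotype_values(fit2, "E1", "t"), "store_effects")
})

test_that("null-model rankings are identical across environments", {
  sc <- small_scenario()
  ph <- simulate_phenotypes(sc$design, sc$truth, seed = 17)
  fit <- mtme(ph, model = "null", n_iter = 1200, burn_in = 200, thin = 5,
              seed = 17, store_effects = TRUE)
  r1 <- genotype_values(fit, "E1", "A")
  r2 <- genotype_values(fit, "E2", "A")
  expect_identical(r1$genotype, r2$genotype)
  expect_equal(r1$value, r2$value)
})

test_that("summary tables carry all parameter groups with valid HPDs", {
  fit <- small_fit()
  st <- summary_table(fit)
  # 4 beta + 2 sigma_g + 4 sigma_int + 4 sigma_r + 4 sigma_e + 4 h2 + 2 rho
  expect_equal(nrow(st), 24L)
  expect_equal(sum(grepl("^beta", st$parameter)), 4L)
  expect_true(all(st$lower <= st$upper))
  h2 <- st[grepl("^h2", st$parameter), ]
  expect_true(all(h2$lower >= 0 & h2$upper <= 1))
  rho <- st[grepl("^rho_g", st$parameter), ]
  expect_equal(nrow(rho), 2L)
  expect_true(all(rho$lower >= -1 & rho$upper <= 1))
  # entire chains respect the ranges, not just the intervals
  for (e in c("E1", "E2")) {
    for (tr in c("A", "B")) {
      h <- heritability_samples(fit, tr, e)
      expect_true(all(h >= 0 & h <= 1))
    }
    r <- genetic_correlation_samples(fit, "A", "B", e)
    expect_true(all(r >= -1 & r <= 1))
  }
})

test_that("coefficients of variation use posterior means over the data mean", {
  fit <- small_fit()
  cv <- coefficient_of_variation(fit, "A", "E1")
  ch <- fit$chain
  sg <- mean(ch$cov$genotype[, "A", "A"] + ch$cov$gxe[["E1"]][, "A", "A"])
  se <- mean(ch$cov$residual[["E1"]][, "A", "A"])
  tab <- fit$model$table
  mu <- mean(tab$value[tab$trait == "A" & tab$environment == "E1"])
  expect_equal(cv$cv_g, 100 * sqrt(sg) / mu)
  expect_equal(cv$cv_e, 100 * sqrt(se) / mu)
  expect_equal(cv$ratio, cv$cv_g / cv$cv_e)
  expect_gt(cv$cv_g, 0)
})
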