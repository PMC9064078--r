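test_that("correlation_to_covariance builds SPD matrices and rejects bad input", {
  expect_equal(correlation_to_covariance(c(1, 1), diag(2)), diag(2))
  expect_equal(correlation_to_covariance(c(2, 3), 0.5),
               matrix(c(4, 3, 3, 9), 2, 2))
  expect_error(correlation_to_covariance(c(1, 1), 1.0), "eigenvalue")
  expect_error(correlation_to_covariance(c(-1, 1), diag(2)), "positive")
  expect_error(correlation_to_covariance(c(1, 1),
                                         matrix(c(1, 2, 2, 1), 2, 2)),
               "\\[-1, 1\\]")
})

test_that("design and truth constructors enforce their invariants", {
  expect_error(trial_design(1, "E1", 3, "t"), ">= 2")
  expect_error(trial_design(5, "E1", 1, "t"), ">= 2")
  des <- trial_design(5, c("E1", "E2"), 2, "t")
  expect_error(generative_truth(des, matrix(1, 2, 1), sigma_g = -1,
                                sigma_int = 1, sigma_r = 1, sigma_e = 1),
               "positive")
  expect_error(generative_truth(des, matrix(Inf, 2, 1), sigma_g = 1,
                                sigma_int = 1, sigma_r = 1, sigma_e = 1),
               "finite")
  expect_error(generative_truth(des, matrix(1, 3, 1), sigma_g = 1,
                                sigma_int = 1, sigma_r = 1, sigma_e = 1),
               "2 x 1")
})

test_that("the noiseless limit returns exactly the cell means", {
  des <- trial_design(3, c("E1", "E2"), 2, c("A", "B"))
  zero <- matrix(0, 2, 2)
  beta <- matrix(c(10, 20, 100, 200), 2, 2)
  tr <- generative_truth(des, beta, sigma_g = zero, sigma_int = zero,
                         sigma_r = zero, sigma_e = zero)
  tab <- simulate_phenotypes(des, tr, seed = 1)
  for (i in seq_len(nrow(tab))) {
    e <- match(tab$environment[i], des$environments)
    t <- match(tab$trait[i], des$traits)
    expect_identical(tab$value[i], beta[e, t])
  }
})

test_that("simulation is seed-deterministic and validates its own output", {
  sc <- small_scenario()
  t1 <- simulate_phenotypes(sc$design, sc$truth, seed = 33)
  t2 <- simulate_phenotypes(sc$design, sc$truth, seed = 33)
  t3 <- simulate_phenotypes(sc$design, sc$truth, seed = 34)
  expect_identical(t1, t2)
  expect_false(identical(t1$value, t3$value))
  expect_s3_class(phenotype_table(t1), "mtme_phenotypes")
})

test_that("empirical cell means fall within 3 standard errors of beta", {
  sc <- default_rice_scenario()
  tab <- simulate_phenotypes(sc$design, sc$truth, seed = 202)
  tr <- sc$truth
  for (e in sc$design$environments) {
    for (t in sc$design$traits) {
      v <- tab$value[tab$environment == e & tab$trait == t]
      # plot values share genotype/block effects; bound SE by total sd
      tot_sd <- sqrt(tr$sigma_g[t, t] + tr$sigma_int[[e]][t, t] +
                       tr$sigma_r[[e]][t, t] + tr$sigma_e[[e]][t, t])
      expect_lt(abs(mean(v) - tr$beta[e, t]), 3 * tot_sd / sqrt(25))
    }
  }
})

test_that("variance of genotype means matches the closed form", {
  # single trait, one environment: var(genotype mean) = sigma_g^2 + sigma_e^2/B
  des <- trial_design(200, "E1", 2, "t")
  tr <- generative_truth(des, matrix(0, 1, 1), sigma_g = 4, sigma_int = 0,
                         sigma_r = 0, sigma_e = 1)
  tab <- simulate_phenotypes(des, tr, seed = 55)
  gm <- tapply(tab$value, tab$genotype, mean)
  target <- 4 + 1 / 2
  # MC error of a sample variance: sqrt(2/(G-1)) * true value
  expect_lt(abs(var(as.numeric(gm)) - target),
            3 * sqrt(2 / 199) * target)
})

test_that("plot-level covariance recovers the summed components", {
  des <- trial_design(400, "E1", 2, c("A", "B"))
  Sg <- correlation_to_covariance(c(2, 1), 0.5)
  Se <- correlation_to_covariance(c(1, 2), -0.2)
  tr <- generative_truth(des, matrix(c(5, 50), 1, 2), sigma_g = Sg,
                         sigma_int = matrix(0, 2, 2),
                         sigma_r = matrix(0, 2, 2), sigma_e = Se)
  tab <- simulate_phenotypes(des, tr, seed = 77)
  wide <- matrix(NA_real_, 800, 2)
  wide[, 1] <- tab$value[tab$trait == "A"]
  wide[, 2] <- tab$value[tab$trait == "B"]
  emp <- stats::cov(wide)
  # ~400 independent genotype clusters dominate the MC error: 3 sigma bound
  expect_lt(max(abs(emp - (Sg + Se))), 3 * sqrt(2 / 400) * 5)
})

test_that("the rice scenario reproduces the published cell means", {
  sc <- default_rice_scenario()
  expect_equal(sc$truth$beta["E1", "GY"], 4210.91)
  expect_equal(sc$truth$beta["E2", "FL"], 76.43)
  expect_equal(sc$truth$beta["E1", "FL"], 99.40)
  expect_equal(sc$truth$beta["E2", "GY"], 3901.56)
  expect_gt(.Machine$double.eps + min(eigen(sc$truth$sigma_g)$values), 0)
  expect_error(default_scenario("wheat"), "rice")
})
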