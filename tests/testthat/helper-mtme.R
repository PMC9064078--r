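# Shared fixtures, all built in code.

# smallest valid design: 1 genotype, 1 environment, 2 blocks, 2 traits
tiny_records <- function() {
  data.frame(genotype = "g1", environment = "e1",
             block = rep(c("b1", "b2"), each = 2L),
             trait = rep(c("t1", "t2"), times = 2L),
             value = c(1.5, 2.5, 1.0, 3.0),
             stringsAsFactors = FALSE)
}

rice_table <- function(seed = 101L) {
  sc <- default_rice_scenario()
  simulate_phenotypes(sc$design, sc$truth, seed = seed)
}

# small two-trait scenario for fast fits
small_scenario <- function() {
  des <- trial_design(10, c("E1", "E2"), 3, c("A", "B"))
  truth <- generative_truth(
    des, beta = matrix(c(50, 45, 20, 18), 2, 2),
    sigma_g = correlation_to_covariance(c(4, 2), 0.5),
    sigma_int = correlation_to_covariance(c(2, 1), 0.1),
    sigma_r = correlation_to_covariance(c(1, 0.5), 0),
    sigma_e = correlation_to_covariance(c(3, 1.5), 0.2))
  list(design = des, truth = truth)
}

# lazy cache shared across test files (one R session per test run)
.fixture_env <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small full-model fit with stored effects, reused by several files
small_fit <- function() {
  cached("small_fit", {
    sc <- small_scenario()
    ph <- simulate_phenotypes(sc$design, sc$truth, seed = 7L)
    mtme(ph, model = "full", n_iter = 2500, burn_in = 500, thin = 10,
         seed = 7L, store_effects = TRUE)
  })
}

# exhaustive minimal-width window oracle for HPD intervals
hpd_brute <- function(x, prob = 0.95) {
  xs <- sort(x)
  n <- length(xs)
  m <- ceiling(prob * n)
  best <- c(xs[1L], xs[m])
  for (i in seq_len(n - m + 1L)) {
    if (xs[i + m - 1L] - xs[i] < best[2L] - best[1L]) {
      best <- c(xs[i], xs[i + m - 1L])
    }
  }
  best
}

# minimal hand-built chain object for summary arithmetic checks
fake_chain <- function(sg, sr, se, sint = NULL, sg_cov = NULL, S = 200L,
                       deviance = NULL, dev_at_mean = NULL) {
  traits <- if (is.matrix(sg_cov)) colnames(sg_cov) else "t"
  if (is.null(traits)) traits <- paste0("t", seq_len(ncol(sg_cov)))
  Tt <- length(traits)
  arr <- function(m) {
    if (!is.matrix(m)) m <- matrix(m, 1L, 1L)
    a <- array(rep(m, each = S), c(S, Tt, Tt),
               dimnames = list(NULL, traits, traits))
    a
  }
  covs <- list(
    genotype = arr(if (is.null(sg_cov)) sg else sg_cov),
    block = list(E1 = arr(sr)),
    gxe = if (!is.null(sint)) list(E1 = arr(sint)),
    residual = list(E1 = arr(se)))
  dv <- if (is.null(deviance)) rep(100, S) else rep(deviance, length.out = S)
  structure(list(
    beta = matrix(1, S, Tt, dimnames = list(NULL, paste0("E1:", traits))),
    cov = covs, deviance = dv,
    dev_at_mean = if (is.null(dev_at_mean)) mean(dv) else dev_at_mean,
    effects = NULL, iters = seq_len(S), n_retained = S,
    labels = list(genotypes = c("g1", "g2"), environments = "E1",
                  traits = traits, blocks = "E1:b1"),
    spec = model_spec(traits,
                      terms = c("block", "genotype",
                                if (!is.null(sint)) "gxe")),
    config = list(seed = 1L), scale = rep(1, Tt),
    fingerprint = list(n = 1L, traits = traits, value_sum = 0,
                       value_ss = 0)),
    class = "mtme_chain")
}
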