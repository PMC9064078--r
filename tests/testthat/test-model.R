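test_that("model variants define the expected random terms", {
  full <- build_model_spec("full", c("GY", "FL"))
  expect_length(full$random_terms, 3L)
  expect_equal(full$terms, c("block", "genotype", "gxe"))
  null1 <- build_model_spec("null", "GY")
  expect_length(null1$random_terms, 2L)
  expect_true(all(lengths(lapply(null1$random_terms,
                                 `[[`, "effect_axis")) == 1L))
  expect_error(build_model_spec("ridge", "GY"), "unknown model variant")
  expect_error(model_spec("GY", terms = "gxe"), "genotype")
})

test_that("assembly produces the documented dimensions and index maps", {
  tab <- rice_table()
  m <- assemble(tab, build_model_spec("full", c("GY", "FL")))
  expect_length(m$y, 300L)
  expect_equal(dim(m$X), c(300L, 4L))        # 2 env x 2 trait cell means
  expect_equal(dim(m$Z$block), c(300L, 12L))
  expect_equal(dim(m$Z$genotype), c(300L, 50L))
  expect_equal(dim(m$Z$gxe), c(300L, 100L))
  # every row selects exactly one cell / one level per trait slot
  expect_true(all(rowSums(m$X) == 1) && all(rowSums(m$X != 0) == 1))
  for (Z in m$Z) expect_true(all(rowSums(Z != 0) == 1))
  # row map is a bijection onto the records
  expect_equal(nrow(unique(m$row_map)), 300L)

  m1 <- assemble(tab, build_model_spec("null", "GY"))
  expect_length(m1$y, 150L)
  expect_equal(dim(m1$X), c(150L, 2L))
  expect_null(m1$Z$gxe)
})

test_that("assembly rejects absent traits and single-genotype tables", {
  tab <- rice_table()
  expect_error(assemble(tab, build_model_spec("full", c("GY", "HT"))),
               "not present")
  tiny <- phenotype_table(tiny_records())
  expect_error(assemble(tiny, build_model_spec("null", c("t1", "t2"))),
               "fewer than 2 genotypes")
})

test_that("assembly is lossless: incidence matrices reproduce the data", {
  sc <- small_scenario()
  tab <- simulate_phenotypes(sc$design, sc$truth, seed = 11,
                             return_effects = TRUE)
  eff <- attr(tab, "effects")
  m <- assemble(tab, build_model_spec("full", c("A", "B")))
  traits <- m$labels$traits

  b_stack <- vapply(colnames(m$X), function(cn) {
    p <- strsplit(cn, ":", fixed = TRUE)[[1]]
    sc$truth$beta[p[1], p[2]]
  }, numeric(1))
  r_stack <- vapply(colnames(m$Z$block), function(cn) {
    p <- strsplit(cn, ":", fixed = TRUE)[[1]]
    eff$block[[p[1]]][p[2], match(p[3], sc$design$traits)]
  }, numeric(1))
  g_stack <- vapply(colnames(m$Z$genotype), function(cn) {
    p <- strsplit(cn, ":", fixed = TRUE)[[1]]
    eff$genotype[p[1], match(p[2], sc$design$traits)]
  }, numeric(1))
  u_stack <- vapply(colnames(m$Z$gxe), function(cn) {
    p <- strsplit(cn, ":", fixed = TRUE)[[1]]
    eff$gxe[[p[2]]][p[1], match(p[3], sc$design$traits)]
  }, numeric(1))
  eps <- do.call(rbind, eff$residual)       # plot order: env, block, genotype
  eps_stack <- as.vector(t(eps[, match(traits, sc$design$traits)]))

  yhat <- as.vector(m$X %*% b_stack + m$Z$block %*% r_stack +
                      m$Z$genotype %*% g_stack + m$Z$gxe %*% u_stack) +
    eps_stack
  expect_equal(yhat, m$y, tolerance = 1e-12)
})
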