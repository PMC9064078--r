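test_that("smallest valid design validates and indexes correctly", {
  tab <- phenotype_table(tiny_records())
  d <- pheno_dims(tab)
  expect_s3_class(tab, "mtme_phenotypes")
  expect_equal(nrow(tab), 4L)
  expect_equal(length(d$genotypes), 1L)
  expect_equal(length(d$environments), 1L)
  expect_equal(d$traits, c("t1", "t2"))
  expect_equal(d$n_plots, 2L)
})

test_that("validation rejects duplicates, missing columns, and imbalance", {
  rec <- tiny_records()
  expect_error(phenotype_table(rbind(rec, rec[1, ])), "duplicate")
  expect_error(phenotype_table(rec[, -4]), "missing required column")
  # drop one cell -> unbalanced, message summarizes the missing cell
  expect_error(phenotype_table(rec[-2, ]), "unbalanced.*missing cell",
               ignore.case = TRUE)
  rec_bad <- rec
  rec_bad$value[1] <- NA
  expect_error(phenotype_table(rec_bad), "non-finite")
  expect_error(phenotype_table(rec[0, ]), "at least one record")
})

test_that("single-block environments are rejected", {
  rec <- tiny_records()
  rec <- rec[rec$block == "b1", ]
  expect_error(phenotype_table(rec), "fewer than 2 blocks")
})

test_that("read_phenotypes parses CSVs, applies dialects, reports counts", {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  df <- tiny_records()
  names(df) <- c("gen", "env", "rep", "var", "y")
  utils::write.csv(df, f, row.names = FALSE)
  expect_error(read_phenotypes(f), "missing required column")
  tab <- read_phenotypes(f, dialect = c(genotype = "gen", environment = "env",
                                        block = "rep", trait = "var",
                                        value = "y"))
  expect_equal(nrow(tab), 4L)
  counts <- attr(tab, "counts")
  expect_equal(sort(unique(counts$n)), 2L)  # 2 plots per trait x env
  expect_error(read_phenotypes(f, dialect = c(genotype = "nope")),
               "missing required column.*nope")
})

test_that("the synthetic rice trial yields 300 records over 150 plots", {
  tab <- rice_table()
  d <- pheno_dims(tab)
  expect_equal(d$n_records, 300L)     # 25 * 2 * 3 plots x 2 traits
  expect_equal(d$n_plots, 150L)
  expect_equal(length(d$genotypes), 25L)
})

test_that("write/read round trip reproduces a table exactly", {
  tab <- rice_table(seed = 5L)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_phenotypes(tab, f)
  back <- read_phenotypes(f)
  expect_identical(back$value, tab$value)
  expect_identical(back$genotype, tab$genotype)
  expect_identical(back$trait, tab$trait)
  expect_equal(length(readLines(f)), 301L)  # header + 300 data rows
  expect_error(write_phenotypes(tab[0, ], tempfile()), "at least one record")
})
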