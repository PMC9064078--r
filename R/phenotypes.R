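#' Construct and validate a phenotype table
#'
#' A phenotype table holds one record per plot x trait of a balanced
#' multi-environment randomized complete block trial: columns `genotype`,
#' `environment`, `block`, `trait` (labels, kept as character) and `value`
#' (numeric, trait units). Block labels are interpreted as nested within
#' environment: block "1" in two environments denotes two physically distinct
#' replications.
#'
#' Validation enforces the balanced-design contract: every (genotype,
#' environment, block) plot must carry a value for every trait, keys must be
#' unique, and values finite. Designs with missing cells are rejected.
#'
#' @param records data.frame with columns `genotype`, `environment`, `block`,
#'   `trait`, `value` (extra columns are dropped).
#' @return A validated data.frame of class `mtme_phenotypes`.
#' @seealso [read_phenotypes()], [simulate_phenotypes()]
#' @export
phenotype_table <- function(records) {
  if (!is.data.frame(records)) {
    stop("`records` must be a data.frame", call. = FALSE)
  }
  req <- c("genotype", "environment", "block", "trait", "value")
  miss <- setdiff(req, names(records))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(records)[req]
  if (nrow(df) == 0L) {
    stop("a phenotype table must contain at least one record", call. = FALSE)
  }
  for (col in c("genotype", "environment", "block", "trait")) {
    df[[col]] <- as.character(df[[col]])
    if (anyNA(df[[col]]) || any(!nzchar(df[[col]]))) {
      stop("column '", col, "' contains missing or empty labels", call. = FALSE)
    }
  }
  df$value <- as.numeric(df$value)
  if (any(!is.finite(df$value))) {
    bad <- which(!is.finite(df$value))[1L]
    stop("non-finite trait value at record ", bad, call. = FALSE)
  }

  key <- paste(df$genotype, df$environment, df$block, df$trait, sep = "\x1f")
  dup <- duplicated(key)
  if (any(dup)) {
    first <- which(dup)[1L]
    stop("duplicate (genotype, environment, block, trait) key: (",
         df$genotype[first], ", ", df$environment[first], ", ",
         df$block[first], ", ", df$trait[first], ")", call. = FALSE)
  }

  genotypes <- sort(unique(df$genotype))
  envs      <- sort(unique(df$environment))
  traits    <- sort(unique(df$trait))

  # complete balanced crossing, per environment (blocks may differ by site)
  missing_cells <- 0L
  example <- NULL
  keyset <- key
  for (e in envs) {
    blocks_e <- sort(unique(df$block[df$environment == e]))
    if (length(blocks_e) < 2L) {
      stop("environment '", e, "' has fewer than 2 blocks", call. = FALSE)
    }
    expected <- expand.grid(genotype = genotypes, block = blocks_e,
                            trait = traits, KEEP.OUT.ATTRS = FALSE,
                            stringsAsFactors = FALSE)
    ekey <- paste(expected$genotype, e, expected$block, expected$trait,
                  sep = "\x1f")
    absent <- !(ekey %in% keyset)
    if (any(absent)) {
      missing_cells <- missing_cells + sum(absent)
      if (is.null(example)) {
        i <- which(absent)[1L]
        example <- paste0("(", expected$genotype[i], ", ", e, ", ",
                          expected$block[i], ", ", expected$trait[i], ")")
      }
    }
  }
  if (missing_cells > 0L) {
    stop("unbalanced design: ", missing_cells,
         " missing cell(s), e.g. ", example, call. = FALSE)
  }

  rownames(df) <- NULL
  class(df) <- c("mtme_phenotypes", "data.frame")
  df
}

#' Index sets of a phenotype table
#'
#' @param table a phenotype table (any data.frame accepted by
#'   [phenotype_table()]).
#' @return list with `genotypes`, `environments`, `traits`, `blocks` (named
#'   list per environment), `n_plots`, and `n_records`.
#' @export
pheno_dims <- function(table) {
  df <- phenotype_table(table)
  envs <- sort(unique(df$environment))
  blocks <- lapply(envs, function(e) sort(unique(df$block[df$environment == e])))
  names(blocks) <- envs
  g <- sort(unique(df$genotype))
  tr <- sort(unique(df$trait))
  n_plots <- length(g) * sum(lengths(blocks))
  list(genotypes = g, environments = envs, traits = tr, blocks = blocks,
       n_plots = n_plots, n_records = nrow(df))
}

#' Read a long-format phenotype CSV
#'
#' Reads a comma-separated file with header and columns `genotype,
#' environment, block, trait, value` (decimal point '.'). Alternative column
#' names in the file are mapped through `dialect`.
#'
#' @param path path to the CSV file.
#' @param dialect optional named character vector mapping standard names to
#'   the file's column names, e.g. `c(genotype = "gen", value = "y")`.
#' @return A validated `mtme_phenotypes` table. The attribute `"counts"`
#'   holds per-trait, per-environment observation counts.
#' @export
read_phenotypes <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  std <- c("genotype", "environment", "block", "trait", "value")
  if (!is.null(dialect)) {
    if (is.null(names(dialect)) || !all(names(dialect) %in% std)) {
      stop("`dialect` must be a named vector using standard column names",
           call. = FALSE)
    }
    for (s in names(dialect)) {
      from <- dialect[[s]]
      if (!from %in% names(raw)) {
        stop("missing required column: '", from, "' (mapped to '", s, "')",
             call. = FALSE)
      }
      names(raw)[names(raw) == from] <- s
    }
  }
  miss <- setdiff(std, names(raw))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tab <- phenotype_table(raw)
  attr(tab, "counts") <- as.data.frame(
    table(trait = tab$trait, environment = tab$environment),
    responseName = "n", stringsAsFactors = FALSE)
  tab
}

#' Write a phenotype table to CSV
#'
#' Writes the long format read back by [read_phenotypes()]. Values are
#' serialized with 17 significant digits so that a read/write round trip
#' reproduces the table exactly.
#'
#' @param table a valid phenotype table.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_phenotypes <- function(table, path) {
  tab <- phenotype_table(table)
  out <- data.frame(genotype = tab$genotype, environment = tab$environment,
                    block = tab$block, trait = tab$trait,
                    value = sprintf("%.17g", tab$value),
                    stringsAsFactors = FALSE)
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e),
         call. = FALSE)
  })
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @export
print.mtme_phenotypes <- function(x, ...) {
  d <- pheno_dims(x)
  cat("Phenotype table:", d$n_records, "records,", d$n_plots, "plots\n")
  cat("  genotypes:   ", length(d$genotypes), "\n")
  cat("  environments:", length(d$environments),
      paste0("(", paste(d$environments, collapse = ", "), ")"), "\n")
  cat("  blocks/env:  ", paste(lengths(d$blocks), collapse = ", "), "\n")
  cat("  traits:      ", paste(d$traits, collapse = ", "), "\n")
  invisible(x)
}
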