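#' Declare an MTME model variant
#'
#' Two standard variants are provided: the *full* model carries random terms
#' for block-within-environment, genotype main effects, and
#' genotype-by-environment interaction deviations; the *null* model omits the
#' interaction term. A *fixed* variant (cell means plus residual only) is
#' available for benchmarking against closed-form posteriors.
#'
#' @param variant one of `"full"`, `"null"`, `"fixed"`.
#' @param traits character vector of trait labels to model jointly (a single
#'   trait gives the single-trait model).
#' @return object of class `mtme_spec` with an ordered `random_terms` list;
#'   each term records its name, grouping factor, effect axis (the traits)
#'   and whether its covariance is per-environment.
#' @export
build_model_spec <- function(variant, traits) {
  if (!is.character(variant) || length(variant) != 1L ||
      !(variant %in% c("full", "null", "fixed"))) {
    stop("unknown model variant '", paste(variant, collapse = ","),
         "'; use \"full\", \"null\" or \"fixed\"", call. = FALSE)
  }
  terms <- switch(variant,
                  full  = c("block", "genotype", "gxe"),
                  null  = c("block", "genotype"),
                  fixed = character(0))
  model_spec(traits, terms = terms, variant = variant)
}

#' Low-level model specification with an explicit term set
#'
#' Mainly for oracle and benchmark fits (e.g. a one-way random-effects toy
#' with only the genotype term); regular use goes through
#' [build_model_spec()].
#'
#' @param traits character vector of trait labels.
#' @param terms subset of `c("block", "genotype", "gxe")`, in update order.
#' @param variant optional variant label; derived from `terms` when `NULL`.
#' @return object of class `mtme_spec`.
#' @export
model_spec <- function(traits, terms = c("block", "genotype", "gxe"),
                       variant = NULL) {
  traits <- as.character(traits)
  if (length(traits) < 1L || anyDuplicated(traits)) {
    stop("`traits` must be a non-empty set of distinct labels", call. = FALSE)
  }
  allowed <- c("block", "genotype", "gxe")
  if (length(terms) && (!all(terms %in% allowed) || anyDuplicated(terms))) {
    stop("`terms` must be distinct elements of ",
         paste(allowed, collapse = ", "), call. = FALSE)
  }
  if ("gxe" %in% terms && !("genotype" %in% terms)) {
    stop("the interaction term requires the genotype main-effect term",
         call. = FALSE)
  }
  terms <- allowed[allowed %in% terms]   # canonical update order
  if (is.null(variant)) {
    variant <- if ("gxe" %in% terms) "full"
               else if (identical(terms, c("block", "genotype"))) "null"
               else "custom"
  }
  random_terms <- lapply(terms, function(tm) {
    list(name = tm,
         grouping = switch(tm, block = "block-within-environment",
                           genotype = "genotype", gxe = "genotype-by-environment"),
         effect_axis = sort(traits),
         per_environment = tm != "genotype")
  })
  structure(list(variant = variant, traits = traits, terms = terms,
                 random_terms = random_terms),
            class = "mtme_spec")
}

#' Assemble the stacked response and incidence matrices
#'
#' Observations are ordered deterministically by (environment, block,
#' genotype, trait label); the stacked response is plot-major, trait-minor.
#' Fixed effects use the cell-means parameterization: one column per
#' environment x trait cell, each row of `X` selecting exactly one cell.
#' Incidence matrices `Z` are built per random term with one column per
#' (level, trait) pair.
#'
#' @param table a phenotype table (see [phenotype_table()]).
#' @param spec an `mtme_spec`.
#' @return object of class `mtme_model`: stacked `y`, `X`, `Z` (named list),
#'   row/column index maps, the plot-level response matrix and factor
#'   indices used by the sampler, and the validated source records.
#' @export
assemble <- function(table, spec) {
  stopifnot(inherits(spec, "mtme_spec"))
  tab <- phenotype_table(table)
  have <- sort(unique(tab$trait))
  missing_tr <- setdiff(spec$traits, have)
  if (length(missing_tr)) {
    stop("trait(s) not present in the table: ",
         paste(missing_tr, collapse = ", "), call. = FALSE)
  }
  tab <- tab[tab$trait %in% spec$traits, , drop = FALSE]
  tab <- phenotype_table(tab)

  genotypes <- sort(unique(tab$genotype))
  if (length(genotypes) < 2L) {
    stop("genotype variance is inestimable with fewer than 2 genotypes",
         call. = FALSE)
  }
  envs <- sort(unique(tab$environment))
  traits <- sort(unique(tab$trait))
  Tt <- length(traits)
  E <- length(envs)
  G <- length(genotypes)

  tab <- tab[order(tab$environment, tab$block, tab$genotype, tab$trait), ,
             drop = FALSE]
  rownames(tab) <- NULL

  # global block levels (environment, block), sorted
  blk_lab <- unique(tab[, c("environment", "block")])
  blk_lab <- blk_lab[order(blk_lab$environment, blk_lab$block), , drop = FALSE]
  blk_levels <- paste(blk_lab$environment, blk_lab$block, sep = ":")
  B_e <- table(factor(blk_lab$environment, levels = envs))
  B_e <- stats::setNames(as.integer(B_e), envs)

  # plot table (one row per plot, same ordering as records)
  plot_key <- paste(tab$environment, tab$block, tab$genotype, sep = "\x1f")
  first <- !duplicated(plot_key)
  plots <- tab[first, c("environment", "block", "genotype"), drop = FALSE]
  rownames(plots) <- NULL
  n_plots <- nrow(plots)

  env_idx  <- match(plots$environment, envs)
  blk_idx  <- match(paste(plots$environment, plots$block, sep = ":"),
                    blk_levels)
  geno_idx <- match(plots$genotype, genotypes)
  ge_levels <- as.vector(outer(genotypes, envs, paste, sep = ":"))
  ge_idx <- match(paste(plots$genotype, plots$environment, sep = ":"),
                  ge_levels)

  # response matrix: rows follow the plot ordering, columns sorted traits
  Y <- matrix(NA_real_, n_plots, Tt, dimnames = list(NULL, traits))
  pr <- match(plot_key, plot_key[first])
  tc <- match(tab$trait, traits)
  Y[cbind(pr, tc)] <- tab$value

  n_obs <- n_plots * Tt
  y <- as.vector(t(Y))

  # fixed-effect incidence (cell means): columns env-major, trait-minor
  x_cols <- as.vector(t(outer(envs, traits, paste, sep = ":")))
  X <- matrix(0, n_obs, E * Tt, dimnames = list(NULL, x_cols))
  row_env <- rep(env_idx, each = Tt)
  row_trait <- rep(seq_len(Tt), times = n_plots)
  X[cbind(seq_len(n_obs), (row_env - 1L) * Tt + row_trait)] <- 1

  make_Z <- function(level_idx, level_names) {
    q <- length(level_names)
    cols <- as.vector(t(outer(level_names, traits, paste, sep = ":")))
    Z <- matrix(0, n_obs, q * Tt, dimnames = list(NULL, cols))
    row_level <- rep(level_idx, each = Tt)
    Z[cbind(seq_len(n_obs), (row_level - 1L) * Tt + row_trait)] <- 1
    Z
  }
  Z <- list()
  if ("block" %in% spec$terms)    Z$block    <- make_Z(blk_idx, blk_levels)
  if ("genotype" %in% spec$terms) Z$genotype <- make_Z(geno_idx, genotypes)
  if ("gxe" %in% spec$terms)      Z$gxe      <- make_Z(ge_idx, ge_levels)

  row_map <- data.frame(environment = plots$environment[rep(seq_len(n_plots),
                                                            each = Tt)],
                        block = plots$block[rep(seq_len(n_plots), each = Tt)],
                        genotype = plots$genotype[rep(seq_len(n_plots),
                                                      each = Tt)],
                        trait = rep(traits, times = n_plots),
                        stringsAsFactors = FALSE)

  rows_e <- lapply(seq_along(envs), function(ei) which(env_idx == ei))
  names(rows_e) <- envs
  blk_local <- blk_idx - c(0L, cumsum(B_e))[env_idx]

  fp <- list(n = nrow(tab), traits = traits,
             value_sum = sum(tab$value), value_ss = sum(tab$value^2))

  structure(list(spec = spec, table = tab, y = y, X = X, Z = Z,
                 row_map = row_map, Y = Y,
                 env_idx = env_idx, blk_idx = blk_idx, geno_idx = geno_idx,
                 ge_idx = ge_idx, blk_local = blk_local, rows_e = rows_e,
                 labels = list(genotypes = genotypes, environments = envs,
                               traits = traits, blocks = blk_levels),
                 dims = list(G = G, E = E, T = Tt, B_e = B_e,
                             n_plots = n_plots, n_obs = n_obs,
                             n_plots_e = stats::setNames(
                               as.integer(lengths(rows_e)), envs)),
                 fingerprint = fp),
            class = "mtme_model")
}

#' @export
print.mtme_model <- function(x, ...) {
  d <- x$dims
  cat("Assembled MTME model (", x$spec$variant, " variant)\n", sep = "")
  cat("  observations:", d$n_obs, "(", d$n_plots, "plots x", d$T, "traits )\n")
  cat("  genotypes:", d$G, " environments:", d$E,
      " blocks/env:", paste(d$B_e, collapse = ", "), "\n")
  cat("  random terms:", if (length(x$spec$terms)) {
    paste(x$spec$terms, collapse = ", ")
  } else "(none)", "\n")
  invisible(x)
}
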