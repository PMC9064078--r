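# Plain-text chain store: one CSV per parameter group plus a JSON sidecar.

.num <- function(x) sprintf("%.17g", x)

.cov_long <- function(lst_or_arr, traits, envs, iters) {
  if (is.array(lst_or_arr) && length(dim(lst_or_arr)) == 3L) {
    lst_or_arr <- list(. = lst_or_arr)
  }
  rows <- list()
  for (e in names(lst_or_arr)) {
    a <- lst_or_arr[[e]]
    for (i in seq_along(traits)) {
      for (j in seq_along(traits)) {
        rows[[length(rows) + 1L]] <- data.frame(
          iter = iters, environment = e, trait_row = traits[i],
          trait_col = traits[j], value = .num(a[, i, j]),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Write a posterior chain to a directory of CSV files
#'
#' Layout: `beta.csv` (iteration plus one column per cell mean),
#' `cov_<term>.csv` in long format (iter, environment, trait_row, trait_col,
#' value; environment is `"."` for the shared genotype term),
#' `deviance.csv`, optional `effects_*.csv`, and `meta.json` holding labels,
#' model spec, chain plan, posterior means and the data fingerprint.
#'
#' @param chain an `mtme_chain`.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_chain <- function(chain, dir) {
  stopifnot(inherits(chain, "mtme_chain"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  traits <- chain$labels$traits
  envs <- chain$labels$environments
  iters <- chain$iters

  bet <- data.frame(iter = iters, stringsAsFactors = FALSE)
  for (cn in colnames(chain$beta)) bet[[cn]] <- .num(chain$beta[, cn])
  utils::write.csv(bet, file.path(dir, "beta.csv"), row.names = FALSE)

  for (term in c("genotype", "block", "gxe", "residual")) {
    a <- chain$cov[[term]]
    if (is.null(a)) next
    utils::write.csv(.cov_long(a, traits, envs, iters),
                     file.path(dir, paste0("cov_", term, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(data.frame(iter = iters, deviance = .num(chain$deviance)),
                   file.path(dir, "deviance.csv"), row.names = FALSE)

  if (!is.null(chain$effects)) {
    g <- chain$effects$genotype
    rows <- list()
    for (i in seq_along(traits)) {
      for (k in seq_along(chain$labels$genotypes)) {
        rows[[length(rows) + 1L]] <- data.frame(
          iter = iters, genotype = chain$labels$genotypes[k],
          trait = traits[i], value = .num(g[, k, i]),
          stringsAsFactors = FALSE)
      }
    }
    utils::write.csv(do.call(rbind, rows),
                     file.path(dir, "effects_genotype.csv"),
                     row.names = FALSE)
    if (!is.null(chain$effects$gxe)) {
      rows <- list()
      for (e in envs) {
        a <- chain$effects$gxe[[e]]
        for (i in seq_along(traits)) {
          for (k in seq_along(chain$labels$genotypes)) {
            rows[[length(rows) + 1L]] <- data.frame(
              iter = iters, environment = e,
              genotype = chain$labels$genotypes[k], trait = traits[i],
              value = .num(a[, k, i]), stringsAsFactors = FALSE)
          }
        }
      }
      utils::write.csv(do.call(rbind, rows),
                       file.path(dir, "effects_gxe.csv"), row.names = FALSE)
    }
  }

  meta <- list(labels = chain$labels,
               dims = chain$dims,
               spec = list(variant = chain$spec$variant,
                           traits = chain$spec$traits,
                           terms = chain$spec$terms),
               config = chain$config,
               n_retained = chain$n_retained,
               dev_at_mean = chain$dev_at_mean,
               scale = as.list(stats::setNames(chain$scale,
                                               chain$labels$traits)),
               post_mean = list(
                 beta = chain$post_mean$beta,
                 residual = chain$post_mean$residual),
               fingerprint = chain$fingerprint,
               package_version = as.character(utils::packageVersion(
                 "mtmebayes")))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, "meta.json"))
  invisible(dir)
}

.cov_from_long <- function(df, traits, envs, S, shared = FALSE) {
  mk <- function(sub) {
    a <- array(NA_real_, c(S, length(traits), length(traits)),
               dimnames = list(NULL, traits, traits))
    for (i in seq_along(traits)) {
      for (j in seq_along(traits)) {
        sel <- sub$trait_row == traits[i] & sub$trait_col == traits[j]
        a[, i, j] <- as.numeric(sub$value[sel])
      }
    }
    a
  }
  if (shared) return(mk(df))
  out <- lapply(envs, function(e) mk(df[df$environment == e, , drop = FALSE]))
  names(out) <- envs
  out
}

#' Read a posterior chain written by [write_chain()]
#'
#' @param dir chain directory.
#' @return an `mtme_chain` (without effect samples unless they were stored).
#' @export
read_chain <- function(dir) {
  metaf <- file.path(dir, "meta.json")
  if (!file.exists(metaf)) stop("not a chain directory (no meta.json): ",
                                dir, call. = FALSE)
  meta <- jsonlite::fromJSON(metaf, simplifyVector = TRUE)
  traits <- meta$labels$traits
  envs <- meta$labels$environments
  S <- meta$n_retained

  bet <- utils::read.csv(file.path(dir, "beta.csv"), check.names = FALSE,
                         colClasses = "character")
  iters <- as.integer(bet$iter)
  beta <- as.matrix(vapply(bet[-1L], as.numeric, numeric(S)))
  colnames(beta) <- names(bet)[-1L]

  rd <- function(term, shared = FALSE) {
    f <- file.path(dir, paste0("cov_", term, ".csv"))
    if (!file.exists(f)) return(NULL)
    df <- utils::read.csv(f, check.names = FALSE, colClasses = "character")
    .cov_from_long(df, traits, envs, S, shared = shared)
  }
  cov <- list(genotype = rd("genotype", shared = TRUE),
              block = rd("block"), gxe = rd("gxe"),
              residual = rd("residual"))

  dev <- utils::read.csv(file.path(dir, "deviance.csv"),
                         colClasses = "character")

  effects <- NULL
  gf <- file.path(dir, "effects_genotype.csv")
  if (file.exists(gf)) {
    gl <- utils::read.csv(gf, colClasses = "character")
    genos <- meta$labels$genotypes
    g <- array(NA_real_, c(S, length(genos), length(traits)),
               dimnames = list(NULL, genos, traits))
    for (i in seq_along(traits)) {
      for (k in seq_along(genos)) {
        sel <- gl$genotype == genos[k] & gl$trait == traits[i]
        g[, k, i] <- as.numeric(gl$value[sel])
      }
    }
    effects <- list(genotype = g)
    uf <- file.path(dir, "effects_gxe.csv")
    if (file.exists(uf)) {
      ul <- utils::read.csv(uf, colClasses = "character")
      effects$gxe <- stats::setNames(lapply(envs, function(e) {
        a <- array(NA_real_, c(S, length(genos), length(traits)),
                   dimnames = list(NULL, genos, traits))
        sube <- ul[ul$environment == e, , drop = FALSE]
        for (i in seq_along(traits)) {
          for (k in seq_along(genos)) {
            sel <- sube$genotype == genos[k] & sube$trait == traits[i]
            a[, k, i] <- as.numeric(sube$value[sel])
          }
        }
        a
      }), envs)
    }
  }

  spec <- model_spec(meta$spec$traits, terms = meta$spec$terms,
                     variant = meta$spec$variant)
  pm_beta <- as.matrix(meta$post_mean$beta)
  dimnames(pm_beta) <- list(envs, traits)
  pm_res <- lapply(meta$post_mean$residual, function(m) {
    m <- as.matrix(m); dimnames(m) <- list(traits, traits); m
  })
  dims <- meta$dims
  dims$B_e <- stats::setNames(as.integer(dims$B_e), envs)
  dims$n_plots_e <- stats::setNames(as.integer(dims$n_plots_e), envs)

  structure(list(beta = beta, cov = cov,
                 deviance = as.numeric(dev$deviance),
                 dev_at_mean = meta$dev_at_mean,
                 effects = effects,
                 post_mean = list(beta = pm_beta, residual = pm_res),
                 iters = iters, n_retained = S,
                 labels = meta$labels, dims = dims, spec = spec,
                 config = meta$config,
                 scale = unlist(meta$scale),
                 fingerprint = meta$fingerprint),
            class = "mtme_chain")
}
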