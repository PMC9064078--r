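#' Fit a Bayesian multi-trait multi-environment mixed model
#'
#' The workhorse of the package: validates the phenotype table, assembles
#' the stacked model
#' \deqn{y = X\beta + W_1 r + W_2 g + W_3 u + \varepsilon,}
#' with cell-mean fixed effects \eqn{\beta} (one mean per environment x
#' trait), block-within-environment effects \eqn{r}, genotype main effects
#' \eqn{g}, genotype-by-environment deviations \eqn{u} (full model only) and
#' residuals \eqn{\varepsilon}, and estimates it by Gibbs sampling with
#' inverse-Wishart priors on all covariance matrices (see [run_gibbs()]).
#'
#' @param data a phenotype table: a data.frame with columns `genotype`,
#'   `environment`, `block`, `trait`, `value`, or a path to such a CSV.
#' @param traits traits to model jointly; default all traits in the data.
#' @param model `"full"` (with genotype-by-environment interaction) or
#'   `"null"` (without).
#' @param n_iter,burn_in,thin,seed,store_effects chain plan, see
#'   [run_config()].
#' @param prior a [prior_spec()].
#' @param verbose print sampler progress.
#' @return object of class `mtme_fit` with components `chain`
#'   (the [run_gibbs()] output), `model` (the assembled model), `spec`,
#'   `config` and `call`. Methods: `print`, `summary`, `coef`, `fitted`,
#'   `residuals`, `plot`, `simulate`.
#' @examples
#' sc <- default_rice_scenario()
#' ph <- simulate_phenotypes(sc$design, sc$truth, seed = 42)
#' fit <- mtme(ph, model = "full", n_iter = 2000, burn_in = 500, thin = 5,
#'             seed = 42)
#' coef(fit)
#' @export
mtme <- function(data, traits = NULL, model = c("full", "null"),
                 n_iter = 20000L, burn_in = 5000L, thin = 10L, seed = 1L,
                 prior = prior_spec(), store_effects = FALSE,
                 verbose = FALSE) {
  model <- match.arg(model)
  if (is.character(data) && length(data) == 1L) {
    data <- read_phenotypes(data)
  }
  tab <- phenotype_table(data)
  if (is.null(traits)) traits <- sort(unique(tab$trait))
  spec <- build_model_spec(model, traits)
  am <- assemble(tab, spec)
  config <- run_config(n_iter = n_iter, burn_in = burn_in, thin = thin,
                       seed = seed, store_effects = store_effects,
                       prior = prior)
  chain <- run_gibbs(am, config, verbose = verbose)
  structure(list(chain = chain, model = am, spec = spec, config = config,
                 call = match.call()),
            class = "mtme_fit")
}

#' @export
print.mtme_fit <- function(x, ...) {
  cat("Bayesian MTME mixed model (", x$spec$variant, " variant)\n", sep = "")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  d <- x$model$dims
  cat(d$G, "genotypes x", d$E, "environments,",
      paste(d$B_e, collapse = "/"), "blocks,",
      d$T, if (d$T == 1L) "trait:" else "traits:",
      paste(x$model$labels$traits, collapse = ", "), "\n")
  cat("Chain:", x$chain$n_retained, "retained samples ( n_iter =",
      x$config$n_iter, ", burn_in =", x$config$burn_in, ", thin =",
      x$config$thin, ")\n")
  ic <- dic(x)
  cat(sprintf("DIC = %.2f (pD = %.1f)\n", ic$DIC, ic$pD))
  cat("\nPosterior-mean cell means (beta):\n")
  print(round(x$chain$post_mean$beta, 3))
  invisible(x)
}

#' @export
coef.mtme_fit <- function(object, ...) object$chain$post_mean$beta

#' @export
fitted.mtme_fit <- function(object, ...) {
  pm <- object$chain$post_mean
  m <- object$model
  fit <- pm$beta[m$env_idx, , drop = FALSE] +
    pm$block[m$blk_idx, , drop = FALSE]
  if (!is.null(pm$genotype)) fit <- fit + pm$genotype[m$geno_idx, ,
                                                      drop = FALSE]
  if (!is.null(pm$gxe)) fit <- fit + pm$gxe[m$ge_idx, , drop = FALSE]
  dimnames(fit) <- list(NULL, m$labels$traits)
  fit
}

#' @export
residuals.mtme_fit <- function(object, ...) {
  object$model$Y - fitted(object)
}

#' @export
summary.mtme_fit <- function(object, prob = 0.95, ...) {
  out <- list(parameters = summary_table(object, prob = prob),
              dic = dic(object),
              convergence = convergence_report(object),
              spec = object$spec, dims = object$model$dims,
              call = object$call)
  class(out) <- "summary.mtme_fit"
  out
}

#' @export
print.summary.mtme_fit <- function(x, digits = 4, ...) {
  cat("Bayesian MTME mixed model (", x$spec$variant, " variant)\n", sep = "")
  cat("Call: ", deparse(x$call), "\n\n", sep = "")
  tabl <- x$parameters
  tabl[-1L] <- lapply(tabl[-1L], signif, digits = digits)
  print(tabl, row.names = FALSE)
  cat(sprintf("\nDIC = %.2f (pD = %.1f)\n", x$dic$DIC, x$dic$pD))
  nflag <- sum(x$convergence$flag)
  if (nflag > 0L) {
    cat("Convergence: ", nflag, " parameter(s) with Geweke |z| > 1.96\n",
        sep = "")
  } else {
    cat("Convergence: all monitored parameters pass the Geweke criterion\n")
  }
  invisible(x)
}

#' Geweke convergence report for every monitored scalar
#'
#' @param object an `mtme_fit` or `mtme_chain`.
#' @return data.frame with columns `parameter`, `z`, `ess`, `flag`
#'   (`TRUE` when |z| > 1.96).
#' @export
convergence_report <- function(object) {
  chain <- .as_chain(object)
  scalars <- monitored_scalars(chain)
  z <- vapply(scalars, function(x) {
    tryCatch(geweke_z(x), error = function(e) NA_real_)
  }, numeric(1))
  ess <- vapply(scalars, function(x) {
    tryCatch(effective_size(x), error = function(e) NA_real_)
  }, numeric(1))
  data.frame(parameter = names(scalars), z = z, ess = ess,
             flag = !is.na(z) & abs(z) > 1.96,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Named list of monitored scalar chains
#'
#' Fixed-effect cell means plus the diagonal (and, for multi-trait fits,
#' off-diagonal) entries of every covariance term.
#'
#' @param object an `mtme_fit` or `mtme_chain`.
#' @return named list of numeric vectors.
#' @export
monitored_scalars <- function(object) {
  chain <- .as_chain(object)
  traits <- chain$labels$traits
  envs <- chain$labels$environments
  out <- list()
  for (cn in colnames(chain$beta)) out[[paste0("beta[", cn, "]")]] <-
      chain$beta[, cn]
  add_cov <- function(a, tag) {
    for (i in seq_along(traits)) {
      for (j in seq_along(traits)) {
        if (i <= j) {
          nm <- if (i == j) paste0(tag, "[", traits[i], "]")
                else paste0(tag, "[", traits[i], ",", traits[j], "]")
          out[[nm]] <<- a[, i, j]
        }
      }
    }
  }
  if (!is.null(chain$cov$genotype)) add_cov(chain$cov$genotype, "Sigma_g")
  for (e in envs) {
    if (!is.null(chain$cov$gxe)) add_cov(chain$cov$gxe[[e]],
                                         paste0("Sigma_int.", e))
    if (!is.null(chain$cov$block)) add_cov(chain$cov$block[[e]],
                                           paste0("Sigma_r.", e))
    add_cov(chain$cov$residual[[e]], paste0("Sigma_e.", e))
  }
  out
}

#' Trace and density plots for a fitted model
#'
#' @param x an `mtme_fit`.
#' @param parameters names among [monitored_scalars()]; default the first
#'   four.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mtme_fit <- function(x, parameters = NULL, ...) {
  scalars <- monitored_scalars(x)
  if (is.null(parameters)) parameters <- names(scalars)[
    seq_len(min(4L, length(scalars)))]
  bad <- setdiff(parameters, names(scalars))
  if (length(bad)) stop("unknown parameter(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  op <- graphics::par(mfrow = c(length(parameters), 2L),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (p in parameters) {
    v <- scalars[[p]]
    graphics::plot(v, type = "l", xlab = "retained iteration", ylab = p,
                   main = paste("trace:", p), ...)
    if (stats::var(v) > 0) {
      graphics::plot(stats::density(v), main = paste("density:", p),
                     xlab = p)
    } else {
      graphics::plot.new()
    }
  }
  invisible(x)
}

#' Posterior-predictive simulation from a fitted model
#'
#' For each replicate, draws one retained iteration at random and simulates a
#' complete phenotype table from that iteration's cell means and covariance
#' components via [simulate_phenotypes()].
#'
#' @param object an `mtme_fit`.
#' @param nsim number of simulated tables.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of `nsim` phenotype tables.
#' @export
simulate.mtme_fit <- function(object, nsim = 1, seed = 1L, ...) {
  chain <- object$chain
  d <- object$model$dims
  if (is.null(chain$cov$genotype) || is.null(chain$cov$block)) {
    stop("posterior-predictive simulation requires genotype and block terms",
         call. = FALSE)
  }
  design <- trial_design(d$G, chain$labels$environments,
                         max(d$B_e), chain$labels$traits)
  set.seed(as.integer(seed))
  picks <- sample.int(chain$n_retained, nsim, replace = TRUE)
  draw_seeds <- sample.int(.Machine$integer.max, nsim)
  envs <- chain$labels$environments
  lapply(seq_len(nsim), function(k) {
    s <- picks[k]
    beta <- matrix(chain$beta[s, ], d$E, d$T, byrow = TRUE,
                   dimnames = list(envs, chain$labels$traits))
    grab <- function(lst) {
      out <- lapply(envs, function(e) lst[[e]][s, , , drop = FALSE][1L, , ,
                                                                    drop = TRUE])
      out <- lapply(out, function(m) {
        if (!is.matrix(m)) m <- matrix(m, d$T, d$T)
        m
      })
      names(out) <- envs
      out
    }
    truth <- generative_truth(
      design, beta,
      sigma_g = matrix(chain$cov$genotype[s, , ], d$T, d$T),
      sigma_int = if (!is.null(chain$cov$gxe)) grab(chain$cov$gxe)
                  else matrix(0, d$T, d$T),
      sigma_r = grab(chain$cov$block),
      sigma_e = grab(chain$cov$residual))
    simulate_phenotypes(design, truth, seed = draw_seeds[k])
  })
}
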