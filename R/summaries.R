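# Posterior summaries of genetic parameters and model comparison.

.as_chain <- function(object) {
  if (inherits(object, "mtme_fit")) return(object$chain)
  if (inherits(object, "mtme_chain")) return(object)
  stop("expected an `mtme_fit` or `mtme_chain` object", call. = FALSE)
}

.trait_index <- function(chain, trait) {
  i <- match(trait, chain$labels$traits)
  if (is.na(i)) {
    stop("unknown trait '", trait, "'; available: ",
         paste(chain$labels$traits, collapse = ", "), call. = FALSE)
  }
  i
}

.env_index <- function(chain, environment) {
  i <- match(environment, chain$labels$environments)
  if (is.na(i)) {
    stop("unknown environment '", environment, "'; available: ",
         paste(chain$labels$environments, collapse = ", "), call. = FALSE)
  }
  i
}

# per-iteration genetic variance samples for (trait pair, environment):
# main-effect component plus, under the full model, the interaction component
.genetic_cov_samples <- function(chain, i, j, ei) {
  if (is.null(chain$cov$genotype)) {
    stop("the fitted model has no genotype term", call. = FALSE)
  }
  out <- chain$cov$genotype[, i, j]
  if (!is.null(chain$cov$gxe)) out <- out + chain$cov$gxe[[ei]][, i, j]
  out
}

#' Posterior samples of broad-sense heritability
#'
#' Per retained iteration,
#' \deqn{h^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_r + \sigma^2_\varepsilon)}
#' where \eqn{\sigma^2_g} is the genetic variance of the trait in the given
#' environment (genotype main-effect variance plus, under the full model, the
#' interaction variance), \eqn{\sigma^2_r} the block (replication) variance
#' and \eqn{\sigma^2_\varepsilon} the residual variance. Every sample lies in
#' [0, 1].
#'
#' @param object an `mtme_fit` or `mtme_chain`.
#' @param trait,environment labels identifying the margin.
#' @return numeric vector of posterior samples.
#' @export
heritability_samples <- function(object, trait, environment) {
  chain <- .as_chain(object)
  i <- .trait_index(chain, trait)
  ei <- .env_index(chain, environment)
  sg <- .genetic_cov_samples(chain, i, i, ei)
  sr <- if (!is.null(chain$cov$block)) chain$cov$block[[ei]][, i, i] else 0
  se <- chain$cov$residual[[ei]][, i, i]
  sg / (sg + sr + se)
}

#' Posterior samples of the genetic correlation between two traits
#'
#' Per retained iteration, the correlation implied by the genetic covariance
#' matrix for the environment (main effect plus interaction under the full
#' model). Iterations with a zero genetic variance for either trait are
#' excluded; their count is attached as attribute `"n_excluded"`.
#'
#' @param object an `mtme_fit` or `mtme_chain`.
#' @param trait_a,trait_b distinct trait labels.
#' @param environment environment label.
#' @return numeric vector of posterior correlation samples in [-1, 1].
#' @export
genetic_correlation_samples <- function(object, trait_a, trait_b,
                                        environment) {
  chain <- .as_chain(object)
  i <- .trait_index(chain, trait_a)
  j <- .trait_index(chain, trait_b)
  if (i == j) stop("`trait_a` and `trait_b` must differ", call. = FALSE)
  ei <- .env_index(chain, environment)
  vi <- .genetic_cov_samples(chain, i, i, ei)
  vj <- .genetic_cov_samples(chain, j, j, ei)
  cij <- .genetic_cov_samples(chain, i, j, ei)
  ok <- vi > 0 & vj > 0
  rho <- cij[ok] / sqrt(vi[ok] * vj[ok])
  rho <- pmin(1, pmax(-1, rho))
  attr(rho, "n_excluded") <- sum(!ok)
  rho
}

#' Genotypic and residual coefficients of variation
#'
#' Point (Table-style) coefficients computed from posterior means of the
#' variance components:
#' \eqn{CV_g = 100 \sqrt{\bar\sigma^2_g} / \bar y},
#' \eqn{CV_e = 100 \sqrt{\bar\sigma^2_\varepsilon} / \bar y}, with \eqn{\bar
#' y} the arithmetic mean of the observed values for the trait x environment.
#' Their ratio is the relative variation index: values above 1 indicate that
#' genetic variation dominates residual variation. A per-iteration chain of
#' the ratio is attached as attribute `"ratio_samples"`.
#'
#' @param object an `mtme_fit` or `mtme_chain`.
#' @param trait,environment labels identifying the margin.
#' @param table phenotype table supplying the mean; defaults to the table the
#'   model was fitted to (available when `object` is an `mtme_fit`).
#' @return list with `cv_g`, `cv_e` (percent) and `ratio`.
#' @export
coefficient_of_variation <- function(object, trait, environment,
                                     table = NULL) {
  chain <- .as_chain(object)
  if (is.null(table)) {
    if (!inherits(object, "mtme_fit")) {
      stop("`table` is required when summarizing a bare chain", call. = FALSE)
    }
    table <- object$model$table
  }
  tab <- phenotype_table(table)
  i <- .trait_index(chain, trait)
  ei <- .env_index(chain, environment)
  sel <- tab$trait == trait & tab$environment == environment
  if (!any(sel)) {
    stop("no observations for trait '", trait, "' in environment '",
         environment, "'", call. = FALSE)
  }
  mu <- mean(tab$value[sel])
  if (mu == 0) stop("phenotype mean is zero; CV undefined", call. = FALSE)
  sg <- .genetic_cov_samples(chain, i, i, ei)
  se <- chain$cov$residual[[ei]][, i, i]
  cv_g <- 100 * sqrt(mean(sg)) / abs(mu)
  cv_e <- 100 * sqrt(mean(se)) / abs(mu)
  out <- list(cv_g = cv_g, cv_e = cv_e,
              ratio = relative_variation_index(cv_g, cv_e))
  attr(out, "ratio_samples") <- sqrt(sg) / sqrt(se)
  out
}

#' Relative variation index
#'
#' The ratio of the genotypic to the residual coefficient of variation,
#' `CVg / CVe`. Values above 1 indicate that genetic variation outweighs
#' residual variation for the trait.
#'
#' @param cv_g,cv_e coefficients of variation (percent), `cv_e` nonzero.
#' @return `cv_g / cv_e`.
#' @export
relative_variation_index <- function(cv_g, cv_e) {
  if (any(cv_e == 0)) stop("`cv_e` must be nonzero", call. = FALSE)
  if (any(cv_g < 0) || any(cv_e < 0)) {
    stop("coefficients of variation must be non-negative", call. = FALSE)
  }
  cv_g / cv_e
}

#' Deviance information criterion of a fit
#'
#' `pD = mean(D) - D(posterior mean)` and `DIC = D(posterior mean) + 2 pD =
#' mean(D) + pD`, with `D` the conditional deviance given all random effects
#' (recorded during sampling) and the posterior-mean parameters accumulated
#' over the same retained iterations.
#'
#' @param object an `mtme_fit` or `mtme_chain`.
#' @return list with `DIC`, `pD`, `D_bar` (posterior-mean deviance) and
#'   `D_at_mean`.
#' @export
dic <- function(object) {
  chain <- .as_chain(object)
  if (is.null(chain$deviance) || !length(chain$deviance)) {
    stop("no deviance track stored in the chain", call. = FALSE)
  }
  d_bar <- mean(chain$deviance)
  p_d <- d_bar - chain$dev_at_mean
  list(DIC = d_bar + p_d, pD = p_d, D_bar = d_bar,
       D_at_mean = chain$dev_at_mean)
}

#' Compare full and null model fits by DIC
#'
#' Applies the decision rule: the full (interaction) model is preferred when
#' `DIC_null - DIC_full > 2`; the null model when the difference is below
#' -2; otherwise the models are indistinguishable.
#'
#' @param fit_full,fit_null fits of the full and null variants to the same
#'   data and traits.
#' @return object of class `mtme_comparison` with fields `DIC_full`,
#'   `DIC_null`, `pD_full`, `pD_null`, `delta` and `preferred`.
#' @export
compare_models <- function(fit_full, fit_null) {
  cf <- .as_chain(fit_full)
  cn <- .as_chain(fit_null)
  if (!isTRUE(all.equal(cf$fingerprint, cn$fingerprint))) {
    stop("the two fits were not run on the same data and traits",
         call. = FALSE)
  }
  df <- dic(cf)
  dn <- dic(cn)
  delta <- dn$DIC - df$DIC
  preferred <- if (delta > 2) "full" else if (delta < -2) "null"
               else "indistinguishable"
  structure(list(DIC_full = df$DIC, DIC_null = dn$DIC,
                 pD_full = df$pD, pD_null = dn$pD,
                 delta = delta, preferred = preferred),
            class = "mtme_comparison")
}

#' @export
print.mtme_comparison <- function(x, ...) {
  cat("Model comparison by DIC (lower is preferred)\n")
  cat(sprintf("  full model: DIC = %.2f (pD = %.1f)\n", x$DIC_full, x$pD_full))
  cat(sprintf("  null model: DIC = %.2f (pD = %.1f)\n", x$DIC_null, x$pD_null))
  cat(sprintf("  delta (null - full) = %.2f -> %s\n", x$delta,
              switch(x$preferred,
                     full = "full model preferred (delta > 2)",
                     null = "null model preferred (delta < -2)",
                     "models indistinguishable (|delta| <= 2)")))
  invisible(x)
}

#' Genotype ranking by posterior-mean genetic value
#'
#' The genetic value of a genotype in an environment is its main effect plus
#' (under the full model) its interaction deviation for that environment.
#' Requires effect samples (`store_effects = TRUE` in the run
#' configuration).
#'
#' @param object an `mtme_fit` or `mtme_chain`.
#' @param environment,trait labels identifying the margin.
#' @param prob mass of the reported HPD interval.
#' @return data.frame with columns `genotype`, `value` (posterior mean),
#'   `lower`, `upper`, `rank`, sorted by decreasing value (ties broken by
#'   genotype label).
#' @export
genotype_values <- function(object, environment, trait, prob = 0.95) {
  chain <- .as_chain(object)
  if (is.null(chain$effects)) {
    stop("effect samples were not stored; re-run the fit with ",
         "store_effects = TRUE", call. = FALSE)
  }
  i <- .trait_index(chain, trait)
  ei <- .env_index(chain, environment)
  gv <- chain$effects$genotype[, , i, drop = FALSE][, , 1L]
  if (!is.null(chain$effects$gxe)) {
    gv <- gv + chain$effects$gxe[[ei]][, , i, drop = FALSE][, , 1L]
  }
  means <- colMeans(gv)
  hpd <- apply(gv, 2L, hpd_interval, prob = prob)
  out <- data.frame(genotype = chain$labels$genotypes,
                    value = means, lower = hpd["lower", ],
                    upper = hpd["upper", ], stringsAsFactors = FALSE)
  out <- out[order(-out$value, out$genotype), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

.summ_row <- function(parameter, x, prob = 0.95) {
  hpd <- hpd_interval(x, prob)
  data.frame(parameter = parameter, mean = mean(x),
             median = stats::median(x), mode = posterior_mode(x),
             lower = hpd[["lower"]], upper = hpd[["upper"]],
             stringsAsFactors = FALSE)
}

#' Posterior summary table
#'
#' One row per fixed-effect cell mean, variance component (diagonal of every
#' covariance term), broad-sense heritability, and between-trait genetic
#' correlation, each with posterior mean, median, mode, and 95% HPD bounds.
#'
#' @param object an `mtme_fit` or `mtme_chain`.
#' @param prob mass of the HPD intervals.
#' @return data.frame of class `mtme_summary_table`.
#' @export
summary_table <- function(object, prob = 0.95) {
  chain <- .as_chain(object)
  if (chain$n_retained < 100L) {
    stop("at least 100 retained samples are required for posterior summaries",
         call. = FALSE)
  }
  traits <- chain$labels$traits
  envs <- chain$labels$environments
  rows <- list()
  for (cn in colnames(chain$beta)) {
    rows[[length(rows) + 1L]] <- .summ_row(paste0("beta[", cn, "]"),
                                           chain$beta[, cn], prob)
  }
  for (i in seq_along(traits)) {
    if (!is.null(chain$cov$genotype)) {
      rows[[length(rows) + 1L]] <- .summ_row(
        paste0("sigma2_g[", traits[i], "]"), chain$cov$genotype[, i, i], prob)
    }
    for (ei in seq_along(envs)) {
      if (!is.null(chain$cov$gxe)) {
        rows[[length(rows) + 1L]] <- .summ_row(
          paste0("sigma2_int[", envs[ei], ":", traits[i], "]"),
          chain$cov$gxe[[ei]][, i, i], prob)
      }
      if (!is.null(chain$cov$block)) {
        rows[[length(rows) + 1L]] <- .summ_row(
          paste0("sigma2_r[", envs[ei], ":", traits[i], "]"),
          chain$cov$block[[ei]][, i, i], prob)
      }
      rows[[length(rows) + 1L]] <- .summ_row(
        paste0("sigma2_e[", envs[ei], ":", traits[i], "]"),
        chain$cov$residual[[ei]][, i, i], prob)
    }
  }
  if (!is.null(chain$cov$genotype) && !is.null(chain$cov$block)) {
    for (tr in traits) {
      for (e in envs) {
        rows[[length(rows) + 1L]] <- .summ_row(
          paste0("h2[", e, ":", tr, "]"),
          heritability_samples(chain, tr, e), prob)
      }
    }
  }
  if (length(traits) > 1L && !is.null(chain$cov$genotype)) {
    for (i in seq_along(traits)) {
      for (j in seq_along(traits)) {
        if (i < j) {
          for (e in envs) {
            rho <- genetic_correlation_samples(chain, traits[i], traits[j], e)
            rows[[length(rows) + 1L]] <- .summ_row(
              paste0("rho_g[", e, ":", traits[i], ",", traits[j], "]"),
              as.numeric(rho), prob)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mtme_summary_table", "data.frame")
  out
}
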