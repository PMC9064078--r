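# Gibbs sampler for the assembled MTME model.
#
# All updates exploit the balanced design: within a random term every level
# shares the same conditional precision, so a whole term is sampled with a
# handful of matrix operations instead of a loop over levels.

# inverse-Wishart draw: X ~ IW(df, S) <=> X^-1 ~ Wishart(df, S^-1)
.riwish <- function(df, S) {
  Sinv <- chol2inv(chol((S + t(S)) / 2))
  W <- stats::rWishart(1L, df, (Sinv + t(Sinv)) / 2)[, , 1L]
  X <- chol2inv(chol(W))
  (X + t(X)) / 2
}

.chol_safe <- function(M, what, it) {
  out <- tryCatch(chol((M + t(M)) / 2), error = function(e) NULL)
  if (is.null(out)) {
    stop("conditional precision for ", what,
         " is numerically non-positive-definite at iteration ", it,
         call. = FALSE)
  }
  out
}

# resolve one prior entry to the standardized scale
.resolve_prior <- function(prior, term, Tt, s, varphen_std) {
  nu0 <- prior$nu0[[term]]
  if (is.null(nu0)) nu0 <- Tt + 1
  if (!is.numeric(nu0) || length(nu0) != 1L || nu0 <= Tt - 1) {
    stop("prior degrees of freedom for '", term, "' must exceed T - 1 = ",
         Tt - 1, call. = FALSE)
  }
  V0 <- prior$V0[[term]]
  if (is.null(V0)) {
    V0s <- diag(varphen_std / 2, Tt)
  } else {
    if (is.numeric(V0) && length(V0) == 1L) V0 <- diag(V0, Tt)
    V0 <- as.matrix(V0)
    if (nrow(V0) != Tt || ncol(V0) != Tt) {
      stop("prior scale matrix for '", term, "' must be ", Tt, "x", Tt,
           call. = FALSE)
    }
    V0s <- V0 / outer(s, s)
  }
  ev <- .min_eigen(V0s)
  if (ev <= 0) {
    stop("prior scale matrix for '", term, "' is not positive definite",
         call. = FALSE)
  }
  list(nu0 = nu0, V0 = (V0s + t(V0s)) / 2)
}

#' Run the Gibbs sampler on an assembled model
#'
#' One systematic-scan sweep per iteration: (1) fixed-effect cell means given
#' everything else (Gaussian); (2) each random term's level effects
#' (Gaussian, all levels jointly by balance); (3) each term covariance
#' (inverse-Wishart with its prior plus the cross-product of current level
#' effects); (4) per-environment residual covariance (inverse-Wishart from
#' per-plot residual vectors). The conditional deviance (-2 log Gaussian
#' likelihood given all effects) is recorded at every retained iteration.
#'
#' Each trait is standardized to unit variance internally for numerical
#' conditioning; all stored samples, the deviance, and the posterior means
#' are back-transformed to the original trait scale.
#'
#' @param model an [assemble()]d model.
#' @param config a [run_config()]; its `prior` field supplies the
#'   [prior_spec()].
#' @param fixed_residual optionally hold the residual covariance fixed
#'   (scalar, T x T matrix, or per-environment named list, original scale) —
#'   used for closed-form benchmark checks.
#' @param verbose print progress every 5000 iterations.
#' @return object of class `mtme_chain` carrying the retained samples
#'   (`beta`, `cov$genotype`, `cov$block`, `cov$gxe`, `cov$residual`,
#'   `deviance`), optional effect samples, the deviance at the posterior
#'   mean, posterior means of all parameters, and metadata.
#' @export
run_gibbs <- function(model, config = run_config(), fixed_residual = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(model, "mtme_model"), inherits(config, "mtme_config"))
  spec <- model$spec
  d <- model$dims
  Tt <- d$T; E <- d$E; G <- d$G
  envs <- model$labels$environments
  traits <- model$labels$traits
  B_e <- d$B_e
  n_e <- d$n_plots_e
  rows_e <- model$rows_e
  has <- list(block = "block" %in% spec$terms,
              genotype = "genotype" %in% spec$terms,
              gxe = "gxe" %in% spec$terms)

  # standardization
  s <- apply(model$Y, 2, stats::sd)
  s[!is.finite(s) | s <= 0] <- 1
  Ys <- sweep(model$Y, 2, s, "/")
  # default prior scale: empirical phenotypic variance in the quantitative-
  # genetics sense — pooled within environment (cell means removed), so that
  # fixed-effect differences between sites do not inflate the prior
  ctr <- Ys
  for (ei in seq_len(E)) {
    rr <- rows_e[[ei]]
    ctr[rr, ] <- sweep(Ys[rr, , drop = FALSE], 2,
                       colMeans(Ys[rr, , drop = FALSE]))
  }
  varphen_std <- colSums(ctr^2) / max(d$n_plots - E, 1)
  varphen_std[!is.finite(varphen_std) | varphen_std <= 0] <- 1
  ss <- outer(s, s)
  dev_offset <- 2 * d$n_plots * sum(log(s))

  prior <- config$prior
  pr_blk <- if (has$block) .resolve_prior(prior, "block", Tt, s, varphen_std)
  pr_g   <- if (has$genotype) .resolve_prior(prior, "genotype", Tt, s,
                                             varphen_std)
  pr_u   <- if (has$gxe) .resolve_prior(prior, "gxe", Tt, s, varphen_std)
  pr_e   <- .resolve_prior(prior, "residual", Tt, s, varphen_std)
  vb_inv <- 1 / prior$beta_var

  res_fixed <- !is.null(fixed_residual)
  if (res_fixed) {
    fr <- .per_env(fixed_residual, envs, "fixed_residual", Tt)
    Se <- lapply(envs, function(e) .check_cov(fr[[e]] / ss,
                                              "fixed_residual", Tt,
                                              strict = TRUE))
  } else {
    Se <- rep(list(pr_e$V0), E)
  }
  names(Se) <- envs
  Seinv <- lapply(Se, function(m) chol2inv(chol(m)))

  # state
  beta <- do.call(rbind, lapply(seq_len(E), function(ei) {
    colMeans(Ys[rows_e[[ei]], , drop = FALSE])
  }))
  nB <- sum(B_e)
  r_all <- matrix(0, nB, Tt)
  g <- matrix(0, G, Tt)
  u_all <- matrix(0, G * E, Tt)
  Sr <- if (has$block) rep(list(pr_blk$V0), E)
  Su <- if (has$gxe) rep(list(pr_u$V0), E)
  Sg <- if (has$genotype) pr_g$V0
  Srinv <- if (has$block) lapply(Sr, function(m) chol2inv(chol(m)))
  Suinv <- if (has$gxe) lapply(Su, function(m) chol2inv(chol(m)))
  Sginv <- if (has$genotype) chol2inv(chol(Sg))

  env_idx <- model$env_idx; blk_idx <- model$blk_idx
  geno_idx <- model$geno_idx; ge_idx <- model$ge_idx
  geno_e <- lapply(rows_e, function(rr) geno_idx[rr])
  blk_loc_e <- lapply(rows_e, function(rr) model$blk_local[rr])
  blk_off <- c(0L, cumsum(B_e))
  ge_off <- (seq_len(E) - 1L) * G

  S_keep <- config$n_retained
  beta_s <- matrix(NA_real_, S_keep, E * Tt,
                   dimnames = list(NULL, colnames(model$X)))
  dev_s <- numeric(S_keep)
  arr <- function() array(NA_real_, c(S_keep, Tt, Tt),
                          dimnames = list(NULL, traits, traits))
  cov_g_s <- if (has$genotype) arr()
  cov_r_s <- if (has$block) stats::setNames(lapply(envs, function(e) arr()),
                                            envs)
  cov_u_s <- if (has$gxe) stats::setNames(lapply(envs, function(e) arr()),
                                          envs)
  cov_e_s <- stats::setNames(lapply(envs, function(e) arr()), envs)
  iters <- integer(S_keep)
  store_eff <- config$store_effects
  eff_g_s <- if (store_eff && has$genotype) {
    array(NA_real_, c(S_keep, G, Tt),
          dimnames = list(NULL, model$labels$genotypes, traits))
  }
  eff_u_s <- if (store_eff && has$gxe) {
    stats::setNames(lapply(envs, function(e) {
      array(NA_real_, c(S_keep, G, Tt),
            dimnames = list(NULL, model$labels$genotypes, traits))
    }), envs)
  }

  acc_beta <- beta * 0; acc_r <- r_all * 0; acc_g <- g * 0
  acc_u <- u_all * 0
  acc_Se <- lapply(Se, function(m) m * 0)

  set.seed(config$seed)
  log2pi <- log(2 * pi)
  ridx <- 0L

  beta_pl <- beta[env_idx, , drop = FALSE]
  r_pl <- r_all[blk_idx, , drop = FALSE]
  g_pl <- g[geno_idx, , drop = FALSE]
  u_pl <- u_all[ge_idx, , drop = FALSE]

  for (it in seq_len(config$n_iter)) {
    ## (1) fixed-effect cell means
    dmat <- Ys - r_pl - g_pl - u_pl
    for (ei in seq_len(E)) {
      b <- Seinv[[ei]] %*% colSums(dmat[rows_e[[ei]], , drop = FALSE])
      P <- n_e[ei] * Seinv[[ei]] + diag(vb_inv, Tt)
      Uc <- .chol_safe(P, "beta", it)
      m <- backsolve(Uc, forwardsolve(t(Uc), b))
      beta[ei, ] <- m + backsolve(Uc, stats::rnorm(Tt))
    }
    beta_pl <- beta[env_idx, , drop = FALSE]

    ## (2) random-term effects
    if (has$block) {
      dmat <- Ys - beta_pl - g_pl - u_pl
      for (ei in seq_len(E)) {
        de <- dmat[rows_e[[ei]], , drop = FALSE]
        Smat <- rowsum(de %*% Seinv[[ei]], blk_loc_e[[ei]])
        P <- G * Seinv[[ei]] + Srinv[[ei]]
        Uc <- .chol_safe(P, "block effects", it)
        V <- chol2inv(Uc)
        means <- Smat %*% V
        r_all[(blk_off[ei] + 1L):blk_off[ei + 1L], ] <-
          means + matrix(stats::rnorm(B_e[ei] * Tt), B_e[ei], Tt) %*% chol(V)
      }
      r_pl <- r_all[blk_idx, , drop = FALSE]
    }
    if (has$genotype) {
      dmat <- Ys - beta_pl - r_pl - u_pl
      Smat <- matrix(0, G, Tt)
      P <- Sginv
      for (ei in seq_len(E)) {
        de <- dmat[rows_e[[ei]], , drop = FALSE]
        Smat <- Smat + rowsum(de %*% Seinv[[ei]], geno_e[[ei]])
        P <- P + B_e[ei] * Seinv[[ei]]
      }
      Uc <- .chol_safe(P, "genotype effects", it)
      V <- chol2inv(Uc)
      g <- Smat %*% V + matrix(stats::rnorm(G * Tt), G, Tt) %*% chol(V)
      g_pl <- g[geno_idx, , drop = FALSE]
    }
    if (has$gxe) {
      dmat <- Ys - beta_pl - r_pl - g_pl
      for (ei in seq_len(E)) {
        de <- dmat[rows_e[[ei]], , drop = FALSE]
        Smat <- rowsum(de %*% Seinv[[ei]], geno_e[[ei]])
        P <- B_e[ei] * Seinv[[ei]] + Suinv[[ei]]
        Uc <- .chol_safe(P, "interaction effects", it)
        V <- chol2inv(Uc)
        u_all[ge_off[ei] + seq_len(G), ] <-
          Smat %*% V + matrix(stats::rnorm(G * Tt), G, Tt) %*% chol(V)
      }
      u_pl <- u_all[ge_idx, , drop = FALSE]
    }

    ## (3) term covariances
    if (has$block) {
      for (ei in seq_len(E)) {
        re <- r_all[(blk_off[ei] + 1L):blk_off[ei + 1L], , drop = FALSE]
        Sr[[ei]] <- .riwish(pr_blk$nu0 + B_e[ei], pr_blk$V0 + crossprod(re))
        Srinv[[ei]] <- chol2inv(chol(Sr[[ei]]))
      }
    }
    if (has$genotype) {
      Sg <- .riwish(pr_g$nu0 + G, pr_g$V0 + crossprod(g))
      Sginv <- chol2inv(chol(Sg))
    }
    if (has$gxe) {
      for (ei in seq_len(E)) {
        ue <- u_all[ge_off[ei] + seq_len(G), , drop = FALSE]
        Su[[ei]] <- .riwish(pr_u$nu0 + G, pr_u$V0 + crossprod(ue))
        Suinv[[ei]] <- chol2inv(chol(Su[[ei]]))
      }
    }

    ## (4) residual covariance per environment
    Eres <- Ys - beta_pl - r_pl - g_pl - u_pl
    if (!res_fixed) {
      for (ei in seq_len(E)) {
        Ee <- Eres[rows_e[[ei]], , drop = FALSE]
        Se[[ei]] <- .riwish(pr_e$nu0 + n_e[ei], pr_e$V0 + crossprod(Ee))
        Seinv[[ei]] <- chol2inv(chol(Se[[ei]]))
      }
    }

    ## store
    keep <- it > config$burn_in &&
      (it - config$burn_in) %% config$thin == 0L
    if (keep) {
      ridx <- ridx + 1L
      iters[ridx] <- it
      beta_s[ridx, ] <- as.vector(t(beta * matrix(s, E, Tt, byrow = TRUE)))
      Dv <- 0
      for (ei in seq_len(E)) {
        Ee <- Eres[rows_e[[ei]], , drop = FALSE]
        ld <- as.numeric(determinant(Se[[ei]], logarithm = TRUE)$modulus)
        Dv <- Dv + n_e[ei] * (Tt * log2pi + ld) +
          sum((Ee %*% Seinv[[ei]]) * Ee)
      }
      dev_s[ridx] <- Dv + dev_offset
      if (has$genotype) cov_g_s[ridx, , ] <- Sg * ss
      for (ei in seq_len(E)) {
        if (has$block) cov_r_s[[ei]][ridx, , ] <- Sr[[ei]] * ss
        if (has$gxe) cov_u_s[[ei]][ridx, , ] <- Su[[ei]] * ss
        cov_e_s[[ei]][ridx, , ] <- Se[[ei]] * ss
      }
      if (store_eff && has$genotype) {
        eff_g_s[ridx, , ] <- g * matrix(s, G, Tt, byrow = TRUE)
      }
      if (store_eff && has$gxe) {
        for (ei in seq_len(E)) {
          eff_u_s[[ei]][ridx, , ] <- u_all[ge_off[ei] + seq_len(G), ,
                                           drop = FALSE] *
            matrix(s, G, Tt, byrow = TRUE)
        }
      }
      acc_beta <- acc_beta + beta; acc_r <- acc_r + r_all
      acc_g <- acc_g + g; acc_u <- acc_u + u_all
      for (ei in seq_len(E)) acc_Se[[ei]] <- acc_Se[[ei]] + Se[[ei]]
    }
    if (verbose && it %% 5000L == 0L) {
      message("iteration ", it, "/", config$n_iter)
    }
  }

  ## deviance at the posterior mean of (beta, effects, residual covariance)
  mb <- acc_beta / S_keep; mr <- acc_r / S_keep
  mg <- acc_g / S_keep; mu <- acc_u / S_keep
  mSe <- lapply(acc_Se, function(m) m / S_keep)
  Em <- Ys - mb[env_idx, , drop = FALSE] - mr[blk_idx, , drop = FALSE] -
    mg[geno_idx, , drop = FALSE] - mu[ge_idx, , drop = FALSE]
  Dm <- 0
  for (ei in seq_len(E)) {
    Ee <- Em[rows_e[[ei]], , drop = FALSE]
    ld <- as.numeric(determinant(mSe[[ei]], logarithm = TRUE)$modulus)
    Dm <- Dm + n_e[ei] * (Tt * log2pi + ld) +
      sum((Ee %*% chol2inv(chol(mSe[[ei]]))) * Ee)
  }
  Dm <- as.numeric(Dm + dev_offset)

  smatG <- matrix(s, G, Tt, byrow = TRUE)
  post_mean <- list(
    beta = mb * matrix(s, E, Tt, byrow = TRUE),
    block = mr * matrix(s, nB, Tt, byrow = TRUE),
    genotype = if (has$genotype) mg * smatG,
    gxe = if (has$gxe) mu * matrix(s, G * E, Tt, byrow = TRUE),
    residual = lapply(mSe, function(m) m * ss))
  dimnames(post_mean$beta) <- list(envs, traits)
  rownames(post_mean$block) <- model$labels$blocks
  if (has$genotype) rownames(post_mean$genotype) <- model$labels$genotypes
  if (has$gxe) {
    rownames(post_mean$gxe) <- as.vector(outer(model$labels$genotypes, envs,
                                               paste, sep = ":"))
  }

  structure(list(
    beta = beta_s,
    cov = list(genotype = cov_g_s, block = cov_r_s, gxe = cov_u_s,
               residual = cov_e_s),
    deviance = dev_s,
    dev_at_mean = Dm,
    effects = if (store_eff && has$genotype) {
      list(genotype = eff_g_s, gxe = eff_u_s)
    },
    post_mean = post_mean,
    iters = iters,
    n_retained = S_keep,
    labels = model$labels,
    dims = d,
    spec = spec,
    config = config[c("n_iter", "burn_in", "thin", "seed", "store_effects")],
    scale = s,
    fingerprint = model$fingerprint),
    class = "mtme_chain")
}

#' @export
print.mtme_chain <- function(x, ...) {
  cat("MTME posterior chain (", x$spec$variant, " variant): ",
      x$n_retained, " retained samples\n", sep = "")
  cat("  traits:", paste(x$labels$traits, collapse = ", "),
      " environments:", paste(x$labels$environments, collapse = ", "), "\n")
  cat("  mean deviance:", format(mean(x$deviance), digits = 6),
      "  D(posterior mean):", format(x$dev_at_mean, digits = 6), "\n")
  invisible(x)
}

#' Gaussian deviance of a residual matrix
#'
#' Computes \eqn{-2 \sum_i \log N(e_i; 0, \Sigma)} for the rows of a residual
#' matrix — the building block of the conditional deviance used for DIC.
#'
#' @param resid numeric vector or n x T matrix of residuals.
#' @param sigma T x T covariance matrix (scalar for T = 1).
#' @return the deviance contribution (a single number).
#' @export
gaussian_deviance <- function(resid, sigma) {
  if (!is.matrix(resid)) resid <- matrix(resid, ncol = 1L)
  if (is.numeric(sigma) && length(sigma) == 1L) sigma <- matrix(sigma, 1L, 1L)
  Tt <- ncol(resid)
  if (nrow(sigma) != Tt || ncol(sigma) != Tt) {
    stop("`sigma` must be ", Tt, "x", Tt, call. = FALSE)
  }
  Uc <- tryCatch(chol((sigma + t(sigma)) / 2), error = function(e) NULL)
  if (is.null(Uc)) stop("`sigma` is singular or not positive definite",
                        call. = FALSE)
  Sinv <- chol2inv(Uc)
  ld <- 2 * sum(log(diag(Uc)))
  nrow(resid) * (Tt * log(2 * pi) + ld) + sum((resid %*% Sinv) * resid)
}

#' Conditional deviance of a parameter state
#'
#' Evaluates \eqn{-2 \log} of the Gaussian likelihood of the observed
#' responses given fixed-effect cell means, all random-effect values, and the
#' per-environment residual covariances (the conditional likelihood on which
#' the package's DIC is based).
#'
#' @param model an [assemble()]d model.
#' @param state list with `beta` (E x T matrix, original scale), optional
#'   `block` (stacked blocks x T), `genotype` (G x T), `gxe` ((G*E) x T,
#'   genotype-major within environment), and `residual` (T x T matrix or
#'   per-environment list).
#' @return the deviance (a single number).
#' @export
conditional_deviance <- function(model, state) {
  stopifnot(inherits(model, "mtme_model"))
  d <- model$dims
  beta <- as.matrix(state$beta)
  if (nrow(beta) != d$E || ncol(beta) != d$T) {
    stop("state$beta must be ", d$E, "x", d$T, call. = FALSE)
  }
  fit <- beta[model$env_idx, , drop = FALSE]
  if (!is.null(state$block)) {
    fit <- fit + as.matrix(state$block)[model$blk_idx, , drop = FALSE]
  }
  if (!is.null(state$genotype)) {
    fit <- fit + as.matrix(state$genotype)[model$geno_idx, , drop = FALSE]
  }
  if (!is.null(state$gxe)) {
    fit <- fit + as.matrix(state$gxe)[model$ge_idx, , drop = FALSE]
  }
  resid <- model$Y - fit
  res_cov <- state$residual
  if (is.null(res_cov)) stop("state$residual is required", call. = FALSE)
  res_cov <- .per_env(res_cov, model$labels$environments, "residual", d$T)
  Dv <- 0
  for (ei in seq_along(model$labels$environments)) {
    Dv <- Dv + gaussian_deviance(resid[model$rows_e[[ei]], , drop = FALSE],
                                 res_cov[[ei]])
  }
  Dv
}
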