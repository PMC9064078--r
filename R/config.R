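#' Prior specification for the Gibbs sampler
#'
#' Priors are conjugate: every covariance matrix (genotype, block,
#' genotype-by-environment, residual) gets an inverse-Wishart prior
#' IW(`nu0`, `V0`); fixed-effect cell means get independent Gaussian priors
#' with mean 0 and variance `beta_var` on the internally standardized scale
#' (each trait is scaled to unit variance during sampling and results are
#' back-transformed).
#'
#' Defaults are weakly informative and resolved against the data at fit time:
#' `nu0 = T + 1` (T = number of traits modelled by the term) and
#' `V0 = diag(phenotypic variance per trait) / 2` on the original trait scale.
#'
#' @param nu0 `NULL` (default), a single number, or a named list with entries
#'   among `block`, `genotype`, `gxe`, `residual` giving the inverse-Wishart
#'   degrees of freedom (must exceed T - 1).
#' @param V0 `NULL` (default), a scalar, a T x T matrix, or a named list per
#'   term, giving the inverse-Wishart scale matrix on the original trait
#'   scale.
#' @param beta_var prior variance of each standardized fixed-effect cell
#'   mean; large values make the prior effectively flat.
#' @return object of class `mtme_prior`.
#' @export
prior_spec <- function(nu0 = NULL, V0 = NULL, beta_var = 1e8) {
  terms <- c("block", "genotype", "gxe", "residual")
  norm_per_term <- function(x, what) {
    if (is.null(x)) return(stats::setNames(vector("list", 4L), terms))
    if (is.list(x) && !is.null(names(x))) {
      bad <- setdiff(names(x), terms)
      if (length(bad)) {
        stop("unknown prior term(s) in ", what, ": ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      out <- stats::setNames(vector("list", 4L), terms)
      out[names(x)] <- x
      return(out)
    }
    stats::setNames(rep(list(x), 4L), terms)
  }
  if (!is.numeric(beta_var) || length(beta_var) != 1L || beta_var <= 0) {
    stop("`beta_var` must be a positive scalar", call. = FALSE)
  }
  structure(list(nu0 = norm_per_term(nu0, "nu0"),
                 V0  = norm_per_term(V0, "V0"),
                 beta_var = beta_var),
            class = "mtme_prior")
}

#' MCMC run configuration
#'
#' @param n_iter total Gibbs iterations (> 0).
#' @param burn_in iterations discarded before storage (>= 0, < `n_iter`).
#' @param thin keep every `thin`-th post-burn-in iteration (> 0). The number
#'   of retained samples is exactly `floor((n_iter - burn_in) / thin)`.
#' @param seed integer seed; identical seed, data and configuration give
#'   bit-identical chains.
#' @param store_effects keep per-iteration samples of the genotype main and
#'   interaction effects (needed by [genotype_values()]).
#' @param prior an [prior_spec()] object.
#' @return object of class `mtme_config`.
#' @export
run_config <- function(n_iter = 20000L, burn_in = 5000L, thin = 10L,
                       seed = 1L, store_effects = FALSE,
                       prior = prior_spec()) {
  chk_int <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x)) {
      stop("`", nm, "` must be a single integer", call. = FALSE)
    }
    as.integer(x)
  }
  n_iter <- chk_int(n_iter, "n_iter")
  burn_in <- chk_int(burn_in, "burn_in")
  thin <- chk_int(thin, "thin")
  seed <- chk_int(seed, "seed")
  if (n_iter <= 0L) stop("`n_iter` must be positive", call. = FALSE)
  if (burn_in < 0L) stop("`burn_in` must be non-negative", call. = FALSE)
  if (burn_in >= n_iter) {
    stop("`burn_in` (", burn_in, ") must be smaller than `n_iter` (",
         n_iter, ")", call. = FALSE)
  }
  if (thin <= 0L) stop("`thin` must be positive", call. = FALSE)
  if (!inherits(prior, "mtme_prior")) {
    stop("`prior` must be created by prior_spec()", call. = FALSE)
  }
  retained <- (n_iter - burn_in) %/% thin
  if (retained < 1L) {
    stop("configuration retains no samples: floor((n_iter - burn_in)/thin) = 0",
         call. = FALSE)
  }
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin, seed = seed,
                 store_effects = isTRUE(store_effects), prior = prior,
                 n_retained = retained),
            class = "mtme_config")
}

#' Number of retained posterior samples under a configuration
#' @param config an `mtme_config`.
#' @return integer, `floor((n_iter - burn_in) / thin)`.
#' @export
n_retained <- function(config) {
  stopifnot(inherits(config, "mtme_config"))
  config$n_retained
}

#' Load a run configuration from YAML or JSON
#'
#' Recognized keys: `n_iter`, `burn_in`, `thin`, `seed`, `store_effects`, and
#' a `prior` block with `nu0`, `V0` (scalar) and `beta_var`. Missing keys take
#' the [run_config()] defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return object of class `mtme_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format '", ext, "' (use yaml or json)",
         call. = FALSE)
  }
  if (!is.list(raw)) stop("config file must define a key-value mapping",
                          call. = FALSE)
  known <- c("n_iter", "burn_in", "thin", "seed", "store_effects", "prior")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  pr <- if (!is.null(raw$prior)) {
    prior_spec(nu0 = raw$prior$nu0, V0 = raw$prior$V0,
               beta_var = if (is.null(raw$prior$beta_var)) 1e8
                          else raw$prior$beta_var)
  } else {
    prior_spec()
  }
  defaults <- formals(run_config)
  pick <- function(key) if (is.null(raw[[key]])) eval(defaults[[key]]) else raw[[key]]
  run_config(n_iter = pick("n_iter"), burn_in = pick("burn_in"),
             thin = pick("thin"), seed = pick("seed"),
             store_effects = pick("store_effects"), prior = pr)
}

#' @export
print.mtme_config <- function(x, ...) {
  cat("MCMC configuration: n_iter =", x$n_iter, ", burn_in =", x$burn_in,
      ", thin =", x$thin, "\n")
  cat("  retained samples:", x$n_retained, "  seed:", x$seed,
      "  store_effects:", x$store_effects, "\n")
  invisible(x)
}
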