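# Chain diagnostics: pure functions of a numeric sample vector.

.check_chain <- function(chain, min_len = 2L) {
  chain <- as.numeric(chain)
  if (length(chain) < min_len) {
    stop("chain too short (need at least ", min_len, " samples)",
         call. = FALSE)
  }
  if (any(!is.finite(chain))) stop("chain contains non-finite values",
                                   call. = FALSE)
  chain
}

# spectral density at frequency zero via an AR fit with AIC order selection
.spectrum0_ar <- function(x) {
  v <- stats::var(x)
  if (v == 0) return(0)
  fit <- stats::ar(x, aic = TRUE,
                   order.max = min(length(x) - 1L,
                                   floor(10 * log10(length(x)))))
  if (fit$order == 0L) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke convergence diagnostic
#'
#' Compares the mean of an early window of the chain with the mean of a late
#' window by a z-score whose variances are spectral densities at frequency
#' zero, estimated from an autoregressive fit with AIC-selected order. For a
#' converged chain the score is approximately standard normal; |z| > 1.96 at
#' the 5% level flags disagreement between the beginning and the end of the
#' chain.
#'
#' @param chain numeric vector of (post burn-in, thinned) samples.
#' @param frac_first fraction of the chain in the early window.
#' @param frac_last fraction of the chain in the late window.
#' @return the z-score (a single number).
#' @export
geweke_z <- function(chain, frac_first = 0.1, frac_last = 0.5) {
  x <- .check_chain(chain, min_len = 20L)
  if (frac_first <= 0 || frac_last <= 0 || frac_first + frac_last > 1) {
    stop("window fractions must be positive with frac_first + frac_last <= 1",
         call. = FALSE)
  }
  n <- length(x)
  n1 <- floor(frac_first * n)
  n2 <- floor(frac_last * n)
  if (n1 < 10L || n2 < 10L) {
    stop("window sizes must be at least 10 samples", call. = FALSE)
  }
  x1 <- x[seq_len(n1)]
  x2 <- x[(n - n2 + 1L):n]
  s1 <- .spectrum0_ar(x1)
  s2 <- .spectrum0_ar(x2)
  if (s1 == 0 || s2 == 0) {
    stop("degenerate chain: a window has zero variance", call. = FALSE)
  }
  (mean(x1) - mean(x2)) / sqrt(s1 / n1 + s2 / n2)
}

#' Highest posterior density interval (Chen-Shao)
#'
#' Sorts the samples and returns the narrowest window containing
#' `ceiling(prob * n)` consecutive order statistics; ties are broken by the
#' lowest start index. Both endpoints are observed sample values.
#'
#' @param chain numeric vector of samples.
#' @param prob interval mass, in (0, 1).
#' @return named numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(chain, prob = 0.95) {
  x <- .check_chain(chain, min_len = 2L)
  if (!is.numeric(prob) || length(prob) != 1L || prob <= 0 || prob >= 1) {
    stop("`prob` must lie strictly between 0 and 1", call. = FALSE)
  }
  n <- length(x)
  if (n * (1 - prob) < 1) {
    stop("interval undefined: n * (1 - prob) < 1", call. = FALSE)
  }
  xs <- sort(x)
  m <- ceiling(prob * n)
  widths <- xs[m:n] - xs[seq_len(n - m + 1L)]
  i <- which.min(widths)   # which.min takes the first (lowest start) on ties
  c(lower = xs[i], upper = xs[i + m - 1L])
}

#' Posterior mode of a scalar chain
#'
#' Argmax of a Gaussian kernel density estimate evaluated on a 512-point
#' grid with Silverman's rule-of-thumb bandwidth; deterministic given the
#' chain. A constant chain returns its value.
#'
#' @param chain numeric vector with at least 100 samples.
#' @return the estimated mode (a single number).
#' @export
posterior_mode <- function(chain) {
  x <- .check_chain(chain, min_len = 100L)
  if (stats::var(x) == 0) return(x[1L])
  de <- stats::density(x, bw = "nrd0", n = 512L)
  de$x[which.max(de$y)]
}

#' Effective sample size
#'
#' `n / (1 + 2 * sum(rho_k))` where the sample autocorrelations `rho_k` are
#' accumulated until the first non-positive value (initial-positive-sequence
#' truncation).
#'
#' @param chain numeric vector with at least 100 samples.
#' @return the effective sample size (a single number in (0, n]).
#' @export
effective_size <- function(chain) {
  x <- .check_chain(chain, min_len = 100L)
  if (stats::var(x) == 0) stop("degenerate chain: zero variance",
                               call. = FALSE)
  n <- length(x)
  rho <- stats::acf(x, lag.max = min(n - 1L, 2000L), plot = FALSE,
                    demean = TRUE)$acf[-1L]
  pos <- which(rho <= 0)
  k <- if (length(pos)) pos[1L] - 1L else length(rho)
  tau <- 1 + 2 * sum(rho[seq_len(k)])
  ess <- n / max(tau, 1e-12)
  min(ess, n)
}
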