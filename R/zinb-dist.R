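#' Zero-inflated negative binomial log probability mass function
#'
#' The ZINB distribution is a two-component mixture of a point mass at zero
#' and a negative binomial (NB) distribution:
#' \deqn{f_{ZINB}(y; \mu, \theta, \pi) = \pi \delta_0(y) +
#'   (1 - \pi) f_{NB}(y; \mu, \theta),}
#' where the NB component is parameterized by its mean \eqn{\mu} and
#' dispersion \eqn{\theta} (size), so that the NB variance is
#' \eqn{\mu + \mu^2/\theta}. The mixture probability \eqn{\pi} is the
#' probability of an excess (inflated) zero.
#'
#' Evaluation is carried out in log space; at \eqn{y = 0} the two mixture
#' terms are combined with a log-sum-exp so that very small NB zero
#' probabilities (large \eqn{\mu}, large \eqn{\theta}) do not underflow.
#'
#' @param y Non-negative integer counts (vectorized; recycled against the
#'   parameters).
#' @param mu Positive NB means.
#' @param theta Positive NB dispersions (size parameter; \eqn{1/\phi}).
#' @param pi Zero-inflation probabilities in `[0, 1]`.
#' @param log Logical; return log-probabilities (default `TRUE`).
#' @return Numeric vector of (log-)probabilities.
#' @examples
#' dzinb(0, mu = 2, theta = 1, pi = 0)   # log f_NB(0; 2, 1) = log(1/3)
#' dzinb(0, mu = 2, theta = 1, pi = 0.5, log = FALSE)
#' @export
dzinb <- function(y, mu, theta, pi, log = TRUE) {
  n <- max(length(y), length(mu), length(theta), length(pi))
  y <- rep_len(y, n); mu <- rep_len(mu, n)
  theta <- rep_len(theta, n); pi <- rep_len(pi, n)
  if (anyNA(y) || anyNA(mu) || anyNA(theta) || anyNA(pi)) {
    stop("arguments must be finite and non-missing")
  }
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8)) {
    stop("'y' must contain non-negative integers")
  }
  if (any(mu <= 0)) stop("'mu' must be positive")
  if (any(theta <= 0)) stop("'theta' must be positive")
  if (any(pi < 0 | pi > 1)) stop("'pi' must lie in [0, 1]")
  lnb <- stats::dnbinom(y, size = theta, mu = mu, log = TRUE)
  out <- log1p(-pi) + lnb
  is0 <- y == 0
  if (any(is0)) {
    # log( pi + (1-pi) f_NB(0) ) via log-sum-exp of log(pi) and log(1-pi)+lnb
    lp <- log(pi[is0])
    lq <- out[is0]
    m <- pmax(lp, lq)
    m[!is.finite(m)] <- 0  # pi = 0 and underflowed NB handled below
    comb <- m + log(exp(lp - m) + exp(lq - m))
    # pi == 0: pure NB branch; pi == 1: point mass, log prob 0
    comb[pi[is0] == 0] <- lq[pi[is0] == 0]
    comb[pi[is0] == 1] <- 0
    out[is0] <- comb
  }
  if (log) out else exp(out)
}

#' ZINB log-likelihood of a count matrix under a fitted model
#'
#' Sums the ZINB log probability mass over all cells and genes, using the
#' fitted means \eqn{\mu_{ij}}, zero-inflation probabilities \eqn{\pi_{ij}}
#' and gene dispersions \eqn{\theta_j} stored in a [zinb_fit()] object (or
#' supplied directly).
#'
#' @param counts A `count_matrix` or cells-by-genes integer matrix.
#' @param fit A `zinb_fit` object, or a list with elements `mu` (n x J),
#'   `pi` (n x J) and `theta` (length J or scalar).
#' @return The total log-likelihood (a finite scalar).
#' @export
zinb_loglik <- function(counts, fit) {
  y <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  mu <- fit$mu; pii <- fit$pi; theta <- fit$theta
  if (!all(dim(y) == dim(mu)) || !all(dim(y) == dim(pii))) {
    stop("dimension mismatch between counts and fitted parameters")
  }
  theta <- rep_len(theta, ncol(y))
  thmat <- matrix(theta, nrow = nrow(y), ncol = ncol(y), byrow = TRUE)
  sum(dzinb(as.vector(y), as.vector(mu), as.vector(thmat), as.vector(pii)))
}

# Internal: stable log(1 + exp(x)).
log1pexp <- function(x) {
  out <- x
  small <- x <= 18
  out[small] <- log1p(exp(x[small]))
  mid <- x > 18 & x < 33.3
  out[mid] <- x[mid] + exp(-x[mid])
  out
}
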