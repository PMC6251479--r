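#' Posterior observation weights from a ZINB fit
#'
#' Computes, for every count, the posterior probability that it was generated
#' by the negative binomial count component of the fitted ZINB mixture:
#' \deqn{w_{ij} = \frac{(1-\pi_{ij}) f_{NB}(y_{ij}; \mu_{ij}, \theta_j)}
#'   {f_{ZINB}(y_{ij}; \mu_{ij}, \theta_j, \pi_{ij})}.}
#' A positive count cannot be an excess zero, so \eqn{w_{ij} = 1} exactly
#' whenever \eqn{y_{ij} > 0}; only zeros receive weights below one. These
#' posterior probabilities are the observation-level weights that plug into
#' weighted negative binomial GLM differential-expression analysis (see
#' [zinb_de()]).
#'
#' All mixture arithmetic is performed in log space and the result is clipped
#' to `[0, 1]`.
#'
#' @param counts A `count_matrix` or cells-by-genes matrix the model was
#'   fitted to.
#' @param fit A [zinb_fit()] object with matching dimensions.
#' @return An object of class `zinb_weights`: an n-by-J numeric matrix of
#'   weights in `[0, 1]` with attributes recording provenance (fit
#'   configuration).
#' @examples
#' # a zero with pi = 0.5, mu = 2, theta = 1: f_NB(0) = 1/3, so w = 0.25
#' fit <- list(mu = matrix(2), pi = matrix(0.5), theta = 1)
#' posterior_weights(matrix(0L), fit)
#' @export
posterior_weights <- function(counts, fit) {
  y <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  mu <- fit$mu; pii <- fit$pi
  if (!all(dim(y) == dim(mu))) stop("dimension mismatch between counts and fit")
  theta <- rep_len(fit$theta, ncol(y))
  w <- matrix(1, nrow(y), ncol(y), dimnames = dimnames(y))
  z0 <- which(y == 0)
  if (length(z0)) {
    Th <- matrix(theta, nrow(y), ncol(y), byrow = TRUE)
    lf0 <- Th * log(Th / (Th + mu))           # log f_NB(0)
    lnum <- log1p(-pii[z0]) + lf0[z0]         # log (1-pi) f_NB(0)
    lpi <- log(pii[z0])
    m <- pmax(lpi, lnum)
    lden <- m + log(exp(lpi - m) + exp(lnum - m))
    wz <- exp(lnum - lden)
    wz[pii[z0] == 0] <- 1                     # no zero inflation
    wz[pii[z0] == 1] <- 0                     # pure point mass
    w[z0] <- pmin(pmax(wz, 0), 1)
  }
  structure(w, class = c("zinb_weights", "matrix", "array"),
            provenance = list(config = fit$config, dims = fit$dims))
}

#' @export
print.zinb_weights <- function(x, ...) {
  cat(sprintf(
    "zinb_weights: %d x %d; %.1f%% of entries below 1 (zeros downweighted); mean zero weight %.3f\n",
    nrow(x), ncol(x), 100 * mean(x < 1),
    if (any(x < 1)) mean(x[x < 1]) else NA_real_
  ))
  invisible(x)
}

#' Average posterior weight of the zeros of each gene
#'
#' For each gene, averages the posterior weights over the cells in which the
#' gene has a zero count. Genes with no zeros have no zero weights to
#' average and are returned as `NA`.
#'
#' @param weights An n-by-J weight matrix (e.g. from [posterior_weights()]).
#' @param counts The matching `count_matrix` or matrix.
#' @return Named numeric vector of length J; `NA` for genes without zeros.
#' @export
average_zero_weight <- function(weights, counts) {
  y <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  w <- unclass(weights)
  stopifnot(all(dim(y) == dim(w)))
  iszero <- y == 0
  nz <- colSums(iszero)
  out <- colSums(w * iszero) / nz
  out[nz == 0] <- NA_real_
  names(out) <- colnames(y)
  out
}
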