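#' @export
print.zinb_fit <- function(x, ...) {
  d <- x$dims
  cat("Zero-inflated negative binomial regression fit\n")
  cat(sprintf("  %d cells x %d genes; X: %d column(s), V: %d column(s), K = %d\n",
              d["n"], d["J"], d["M"], d["L"], d["K"]))
  cat(sprintf("  dispersion: %s (theta %s); epsilon = %g\n",
              x$config$dispersion,
              if (x$config$dispersion == "common") sprintf("= %.4g", x$theta[1L])
              else sprintf("median %.4g", stats::median(x$theta)),
              x$config$epsilon))
  cat(sprintf("  log-likelihood %.2f over %d iterations (%s)\n",
              x$loglik, length(x$penalized_loglik_trace),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
summary.zinb_fit <- function(object, ...) {
  out <- list(
    dims = object$dims,
    converged = object$converged,
    loglik = object$loglik,
    aic = 2 * object$n_params - 2 * object$loglik,
    theta = summary(object$theta),
    mean_pi = mean(object$pi),
    zero_fraction_explained = mean(object$pi > 0.5)
  )
  class(out) <- "summary.zinb_fit"
  out
}

#' @export
print.summary.zinb_fit <- function(x, ...) {
  cat("ZINB regression fit summary\n")
  cat(sprintf("  cells: %d  genes: %d  converged: %s\n",
              x$dims["n"], x$dims["J"], x$converged))
  cat(sprintf("  log-likelihood: %.2f   AIC: %.2f\n", x$loglik, x$aic))
  cat(sprintf("  mean zero-inflation probability: %.4f\n", x$mean_pi))
  cat("  dispersion theta:\n")
  print(x$theta)
  invisible(x)
}

#' Extract ZINB coefficient blocks
#'
#' @param object A `zinb_fit`.
#' @param ... Ignored.
#' @return A named list with the coefficient matrices `beta_mu`, `beta_pi`,
#'   `gamma_mu`, `gamma_pi`, `alpha_mu`, `alpha_pi` and the log-dispersion
#'   vector `zeta`.
#' @export
coef.zinb_fit <- function(object, ...) {
  object[c("beta_mu", "beta_pi", "gamma_mu", "gamma_pi",
           "alpha_mu", "alpha_pi", "zeta")]
}

#' @export
logLik.zinb_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params,
            nobs = prod(object$dims[c("n", "J")]), class = "logLik")
}

#' Akaike information criterion of a ZINB fit
#'
#' Computes `2 * n_params - 2 * loglik` using the unpenalized log-likelihood
#' at the fitted parameters; equivalent to `stats::AIC()` on the fit. Used,
#' for example, to choose the number of latent factors `K`.
#'
#' @param fit A `zinb_fit`.
#' @return AIC value (scalar).
#' @export
model_aic <- function(fit) {
  stopifnot(inherits(fit, "zinb_fit"))
  2 * fit$n_params - 2 * fit$loglik
}

#' Predict from a ZINB fit
#'
#' @param object A `zinb_fit`.
#' @param type One of `"mu"` (NB means), `"pi"` (zero-inflation
#'   probabilities), `"theta"` (gene dispersions).
#' @param ... Ignored.
#' @return A matrix (or vector for `"theta"`) of fitted quantities.
#' @export
predict.zinb_fit <- function(object, type = c("mu", "pi", "theta"), ...) {
  type <- match.arg(type)
  switch(type, mu = object$mu, pi = object$pi, theta = object$theta)
}

#' @export
fitted.zinb_fit <- function(object, ...) object$mu

#' Simulate count matrices from a fitted ZINB model
#'
#' Draws `nsim` cells-by-genes matrices from the fitted mixture: each entry
#' is an excess zero with probability \eqn{\pi_{ij}}, otherwise a draw from
#' \eqn{NB(\mu_{ij}, \theta_j)}.
#'
#' @param object A `zinb_fit`.
#' @param nsim Number of matrices to simulate.
#' @param seed Optional integer seed.
#' @param ... Ignored.
#' @return A list of `nsim` integer matrices.
#' @export
simulate.zinb_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$dims[["n"]]; J <- object$dims[["J"]]
  Th <- matrix(object$theta, n, J, byrow = TRUE)
  lapply(seq_len(nsim), function(k) {
    y <- matrix(stats::rnbinom(n * J, size = Th, mu = object$mu), n, J)
    drop0 <- matrix(stats::runif(n * J) < object$pi, n, J)
    y[drop0] <- 0L
    dimnames(y) <- list(object$cell_ids, object$gene_ids)
    y
  })
}

#' Pearson residuals under the fitted ZINB distribution
#'
#' Residuals are computed against the ZINB mean \eqn{(1-\pi)\mu} and variance
#' \eqn{(1-\pi)\mu(1 + \mu(\pi + 1/\theta))}.
#'
#' @param object A `zinb_fit`.
#' @param counts The `count_matrix` (or matrix) the model was fitted to.
#' @param ... Ignored.
#' @return An n-by-J matrix of Pearson residuals.
#' @export
residuals.zinb_fit <- function(object, counts, ...) {
  y <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  stopifnot(all(dim(y) == dim(object$mu)))
  Th <- matrix(object$theta, nrow(y), ncol(y), byrow = TRUE)
  m <- (1 - object$pi) * object$mu
  v <- (1 - object$pi) * object$mu * (1 + object$mu * (object$pi + 1 / Th))
  (y - m) / sqrt(pmax(v, 1e-12))
}
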