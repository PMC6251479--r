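# Vectorized weighted NB GLM fitting across genes sharing a design matrix.
#
# For each gene j the IRLS loop maximizes the weighted NB log-likelihood
#   sum_i w_ij * logNB(y_ij; exp(x_i' beta_j + o_i), theta_j)
# with log link, gene dispersions theta_j (scalar or length J) and
# observation weights w_ij in [0, 1]. All genes are updated simultaneously
# through cross-product algebra on n x J matrices; the design X is common.

.MINMU <- 1e-6   # floor on fitted means (low-count stability)

.glm_nb_irls <- function(Y, X, offset, Wobs, theta, beta0 = NULL,
                         maxit = 50L, tol = 1e-8, ridge = 0) {
  n <- nrow(Y); J <- ncol(Y); p <- ncol(X)
  theta <- rep_len(theta, J)
  if (is.null(dim(offset))) offset <- matrix(offset, n, J)
  Th <- matrix(theta, n, J, byrow = TRUE)
  if (is.null(beta0)) {
    # moment start: intercept-like init through weighted log means
    beta <- matrix(0, p, J)
    int <- .intercept_col(X)
    if (!is.na(int)) {
      m0 <- colSums(Wobs * Y / exp(offset)) / pmax(colSums(Wobs), 1e-8)
      beta[int, ] <- log(pmax(m0, .MINMU)) / X[1L, int]
    }
  } else beta <- beta0
  ll_fun <- function(Mu) colSums(Wobs * .nb_ll_mat(Y, Mu, theta))
  eta <- X %*% beta + offset
  Mu <- pmax(exp(.cap_eta(eta)), .MINMU)
  ll <- ll_fun(Mu)
  converged <- rep(FALSE, J)
  for (it in seq_len(maxit)) {
    Wk <- Wobs * Mu * Th / (Mu + Th)          # working weights
    R <- Wobs * (Y - Mu) * Th / (Mu + Th)     # score residuals
    S <- crossprod(X, R) - ridge * beta
    XtWX <- .xtwx_many(X, Wk)
    if (ridge > 0 || p > 0) {
      idx <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
      for (r in seq_len(nrow(idx))) {
        if (idx[r, 1L] == idx[r, 2L]) XtWX[r, ] <- XtWX[r, ] + ridge + 1e-10
      }
    }
    Delta <- .solve_sym_many(XtWX, S, p)
    Delta <- pmin(pmax(Delta, -10), 10)
    f <- rep(1, J)
    active <- which(!converged)
    if (!length(active)) break
    beta_new <- beta
    ll_new <- ll
    for (h in 1:12) {
      bt <- beta[, active, drop = FALSE] +
        Delta[, active, drop = FALSE] * rep(f[active], each = p)
      eta_t <- X %*% bt + offset[, active, drop = FALSE]
      mu_t <- pmax(exp(.cap_eta(eta_t)), .MINMU)
      ll_t <- colSums(Wobs[, active, drop = FALSE] *
                        .nb_ll_mat(Y[, active, drop = FALSE], mu_t,
                                   theta[active])) -
        0.5 * ridge * colSums(bt^2)
      ll_ref <- ll[active] - 0.5 * ridge * colSums(beta[, active, drop = FALSE]^2)
      ok <- ll_t >= ll_ref - 1e-9 * (abs(ll_ref) + 1)
      if (any(ok)) {
        cols <- active[ok]
        beta_new[, cols] <- bt[, ok, drop = FALSE]
        ll_new[cols] <- ll_t[ok] + 0.5 * ridge * colSums(bt[, ok, drop = FALSE]^2)
      }
      active <- active[!ok]
      if (!length(active)) break
      f[active] <- f[active] / 2
    }
    moved <- abs(ll_new - ll)
    converged <- converged | (moved < tol * (abs(ll_new) + 1))
    beta <- beta_new
    ll <- ll_new
    eta <- X %*% beta + offset
    Mu <- pmax(exp(.cap_eta(eta)), .MINMU)
    if (all(converged)) break
  }
  # weighted deviance: 2 * (saturated - fitted), saturated at mu = max(y, minmu)
  Musat <- pmax(Y, .MINMU)
  ll_sat <- colSums(Wobs * .nb_ll_mat(Y, Musat, theta))
  dev <- 2 * (ll_sat - ll_fun(Mu))
  list(beta = beta, mu = Mu, loglik = ll_fun(Mu), deviance = dev,
       converged = converged, theta = theta)
}

#' Fit a weighted negative binomial GLM for one gene
#'
#' Maximizes \eqn{\sum_i w_i \log f_{NB}(y_i; \exp(x_i'\beta + o_i), \theta)}
#' by iteratively reweighted least squares with step halving. Observations
#' with weight zero contribute nothing and the fit is identical to deleting
#' them. If the IRLS diverges (e.g. separation), a small ridge is added and
#' the fit retried with a warning.
#'
#' @param y Integer count vector (length n).
#' @param X Design matrix (n x p, full rank).
#' @param offset Per-observation offset on the log scale (length n, default 0).
#' @param w Observation weights in `[0, 1]` (default all 1).
#' @param theta Positive NB dispersion (size).
#' @return A list with `coefficients`, `fitted`, `deviance` (weighted),
#'   `loglik`, `se` (from the expected information), `df_residual`
#'   (\eqn{\sum_i w_i - p}) and `converged`.
#' @export
fit_weighted_nb_glm <- function(y, X, offset = NULL, w = NULL, theta) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, theta > 0)
  if (is.null(offset)) offset <- rep(0, n)
  if (is.null(w)) w <- rep(1, n)
  stopifnot(length(offset) == n, length(w) == n, all(w >= 0), all(w <= 1))
  Y <- matrix(y, n, 1L)
  fit <- .glm_nb_irls(Y, X, matrix(offset, n, 1L), matrix(w, n, 1L), theta)
  if (!fit$converged[1L]) {
    warning("weighted NB GLM did not converge; refitting with a small ridge")
    fit <- .glm_nb_irls(Y, X, matrix(offset, n, 1L), matrix(w, n, 1L), theta,
                        ridge = 1e-4)
  }
  mu <- fit$mu[, 1L]
  wk <- w * mu * theta / (mu + theta)
  info <- crossprod(X, X * wk)
  se <- sqrt(diag(tryCatch(solve(info), error = function(e)
    matrix(NA_real_, ncol(X), ncol(X)))))
  list(coefficients = stats::setNames(fit$beta[, 1L], colnames(X)),
       fitted = mu,
       deviance = fit$deviance[1L],
       loglik = fit$loglik[1L],
       se = se,
       df_residual = sum(w) - ncol(X),
       converged = fit$converged[1L])
}
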