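# Weighted Cox-Reid adjusted profile likelihood (APL) dispersion machinery.
#
# For gene j at dispersion phi (theta = 1/phi), the APL is
#   APL_j(phi) = sum_i w_ij logNB(y_ij; mu_hat_ij, 1/phi)
#                - 0.5 * log det( X' diag(w_ij mu/(1 + phi mu)) X ),
# where mu_hat is the weighted NB GLM fit at that dispersion. The Cox-Reid
# term removes the leading-order bias from estimating the p mean parameters.

# APL for all genes at gene-specific dispersions `phi` (scalar or length J).
.apl_all <- function(Y, X, offset, Wobs, phi, beta0 = NULL) {
  J <- ncol(Y)
  phi <- rep_len(phi, J)
  theta <- 1 / phi
  fit <- .glm_nb_irls(Y, X, offset, Wobs, theta, beta0 = beta0,
                      maxit = 15L, tol = 1e-8)
  Th <- matrix(theta, nrow(Y), J, byrow = TRUE)
  Wk <- Wobs * fit$mu * Th / (fit$mu + Th)
  p <- ncol(X)
  XtWX <- .xtwx_many(X, Wk)
  # log det of the packed symmetric matrices
  ldet <- numeric(J)
  if (p == 1L) {
    ldet <- log(pmax(XtWX[1L, ], 1e-300))
  } else if (p == 2L) {
    det <- XtWX[1L, ] * XtWX[3L, ] - XtWX[2L, ]^2
    ldet <- log(pmax(det, 1e-300))
  } else {
    iu <- which(upper.tri(diag(p), diag = TRUE))
    for (j in seq_len(J)) {
      A <- matrix(0, p, p)
      A[iu] <- XtWX[, j]
      A <- A + t(A) - diag(diag(A), p)
      d <- determinant(A, logarithm = TRUE)
      ldet[j] <- as.numeric(d$modulus)
    }
  }
  list(apl = fit$loglik - 0.5 * ldet, beta = fit$beta)
}

#' Estimate weighted dispersions with empirical-Bayes shrinkage
#'
#' Estimates negative binomial dispersions \eqn{\phi_j} (with
#' \eqn{\theta_j = 1/\phi_j}) for every gene from weighted counts, in the
#' classical three stages: a common dispersion maximizing the summed
#' weighted Cox-Reid adjusted profile likelihood (APL); a smooth trend of
#' dispersion on average log CPM obtained by maximizing binned APLs and
#' lowess smoothing; and tagwise (gene-specific) dispersions that maximize a
#' weighted combination of the gene's own APL and the averaged APL of genes
#' at the same relative position of the trend, with `prior_df` pseudo-degrees
#' of freedom of borrowed information. Observations with weight ~0 contribute
#' essentially nothing, which is what lets zero-inflation weights restore the
#' mean-variance trend of the underlying count component.
#'
#' @param counts A `count_matrix` or cells-by-genes matrix.
#' @param design Cell-level design matrix (n x p) or formula on `cell_data`.
#' @param weights Optional n-by-J observation weights in `[0,1]` (default 1).
#' @param norm A `norm_factors` object, or `NULL` for [poscounts_size_factors()].
#' @param prior_df Prior degrees of freedom for tagwise shrinkage (default 10).
#' @param cell_data Optional data frame for a formula `design`.
#' @param span Lowess span for the trend (default 0.5).
#' @return An object of class `dispersion_fit`: a list with `common`,
#'   `trend` (length J), `tagwise` (length J), `prior_df`, `ave_log_cpm`,
#'   `low_df` (logical flag for genes with < 2 effective residual df, pinned
#'   to the trend), and the offsets/design used.
#' @export
estimate_dispersions <- function(counts, design, weights = NULL, norm = NULL,
                                 prior_df = 10, cell_data = NULL, span = 0.5) {
  cm <- as_count_matrix(counts)
  Y <- cm$counts
  n <- nrow(Y); J <- ncol(Y)
  X <- .resolve_design(design, cell_data, n, "x")
  p <- ncol(X)
  if (qr(X)$rank < p) stop("design matrix is not of full column rank")
  if (is.null(weights)) weights <- matrix(1, n, J)
  W <- unclass(weights)
  stopifnot(all(dim(W) == c(n, J)), all(W >= 0), all(W <= 1))
  if (is.null(norm)) norm <- poscounts_size_factors(cm)
  offset <- matrix(log(norm$size_factors), n, J)
  A <- ave_log_cpm(cm)
  df_eff <- colSums(W) - p
  low_df <- df_eff < 2

  # --- common dispersion ---
  usable <- which(!low_df)
  if (!length(usable)) usable <- seq_len(J)
  warm <- NULL
  apl_sum <- function(lphi) {
    a <- .apl_all(Y[, usable, drop = FALSE], X, offset[, usable, drop = FALSE],
                  W[, usable, drop = FALSE], exp(lphi), beta0 = warm)
    warm <<- a$beta
    sum(a$apl)
  }
  opt <- stats::optimize(apl_sum, interval = log(c(1e-6, 50)), maximum = TRUE,
                         tol = 5e-3)
  common <- exp(opt$maximum)

  # --- trend: binned APL maximization against average log CPM ---
  nbins <- max(2L, min(20L, floor(length(usable) / 50)))
  if (length(usable) >= 100L && nbins >= 2L) {
    bins <- cut(rank(A[usable], ties.method = "first"), breaks = nbins,
                labels = FALSE)
    grid <- common * 2^seq(-8, 8, length.out = 17L)
    aplg <- matrix(0, length(usable), length(grid))
    wb <- warm
    for (g in seq_along(grid)) {
      a <- .apl_all(Y[, usable, drop = FALSE], X, offset[, usable, drop = FALSE],
                    W[, usable, drop = FALSE], grid[g], beta0 = wb)
      aplg[, g] <- a$apl
      wb <- a$beta
    }
    bin_phi <- bin_A <- numeric(nbins)
    for (b in seq_len(nbins)) {
      sel <- bins == b
      tot <- colSums(aplg[sel, , drop = FALSE])
      bin_phi[b] <- .interp_max(log(grid), tot)
      bin_A[b] <- stats::median(A[usable][sel])
    }
    lo <- stats::lowess(bin_A, bin_phi, f = span)
    trend <- exp(stats::approx(lo$x, lo$y, xout = A, rule = 2)$y)
  } else {
    trend <- rep(common, J)
  }

  # --- tagwise shrinkage toward the trend ---
  relgrid <- 2^seq(-6, 6, length.out = 15L)
  aplmat <- matrix(0, J, length(relgrid))      # J x G
  wb <- NULL
  for (g in seq_along(relgrid)) {
    a <- .apl_all(Y, X, offset, W, trend * relgrid[g], beta0 = wb)
    aplmat[, g] <- a$apl
    wb <- a$beta
  }
  shared <- colMeans(aplmat[!low_df, , drop = FALSE])
  wg <- df_eff / (df_eff + prior_df)
  wg[wg < 0] <- 0
  score <- aplmat * wg + matrix(shared, J, length(relgrid), byrow = TRUE) *
    (1 - wg)
  tagwise <- numeric(J)
  lg <- log(relgrid)
  for (j in seq_len(J)) {
    tagwise[j] <- trend[j] * exp(.interp_max(lg, score[j, ]))
  }
  tagwise[low_df] <- trend[low_df]

  structure(list(common = common, trend = trend, tagwise = tagwise,
                 prior_df = prior_df, ave_log_cpm = A,
                 low_df = low_df, design = X, offset = offset[1L, ],
                 size_factors = norm$size_factors, df_eff = df_eff),
            class = "dispersion_fit")
}

# Quadratic interpolation of the maximizer of y over a uniform grid x.
.interp_max <- function(x, y) {
  i <- which.max(y)
  if (i == 1L || i == length(x)) return(x[i])
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  if (!is.finite(denom) || abs(denom) < 1e-12) return(x[i])
  v <- x[i] + 0.5 * (x[i] - x[i - 1L]) * (y[i - 1L] - y[i + 1L]) / denom
  min(max(v, x[i - 1L]), x[i + 1L])
}

#' @export
print.dispersion_fit <- function(x, ...) {
  cat(sprintf(
    "dispersion_fit: common phi %.4g; tagwise phi median %.4g (BCV %.3f); prior_df %.3g\n",
    x$common, stats::median(x$tagwise), sqrt(stats::median(x$tagwise)),
    x$prior_df))
  invisible(x)
}

#' BCV plot of a dispersion fit
#'
#' Plots the gene-wise biological coefficient of variation
#' \eqn{\sqrt{\phi_j}} against average log CPM, with the fitted trend, the
#' classic diagnostic for zero-inflation-driven dispersion inflation.
#'
#' @param x A `dispersion_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dispersion_fit <- function(x, ...) {
  o <- order(x$ave_log_cpm)
  graphics::plot(x$ave_log_cpm, sqrt(x$tagwise), pch = 16, cex = 0.4,
                 col = "grey40", xlab = "average log CPM", ylab = "BCV", ...)
  graphics::lines(x$ave_log_cpm[o], sqrt(x$trend[o]), col = "red", lwd = 2)
  graphics::abline(h = sqrt(x$common), col = "blue", lty = 2)
  invisible(x)
}
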