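# Shared fixtures and independent oracles used across the test files.
# Oracles are deliberately implemented by brute force (grids, enumeration),
# not by calling the code paths they check.

# Exhaustive two-stage grid search for the ZINB MLE of a single gene under
# an intercept-only model with common dispersion: maximizes
# sum_i log f_ZINB(y_i; mu, theta, pi) over (mu, theta, pi).
grid_zinb_mle <- function(y, n_coarse = 40L, n_fine = 40L) {
  obj <- function(mu, th, pp) {
    lnb <- stats::dnbinom(y, size = th, mu = mu, log = TRUE)
    ll <- log1p(-pp) + lnb
    ll[y == 0] <- log(pp + (1 - pp) * exp(lnb[y == 0]))
    sum(ll)
  }
  search <- function(mu_r, th_r, pi_r, k) {
    mus <- exp(seq(log(mu_r[1]), log(mu_r[2]), length.out = k))
    ths <- exp(seq(log(th_r[1]), log(th_r[2]), length.out = k))
    pis <- seq(pi_r[1], pi_r[2], length.out = k)
    best <- c(-Inf, NA, NA, NA)
    for (mu in mus) for (th in ths) {
      vals <- vapply(pis, function(pp) obj(mu, th, pp), numeric(1))
      i <- which.max(vals)
      if (vals[i] > best[1]) best <- c(vals[i], mu, th, pis[i])
    }
    best
  }
  b <- search(c(max(mean(y), 0.1) / 8, max(y) + 1), c(0.05, 100),
              c(1e-4, 0.95), n_coarse)
  for (r in 1:2) {
    b <- search(c(b[2] / 1.6, b[2] * 1.6), c(b[3] / 1.6, b[3] * 1.6),
                c(max(b[4] - 0.08 / r, 1e-6), min(b[4] + 0.08 / r, 1 - 1e-6)),
                n_fine)
  }
  list(loglik = b[1], mu = b[2], theta = b[3], pi = b[4])
}

# Fine grid search for the weighted NB GLM deviance of a two-group design:
# beta = (intercept, group effect), fixed theta and weights.
grid_weighted_nb <- function(y, group, w, theta, offset = NULL) {
  if (is.null(offset)) offset <- rep(0, length(y))
  ll <- function(b0, b1) {
    mu <- exp(b0 + b1 * group + offset)
    sum(w * stats::dnbinom(y, size = theta, mu = mu, log = TRUE))
  }
  b0s <- seq(-3, 6, length.out = 120)
  b1s <- seq(-4, 4, length.out = 120)
  best <- c(-Inf, NA, NA)
  for (b0 in b0s) {
    vals <- vapply(b1s, function(b1) ll(b0, b1), numeric(1))
    i <- which.max(vals)
    if (vals[i] > best[1]) best <- c(vals[i], b0, b1s[i])
  }
  for (r in 1:3) {
    b0s <- seq(best[2] - 0.2 / r, best[2] + 0.2 / r, length.out = 60)
    b1s <- seq(best[3] - 0.2 / r, best[3] + 0.2 / r, length.out = 60)
    for (b0 in b0s) {
      vals <- vapply(b1s, function(b1) ll(b0, b1), numeric(1))
      i <- which.max(vals)
      if (vals[i] > best[1]) best <- c(vals[i], b0, b1s[i])
    }
  }
  musat <- pmax(y, 1e-6)
  llsat <- sum(w * stats::dnbinom(y, size = theta, mu = musat, log = TRUE))
  list(loglik = best[1], deviance = 2 * (llsat - best[1]),
       beta = best[2:3])
}

# Bulk-like NB counts with a decreasing mean-dispersion trend.
make_nb_trend_data <- function(n, J, seed, lib_size = 1e6,
                               phi0 = 0.05, phi_amp = 3) {
  set.seed(seed)
  mu_g <- exp(stats::runif(J, log(20), log(2000)))
  phi <- phi0 + phi_amp / mu_g
  Y <- matrix(stats::rnbinom(n * J, size = rep(1 / phi, each = n),
                             mu = rep(mu_g, each = n)), n, J)
  list(Y = Y, mu = mu_g, phi = phi)
}

# Small deterministic two-group NB dataset for pipeline identity checks.
make_small_de_data <- function(seed = 42L, n = 30L, J = 120L) {
  set.seed(seed)
  grp <- rep(c(0, 1), length.out = n)
  mu <- exp(stats::runif(J, log(5), log(50)))
  lfc <- c(rep(1, 10), rep(0, J - 10))
  Mu <- outer(rep(1, n), mu) * 2^(outer(grp, lfc))
  Y <- matrix(stats::rnbinom(n * J, size = 2, mu = Mu), n, J)
  Y[, colSums(Y) == 0] <- Y[, colSums(Y) == 0] + 1L  # avoid all-zero genes
  list(Y = Y, grp = grp, de = lfc != 0)
}
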