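# Penalized ZINB regression fitting: small-instance oracles, parameter
# recovery, monotonicity and equivariance properties, AIC.

test_that("intercept-only ZINB MLE matches an exhaustive grid search", {
  y <- c(0L, 0L, 1L, 3L, 5L, 12L)
  oracle <- grid_zinb_mle(y)
  fit <- zinb_fit(matrix(y, ncol = 1), X = ~1, V = NULL, epsilon = 0,
                  maxit = 400, tol = 1e-12)
  # objective to 1e-4; the fit may not be worse than the exhaustive search
  expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-4)
  expect_gte(fit$loglik, oracle$loglik - 1e-4)
  # parameters agree up to the flatness of the likelihood near the optimum
  expect_equal(unname(fit$mu[1, 1]), oracle$mu, tolerance = 0.02)
  expect_equal(unname(fit$theta[1]), oracle$theta, tolerance = 0.02)
  expect_equal(unname(fit$pi[1, 1]), oracle$pi, tolerance = 0.02)
})

test_that("a second small instance (more zeros) also matches its grid optimum", {
  y <- c(0L, 0L, 0L, 0L, 2L, 9L, 14L, 0L)
  oracle <- grid_zinb_mle(y)
  fit <- zinb_fit(matrix(y, ncol = 1), X = ~1, V = NULL, epsilon = 0,
                  maxit = 400, tol = 1e-12)
  expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-4)
})

test_that("pure NB two-group data: pi concentrates at 0, means recovered", {
  set.seed(11)
  n <- 200; J <- 100
  grp <- rep(c(0, 1), each = n / 2)
  mu_g <- exp(runif(J, log(5), log(80)))
  lfc <- rnorm(J, 0, 0.5)
  Mu <- outer(rep(1, n), mu_g) * 2^outer(grp - 0.5, lfc)
  Y <- matrix(rnbinom(n * J, size = 3, mu = Mu), n, J)
  keep <- colSums(Y > 0) >= 5
  fit <- zinb_fit(Y[, keep], X = ~grp, V = NULL, epsilon = 1,
                  cell_data = data.frame(grp = grp))
  expect_lt(mean(fit$pi), 0.05)
  # fitted group means within 10% of the truth (median over genes)
  rel1 <- abs(colMeans(fit$mu[grp == 0, ]) / colMeans(Mu[grp == 0, keep]) - 1)
  rel2 <- abs(colMeans(fit$mu[grp == 1, ]) / colMeans(Mu[grp == 1, keep]) - 1)
  expect_lt(median(c(rel1, rel2)), 0.10)
})

test_that("ZINB data: zero-inflation structure is recovered", {
  # logit pi depends on the cell through a known coefficient; repeated
  # simulation keeps the estimated cell-level inflation within bounds
  set.seed(21)
  errs <- replicate(3, {
    n <- 120; J <- 150
    mu_g <- exp(runif(J, log(10), log(100)))
    pi_cell <- plogis(rnorm(n, qlogis(0.3), 0.7))
    Y <- matrix(rnbinom(n * J, size = 2, mu = rep(mu_g, each = n)), n, J)
    drop <- matrix(runif(n * J) < pi_cell, n, J)
    Y[drop] <- 0L
    keep <- colSums(Y > 0) >= 5
    fit <- zinb_fit(Y[, keep], X = ~1, epsilon = 1e4)
    # cell-level inflation: fitted pi per cell tracks the generating pi
    cor(rowMeans(fit$pi), pi_cell)
  })
  expect_gt(median(errs), 0.8)
})

test_that("penalized objective is monotone non-decreasing on varied data", {
  for (s in 1:3) {
    set.seed(s)
    n <- 25; J <- 40
    Y <- matrix(rnbinom(n * J, size = 0.8, mu = 6), n, J)
    Y[matrix(runif(n * J) < 0.2, n, J)] <- 0L
    Y <- Y[, colSums(Y) > 0]
    for (disp in c("common", "genewise")) {
      fit <- suppressWarnings(
        zinb_fit(Y, X = ~1, epsilon = 10, dispersion = disp,
                 epsilon_zeta = if (disp == "genewise") 5 else NULL,
                 maxit = 40))
      tr <- fit$penalized_loglik_trace
      expect_true(all(diff(tr) >= -1e-6 * (abs(tr[-length(tr)]) + 1)),
                  info = sprintf("seed %d, %s", s, disp))
    }
  }
})

test_that("increasing epsilon shrinks penalized coefficient norms", {
  set.seed(5)
  n <- 40; J <- 60
  grp <- rep(c(0, 1), each = n / 2)
  Y <- matrix(rnbinom(n * J, size = 1.5, mu = 8), n, J)
  Y[matrix(runif(n * J) < 0.15, n, J)] <- 0L
  Y <- Y[, colSums(Y) > 0]
  norms <- sapply(c(1, 1e6, 1e12), function(eps) {
    fit <- zinb_fit(Y, X = ~grp, cell_data = data.frame(grp = grp),
                    epsilon = eps)
    sqrt(sum(fit$beta_mu[2, ]^2) + sum(fit$beta_pi[2, ]^2))
  })
  expect_true(all(diff(norms) < 0))
})

test_that("fit is equivariant to cell and gene permutations", {
  set.seed(8)
  n <- 20; J <- 30
  Y <- matrix(rnbinom(n * J, size = 1, mu = 5), n, J)
  Y <- Y[, colSums(Y) > 0]
  J <- ncol(Y)
  fit <- zinb_fit(Y, X = ~1, epsilon = 100, maxit = 50)
  pc <- sample(n); pg <- sample(J)
  fitp <- zinb_fit(Y[pc, pg], X = ~1, epsilon = 100, maxit = 50)
  expect_equal(fitp$mu, fit$mu[pc, pg], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(fitp$pi, fit$pi[pc, pg], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("degenerate inputs are rejected with clear messages", {
  Y <- matrix(c(0, 0, 0, 1, 2, 3), 3, 2)
  expect_error(zinb_fit(Y), "all-zero")
  Y2 <- matrix(rpois(20, 4) + 1, 5, 4)
  X <- cbind(1, c(1, 1, 1, 1, 1))       # rank deficient
  expect_error(zinb_fit(Y2, X = X), "full column rank")
  expect_error(zinb_fit(Y2, K = 99), "K")
})

test_that("AIC follows its definition and penalizes inactive covariates", {
  set.seed(13)
  n <- 40; J <- 30
  Y <- matrix(rnbinom(n * J, size = 2, mu = 10), n, J)
  Y <- Y[, colSums(Y) > 0]
  fit0 <- zinb_fit(Y, X = ~1, epsilon = 1)
  expect_equal(model_aic(fit0), 2 * fit0$n_params - 2 * fit0$loglik)
  expect_equal(AIC(fit0), model_aic(fit0))
  # an inactive covariate adds coefficients on both model sides; the fit
  # cannot improve the likelihood by more than the parameter count allows
  junk <- rnorm(n)
  fit1 <- zinb_fit(Y, X = ~junk, cell_data = data.frame(junk = junk),
                   epsilon = 1)
  added <- fit1$n_params - fit0$n_params
  expect_equal(added, 2 * ncol(Y))
  expect_gt(model_aic(fit1), model_aic(fit0) - 2 * added)
})

test_that("AIC prefers K = 0 when the data have no latent structure", {
  wins <- 0
  for (s in 1:3) {
    set.seed(30 + s)
    n <- 30; J <- 40
    Y <- matrix(rnbinom(n * J, size = 2, mu = 8), n, J)
    Y <- Y[, colSums(Y) > 0]
    a0 <- model_aic(zinb_fit(Y, X = ~1, K = 0, epsilon = 1))
    a2 <- suppressWarnings(
      model_aic(zinb_fit(Y, X = ~1, K = 2, epsilon = 1, seed = s)))
    if (a0 <= a2) wins <- wins + 1
  }
  expect_gte(wins, 2)
})

test_that("fit serialization round-trips through plain text", {
  set.seed(17)
  Y <- matrix(rnbinom(60, size = 2, mu = 6), 10, 6)
  Y <- Y[, colSums(Y) > 0]
  fit <- zinb_fit(Y, X = ~1, epsilon = 10, maxit = 30)
  d <- tempfile("zfit")
  write_zinb_fit(fit, d)
  back <- read_zinb_fit(d)
  expect_equal(back$mu, fit$mu, tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(back$pi, fit$pi, tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(back$theta, fit$theta, tolerance = 1e-10)
  expect_equal(back$loglik, fit$loglik)
  unlink(d, recursive = TRUE)
})

test_that("simulate() and residuals() methods are coherent with the fit", {
  set.seed(19)
  Y <- matrix(rnbinom(400, size = 2, mu = 12), 20, 20)
  Y <- Y[, colSums(Y) > 0]
  fit <- zinb_fit(Y, X = ~1, epsilon = 10)
  sims <- simulate(fit, nsim = 20, seed = 1)
  zf <- mean(sapply(sims, function(m) mean(m == 0)))
  # simulated zero fraction matches the model's own zero probability
  thm <- matrix(fit$theta, nrow(Y), ncol(Y), byrow = TRUE)
  p0 <- mean(fit$pi + (1 - fit$pi) * (thm / (thm + fit$mu))^thm)
  expect_lt(abs(zf - p0), 0.005)
  r <- residuals(fit, Y)
  expect_equal(dim(r), dim(Y))
  expect_lt(abs(mean(r)), 0.2)
})
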