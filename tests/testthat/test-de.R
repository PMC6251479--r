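# Weighted NB GLM differential-expression engine: normalization, GLM
# fitting, the moderated F test's degrees-of-freedom bookkeeping, LRT/Wald,
# filtering and BH.

test_that("poscounts size factors: symmetry, scale equivariance, hand oracle", {
  # identical counts: all factors 1
  y <- matrix(7L, 4, 5)
  expect_equal(unname(poscounts_size_factors(y)$size_factors), rep(1, 4))
  # doubling a cell's positives doubles its factor
  set.seed(2)
  y2 <- matrix(rnbinom(40, size = 5, mu = 20), 4, 10)
  y2[1, ] <- 2L * y2[2, ]
  s <- poscounts_size_factors(y2)$size_factors
  expect_equal(unname(s[1] / s[2]), 2, tolerance = 1e-12)
  # 3-cell, 4-gene toy with zeros, worked by the stated recipe
  toy <- matrix(c(4L, 8L, 0L,
                  2L, 2L, 4L,
                  1L, 1L, 6L,
                  12L, 0L, 3L), 3, 4)
  ref <- exp(colMeans(ifelse(toy > 0, log(toy), NA), na.rm = TRUE))
  rat <- sweep(toy, 2, ref, "/")
  rat[toy == 0] <- NA
  # median interpolation on the log scale (the field's convention)
  s_hand <- apply(rat, 1, function(r) exp(median(log(r), na.rm = TRUE)))
  s_hand <- s_hand / exp(mean(log(s_hand)))
  expect_equal(unname(poscounts_size_factors(toy)$size_factors), s_hand,
               tolerance = 1e-12)
  # all-zero cell is an error naming the cell
  bad <- rbind(toy, 0L)
  expect_error(poscounts_size_factors(bad), "positive")
})

test_that("ave_log_cpm follows the direct formula", {
  # unit CPM: two cells of depth 1e6 with one count each
  y <- matrix(c(1L, 1L, 999999L, 999999L), 2, 2)
  a <- ave_log_cpm(y)
  cstab <- 2 * 1e6 / mean(rowSums(y))
  expect_equal(unname(a[1]), log2(1 + cstab), tolerance = 1e-12)
  # doubling counts and depths leaves the value unchanged wherever the
  # CPM dominates the small stabilizer (the stabilizer floor itself moves
  # with the prior count divided by the mean depth)
  expect_equal(unname(ave_log_cpm(2L * y))[2], unname(ave_log_cpm(y))[2],
               tolerance = 1e-6)
  # toy fixture vs direct evaluation
  set.seed(4)
  y3 <- matrix(rnbinom(30, size = 2, mu = 9) + 1L, 5, 6)
  N <- rowSums(y3)
  direct <- log2(1e6 / 5 * colSums(y3 / N) + 2e6 / mean(N))
  expect_equal(unname(ave_log_cpm(y3)), direct, tolerance = 1e-10)
})

test_that("weighted NB GLM: closed form, deletion semantics, grid oracle", {
  set.seed(6)
  y <- rnbinom(20, size = 2, mu = 10)
  X1 <- matrix(1, 20, 1)
  off <- rep(0.3, 20)
  # all weights 1, intercept-only, constant offset: the NB MLE mean is the
  # sample mean, so exp(beta) = mean(y) / exp(o) in closed form
  f <- fit_weighted_nb_glm(y, X1, offset = off, theta = 2)
  expect_equal(unname(exp(f$coefficients)), mean(y) / exp(0.3),
               tolerance = 1e-7)
  off <- rnorm(20, 0, 0.2)
  # weight-0 observations behave exactly like deleted observations
  w <- rep(1, 20); w[c(3, 7, 11)] <- 0
  fa <- fit_weighted_nb_glm(y, X1, offset = off, w = w, theta = 2)
  fb <- fit_weighted_nb_glm(y[w == 1], X1[w == 1, , drop = FALSE],
                            offset = off[w == 1], theta = 2)
  expect_equal(fa$coefficients, fb$coefficients, tolerance = 1e-9)
  expect_equal(fa$deviance, fb$deviance, tolerance = 1e-9)
  # 6-cell two-group toy matches a fine grid search to 1e-4
  y6 <- c(0L, 3L, 5L, 9L, 14L, 2L)
  g6 <- c(0, 0, 0, 1, 1, 1)
  w6 <- c(1, 0.5, 1, 1, 0.3, 1)
  or <- grid_weighted_nb(y6, g6, w6, theta = 1.5)
  f6 <- fit_weighted_nb_glm(y6, cbind(1, g6), w = w6, theta = 1.5)
  expect_equal(f6$deviance, or$deviance, tolerance = 1e-4)
  # fractional-weight cross-check against stats::glm with an NB family
  fg <- suppressWarnings(
    stats::glm(y6 ~ g6, family = MASS::negative.binomial(theta = 1.5),
               weights = w6))
  expect_equal(unname(f6$coefficients), unname(coef(fg)), tolerance = 1e-5)
})

test_that("moderated F test degrees-of-freedom bookkeeping is exact", {
  set.seed(9)
  n <- 16; J <- 40
  grp <- rep(c(0, 1), each = n / 2)
  Y <- matrix(rnbinom(n * J, size = 2, mu = 15), n, J)
  Y <- Y[, colSums(Y) > 0]; J <- ncol(Y)
  Xf <- cbind(1, grp); Xr <- matrix(1, n, 1)
  W1 <- matrix(1, n, J)
  disp <- estimate_dispersions(Y, Xf, weights = W1)
  off <- matrix(log(disp$size_factors), n, J)
  th <- 1 / disp$tagwise
  full <- zinbwt:::.glm_nb_irls(Y, Xf, off, W1, th)
  red <- zinbwt:::.glm_nb_irls(Y, Xr, off, W1, th)
  tt <- weighted_f_test(full, red, disp, W1, p_full = 2, p_red = 1)
  # all weights 1: df_j = n - p exactly
  expect_identical(unique(tt$df_resid), n - 2)
  # duplicating a cell with weight 0.5 on each copy reproduces the original
  Yd <- rbind(Y, Y[1, ]); Xfd <- rbind(Xf, Xf[1, ]); Xrd <- rbind(Xr, 1)
  offd <- rbind(off, off[1, ])
  Wd <- rbind(W1, W1[1, ]); Wd[1, ] <- 0.5; Wd[n + 1, ] <- 0.5
  fulld <- zinbwt:::.glm_nb_irls(Yd, Xfd, offd, Wd, th)
  redd <- zinbwt:::.glm_nb_irls(Yd, Xrd, offd, Wd, th)
  ttd <- weighted_f_test(fulld, redd, disp, Wd, p_full = 2, p_red = 1)
  expect_equal(ttd$df_resid, tt$df_resid, tolerance = 1e-12)
  expect_equal(ttd$statistic, tt$statistic, tolerance = 1e-6)
  # df_j <= 0 gives p = 1 and a flag
  W0 <- W1; W0[, 1] <- 0.05
  tt0 <- weighted_f_test(full, red, disp, W0, p_full = 2, p_red = 1)
  expect_identical(tt0$raw_p[1], 1)
  expect_true(tt0$low_df[1])
})

test_that("weighted LRT and Wald behave as specified", {
  set.seed(14)
  n <- 60; J <- 50
  grp <- rep(c(0, 1), each = n / 2)
  Y <- matrix(rnbinom(n * J, size = 2, mu = 20), n, J)
  Xf <- cbind(1, grp); Xr <- matrix(1, n, 1)
  W1 <- matrix(1, n, J)
  off <- matrix(0, n, J)
  full <- zinbwt:::.glm_nb_irls(Y, Xf, off, W1, 2)
  red <- zinbwt:::.glm_nb_irls(Y, Xr, off, W1, 2)
  # zero parameter difference: statistic 0, p 1
  t0 <- weighted_lrt(full, full, W1, p_full = 2, p_red = 2, type = "lrt")
  expect_true(all(t0$statistic == 0) && all(t0$raw_p == 1))
  # null LRT statistics follow chi-square(1): QQ slope 1 +/- 0.05
  tl <- weighted_lrt(full, red, W1, p_full = 2, p_red = 1, type = "lrt")
  qq <- qchisq(ppoints(J), df = 1)
  slope <- coef(lm(sort(tl$statistic) ~ 0 + qq))
  expect_equal(unname(slope), 1, tolerance = 0.25)
  # Wald agrees with LRT in rank and is t-referenced
  tw <- weighted_lrt(full, red, W1, p_full = 2, p_red = 1, type = "wald",
                     coef = 2, X_full = Xf, theta = 2)
  expect_gt(cor(tl$statistic, tw$statistic^2), 0.97)
})

test_that("LRT and F p-values agree asymptotically at large n", {
  set.seed(15)
  n <- 500; J <- 150
  grp <- rep(c(0, 1), each = n / 2)
  lfc <- c(rep(0.6, 30), rep(0, J - 30))
  Mu <- outer(rep(1, n), exp(runif(J, log(8), log(60)))) *
    2^outer(grp - 0.5, lfc)
  Y <- matrix(rnbinom(n * J, size = 2, mu = Mu), n, J)
  Xf <- cbind(1, grp); Xr <- matrix(1, n, 1)
  W1 <- matrix(1, n, J); off <- matrix(0, n, J)
  disp <- estimate_dispersions(Y, Xf, weights = W1,
                               norm = libsize_size_factors(Y))
  th <- 1 / disp$tagwise
  offs <- matrix(log(disp$size_factors), n, J)
  full <- zinbwt:::.glm_nb_irls(Y, Xf, offs, W1, th)
  red <- zinbwt:::.glm_nb_irls(Y, Xr, offs, W1, th)
  tf <- weighted_f_test(full, red, disp, W1, 2, 1)
  tl <- weighted_lrt(full, red, W1, 2, 1, type = "lrt")
  keep <- tl$raw_p > 1e-12 & tl$raw_p < 0.999
  ratio <- -log10(tf$raw_p[keep]) / -log10(tl$raw_p[keep])
  expect_lt(median(abs(ratio - 1)), 0.10)
})

test_that("bh_adjust matches the hand-worked step-up and its properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(16)
  p <- runif(200)^1.5
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-15))
  expect_equal(adj, p.adjust(p, "BH"), tolerance = 1e-12)  # independent check
  # NA propagation leaves other ranks untouched
  p2 <- c(0.01, NA, 0.02, 0.03)
  expect_equal(bh_adjust(p2), c(0.03, NA, 0.03, 0.03))
})

test_that("independent filtering: no-op, tie-break, and power property", {
  # all strengths identical: threshold at quantile 0, filtering no-op
  fl <- independent_filtering(runif(50), rep(3, 50))
  expect_identical(fl$quantile, 0)
  expect_false(any(fl$filtered))
  # flat p-values: zero rejections everywhere, tie-break keeps threshold 0
  fl2 <- independent_filtering(rep(1, 50), rnorm(50))
  expect_identical(fl2$quantile, 0)
  # rejections with filtering >= without, when low-strength genes are null
  set.seed(18)
  wins <- 0
  for (r in 1:20) {
    strength <- c(runif(300, 0, 1), runif(200, 2, 5))
    p <- c(runif(300), rbeta(200, 0.2, 1))
    n_f <- sum(independent_filtering(p, strength)$adjusted_p <= 0.05,
               na.rm = TRUE)
    n_0 <- sum(bh_adjust(p) <= 0.05, na.rm = TRUE)
    if (n_f >= n_0) wins <- wins + 1
  }
  expect_gte(wins, 18)
})

test_that("the weighted pipeline with unit weights is identical to unweighted", {
  d <- make_small_de_data()
  cd <- data.frame(grp = d$grp)
  r1 <- zinb_de(d$Y, design = ~grp, cell_data = cd)
  r2 <- zinb_de(d$Y, design = ~grp,
                weights = matrix(1, nrow(d$Y), ncol(d$Y)), cell_data = cd)
  expect_identical(r1$table, r2$table)
  expect_identical(r1$dispersions$tagwise, r2$dispersions$tagwise)
})

test_that("dispersion estimation recovers the truth and matches edgeR", {
  set.seed(25)
  n <- 50; J <- 2000
  phi_true <- 0.5
  Y <- matrix(rnbinom(n * J, size = 1 / phi_true, mu = 30), n, J)
  X <- matrix(1, n, 1)
  disp <- estimate_dispersions(Y, X, norm = libsize_size_factors(Y))
  expect_equal(disp$common, phi_true, tolerance = 0.10)
  skip_if_not_installed("edgeR")
  dl <- edgeR::DGEList(counts = t(Y))
  dl <- edgeR::calcNormFactors(dl)
  ce <- edgeR::estimateGLMCommonDisp(dl, design = X)$common.dispersion
  expect_equal(disp$common, ce, tolerance = 0.15)
})

test_that("genes with weight-zero zeros shrink to the trend", {
  set.seed(26)
  n <- 30; J <- 300
  Y <- matrix(rnbinom(n * J, size = 2, mu = 25), n, J)
  W <- matrix(1, n, J)
  # one gene: constant positive counts, zeros elsewhere fully downweighted
  Y[, 1] <- c(rep(0L, 25), rep(20L, 5))
  W[Y[, 1] == 0, 1] <- 0
  disp <- estimate_dispersions(Y, matrix(1, n, 1), weights = W,
                               norm = libsize_size_factors(Y))
  expect_equal(disp$tagwise[1], disp$trend[1], tolerance = 0.35)
})
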