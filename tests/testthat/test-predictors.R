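# closed-form ridge oracle used against the rrBLUP path
ridge_oracle <- function(X, y, lambda, mu = mean(y)) {
  Xc <- sweep(X, 2, colMeans(X))
  drop(solve(crossprod(Xc) + lambda * diag(ncol(X)), crossprod(Xc, y - mu)))
}

test_that("rrBLUP solves the ridge system (fixed-lambda toy: beta = 2/3)", {
  d <- gp_dataset(c("a", "b"), "P",
                  matrix(c(0, 2), 2, 1, dimnames = list(NULL, "M1")),
                  c(-1, 1))
  fit <- fit_rrblup(d, lambda = 1)
  # centred X = (-1, 1)', y = (-1, 1): (X'X + 1)^{-1} X'y = 2/3
  expect_equal(unname(fit$beta["M1"]), 2 / 3, tolerance = 1e-10)
  expect_equal(fit$mu, 0, tolerance = 1e-10)

  d2 <- toy_dataset(n = 15, p = 4, seed = 2, y = rep(5, 15))
  fit2 <- fit_rrblup(d2)
  expect_equal(unname(fit2$beta), rep(0, 5))
  expect_equal(fit2$mu, 5)
  expect_equal(unname(predict(fit2, d2)), rep(5, 15))

  expect_error(fit_rrblup(subset_records(d, 1)), "2 records")
})

test_that("rrBLUP marker solution matches the dense GBLUP dual solve", {
  for (seed in 1:3) {
    d <- toy_dataset(n = 8, p = 6, seed = seed)
    lam <- c(0.5, 2, 10)[seed]
    fit <- fit_rrblup(d, lambda = lam)
    X <- feature_matrix(d)
    oracle <- ridge_oracle(X, d$y, lam, mu = fit$mu)
    expect_equal(unname(fit$beta), unname(oracle), tolerance = 1e-8)
  }
})

test_that("rrBLUP recovers a dense additive architecture (h2 = 0.9)", {
  set.seed(42)
  n <- 400; p <- 100
  G <- matrix(sample(0:2, n * p, replace = TRUE), n, p,
              dimnames = list(NULL, sprintf("M%04d", 1:p)))
  beta_true <- rnorm(p)
  g <- drop(G %*% beta_true)
  y <- g + rnorm(n, 0, sqrt(var(g) * (1 - 0.9) / 0.9))
  d <- gp_dataset(sprintf("R%03d", 1:n), "P", G, y)
  fit <- fit_rrblup(d)
  expect_gte(cor(fit$beta[1:p], beta_true), 0.8)
})

test_that("BayesB behaves on null data and recovers a single QTL", {
  d0 <- toy_dataset(n = 30, p = 6, seed = 3, y = rep(0, 30))
  f0 <- fit_bayesb(d0, n_iter = 1500, burn_in = 300, seed = 1)
  expect_true(all(abs(f0$beta) < 1e-8))

  d <- one_qtl_dataset(n = 150, p = 10, causal = 4, h2 = 0.9, seed = 5)
  f1 <- fit_bayesb(d, n_iter = 2000, burn_in = 500, seed = 11)
  expect_equal(which.max(abs(f1$beta[1:10])), c(M0004 = 4L))
  expect_equal(which.max(f1$inclusion_prob[1:10]), c(M0004 = 4L))

  # chain stability: an independent chain agrees on the causal ranking
  f2 <- fit_bayesb(d, n_iter = 2000, burn_in = 500, seed = 99)
  expect_equal(which.max(abs(f2$beta[1:10])), c(M0004 = 4L))

  expect_error(fit_bayesb(d, n_iter = 100, burn_in = 200), "exceed")
})

test_that("BayesB with spike off and fixed variances converges to ridge", {
  set.seed(6)
  d <- toy_dataset(n = 40, p = 5, seed = 6,
                   y = NULL)
  lam <- 2
  s2e <- 1
  fit <- fit_bayesb(d, n_iter = 6000, burn_in = 1000, seed = 7, pi = 1,
                    sigma2_beta = s2e / lam, sigma2_e = s2e)
  oracle <- ridge_oracle(feature_matrix(d), d$y, lam, mu = fit$mu)
  expect_equal(unname(fit$beta), unname(oracle), tolerance = 0.05)
})

test_that("gaussian_kernel matches the stated closed form", {
  x <- matrix(c(1, 2, 0), 1)
  expect_equal(drop(gaussian_kernel(x, x, h = 3)), 1)
  # x = (0,0), x' = (2,2), h = 1, p = 2 -> exp(-h * 8/2) = exp(-4)
  expect_equal(drop(gaussian_kernel(matrix(c(0, 0), 1), matrix(c(2, 2), 1),
                                    h = 1)),
               exp(-4), tolerance = 1e-12)
  A <- matrix(sample(0:2, 12, TRUE), 4, 3)
  K <- gaussian_kernel(A, A, h = 0.7)
  expect_equal(K, t(K))
  expect_true(all(K > 0 & K <= 1))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  expect_error(gaussian_kernel(A[, 0], A[, 0]), "at least one")
})

test_that("RKHS solves the kernel-ridge system and shrinks to the mean", {
  d <- toy_dataset(n = 15, p = 4, seed = 8, y = rep(3.5, 15))
  f0 <- fit_rkhs(d)
  expect_equal(unname(predict(f0, d)), rep(3.5, 15))

  d1 <- toy_dataset(n = 20, p = 5, seed = 9)
  fbig <- fit_rkhs(d1, lambda = 1e8)
  expect_equal(unname(predict(fbig, d1)), rep(mean(d1$y), 20),
               tolerance = 1e-3)

  # near-identity kernel (huge h): alpha = (y - mu) / (1 + lambda)
  d2 <- gp_dataset(c("a", "b"), "P",
                   matrix(c(0, 2, 2, 0), 2, 2,
                          dimnames = list(NULL, c("M1", "M2"))),
                   c(1, 3))
  f2 <- fit_rkhs(d2, h = 1e4, lambda = 1)
  expect_equal(f2$alpha, (d2$y - f2$mu) / 2, tolerance = 1e-8)
})

test_that("random forest honours its contract", {
  d <- toy_dataset(n = 30, p = 4, seed = 10, y = rep(2.5, 30))
  f0 <- fit_rf(d, n_trees = 20, seed = 1)
  expect_equal(unname(predict(f0, d)), rep(2.5, 30))

  # single depth-unbounded tree memorises unique genotypes
  set.seed(11)
  G <- unique(matrix(sample(0:2, 60 * 5, replace = TRUE), 60, 5))
  colnames(G) <- sprintf("M%04d", 1:5)
  d1 <- gp_dataset(sprintf("R%03d", seq_len(nrow(G))), "P", G,
                   rnorm(nrow(G)))
  f1 <- fit_rf(d1, n_trees = 1, bootstrap = FALSE, seed = 2)
  expect_equal(unname(predict(f1, d1)), d1$y, tolerance = 1e-10)

  d2 <- one_qtl_dataset(n = 100, seed = 12)
  fa <- fit_rf(d2, n_trees = 50, seed = 33)
  fb <- fit_rf(d2, n_trees = 50, seed = 33)
  expect_identical(predict(fa, d2), predict(fb, d2))
  expect_gte(cor(predict(fa, d2), d2$y), 0.8)
})

test_that("SVR fits constants, is duplication-invariant, tracks linear signal", {
  d0 <- toy_dataset(n = 20, p = 3, seed = 13, y = rep(4, 20))
  f0 <- fit_svr(d0)
  expect_true(all(abs(predict(f0, d0) - 4) <= f0$epsilon + 1e-6))

  set.seed(14)
  n <- 60
  G <- matrix(sample(0:2, n, replace = TRUE), n, 1,
              dimnames = list(NULL, "M0001"))
  y <- G[, 1] + rnorm(n, 0, 0.05)
  d1 <- gp_dataset(sprintf("R%03d", 1:n), "P", G, y)
  f1 <- fit_svr(d1)
  dup <- gp_dataset(c(sprintf("R%03d", 1:n), sprintf("S%03d", 1:n)), "P",
                    rbind(G, G), c(y, y))
  f2 <- fit_svr(dup)
  expect_equal(unname(predict(f1, d1)), unname(predict(f2, d1)),
               tolerance = 0.05)

  test <- gp_dataset(sprintf("T%02d", 1:30), "P",
                     matrix(sample(0:2, 30, TRUE), 30, 1,
                            dimnames = list(NULL, "M0001")),
                     rep(0, 30))
  test$y <- test$G[, 1]
  expect_gte(cor(predict(f1, test), test$y), 0.9)
})

test_that("GAT trains, attends to 1, and learns a strong QTL", {
  d <- one_qtl_dataset(n = 150, p = 10, causal = 4, h2 = 0.9, seed = 15)
  sp <- split_train_test(d, 0.8, seed = 16)
  fit <- fit_gat(sp$train, seed = 17)
  A <- gat_attention(fit, feature_matrix(sp$test))
  expect_equal(unname(rowSums(A)), rep(1, nrow(A)), tolerance = 1e-12)
  expect_true(all(A >= 0))
  expect_gte(cor(predict(fit, sp$test), sp$test$y), 0.5)

  d0 <- toy_dataset(n = 40, p = 4, seed = 18, y = rep(7, 40))
  f0 <- fit_gat(d0, seed = 19)
  expect_lte(mean((predict(f0, d0) - 7)^2), 0.01 * (0 + 1))
})

test_that("all models return finite predictions and are seed-reproducible", {
  d <- one_qtl_dataset(n = 60, p = 6, seed = 20)
  sp <- split_train_test(d, 0.7, seed = 21)
  fits <- list(
    fit_rrblup(sp$train),
    fit_bayesb(sp$train, n_iter = 600, burn_in = 100, seed = 1),
    fit_rkhs(sp$train),
    fit_rf(sp$train, n_trees = 30, seed = 1),
    fit_svr(sp$train),
    fit_gat(sp$train, epochs = 10, seed = 1))
  for (f in fits) {
    pr <- predict(f, sp$test)
    expect_length(pr, n_records_public(sp$test))
    expect_true(all(is.finite(pr)))
    expect_true(all(is.finite(predict(f, sp$train))))
  }
  f2 <- fit_bayesb(sp$train, n_iter = 600, burn_in = 100, seed = 1)
  expect_identical(fits[[2]]$beta, f2$beta)
  g2 <- fit_gat(sp$train, epochs = 10, seed = 1)
  expect_identical(fits[[6]]$par, g2$par)
})
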