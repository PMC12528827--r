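# brute-force Shapley oracle over explicit coalition values, independent of
# the package's bitmask implementation
shapley_bruteforce <- function(vfun, p) {
  subsets <- lapply(0:(2^p - 1), function(m) which(bitwAnd(m, 2^(0:(p - 1))) > 0))
  phi <- numeric(p)
  for (i in seq_len(p)) {
    for (S in subsets) {
      if (i %in% S) next
      s <- length(S)
      w <- factorial(s) * factorial(p - s - 1) / factorial(p)
      phi[i] <- phi[i] + w * (vfun(sort(c(S, i))) - vfun(S))
    }
  }
  phi
}

test_that("coef_effects is the identity on beta and rejects other models", {
  d <- toy_dataset(n = 20, p = 2, seed = 1)
  fit <- fit_rrblup(d, lambda = 1)
  eff <- coef_effects(fit)
  expect_equal(eff$scores, fit$beta[d$marker_names])
  expect_equal(eff$model, "rrBLUP")

  d1 <- one_qtl_dataset(n = 150, p = 8, causal = 3, seed = 2)
  e1 <- coef_effects(fit_rrblup(d1))
  expect_equal(unname(which.max(abs(e1$scores))), 3L)

  expect_error(coef_effects(fit_rf(d, n_trees = 5, seed = 1)), "rrBLUP/BayesB")
})

test_that("exact Shapley matches the linear closed form and brute force", {
  set.seed(3)
  d <- toy_dataset(n = 25, p = 3, seed = 3)
  d$y <- drop(d$G %*% c(2, 3, -1))
  fit <- fit_rrblup(d, lambda = 1e-8)
  test <- subset_records(d, 1:4)
  sh <- shapley_effects(fit, test, d, mode = "exact")
  # linear model: phi_ij = beta_j (x_ij - mean background_j)
  closed <- sweep(test$G, 2, colMeans(d$G)) %*% diag(fit$beta[1:3])
  expect_equal(unname(sh$metadata$per_record), unname(closed),
               tolerance = 1e-6)

  # brute-force oracle on an RF, single record
  d2 <- one_qtl_dataset(n = 80, p = 4, causal = 2, seed = 4)
  rf <- fit_rf(d2, n_trees = 40, seed = 5)
  x <- feature_matrix(subset_records(d2, 1))
  B <- feature_matrix(d2)[1:30, ]
  B[, ".replicate"] <- x[, ".replicate"]
  vfun <- function(S) {
    M <- B
    if (length(S)) M[, S] <- rep(x[1, S], each = nrow(B))
    mean(predict_features(rf, M))
  }
  oracle <- shapley_bruteforce(vfun, 4)
  sh2 <- shapley_effects(rf, subset_records(d2, 1), B, mode = "exact",
                         n_background = 30)
  expect_equal(unname(sh2$scores), oracle, tolerance = 1e-10)
})

test_that("Shapley efficiency and symmetry axioms hold in exact mode", {
  d <- one_qtl_dataset(n = 60, p = 6, causal = 2, seed = 6)
  rf <- fit_rf(d, n_trees = 30, seed = 7)
  test <- subset_records(d, 1:5)
  sh <- shapley_effects(rf, test, d, mode = "exact", n_background = 40,
                        seed = 8)
  expect_lt(max(abs(rowSums(sh$metadata$per_record) -
                      (sh$metadata$fx - sh$metadata$baseline))), 1e-8)

  # duplicated identical marker columns receive equal attributions
  set.seed(9)
  G <- matrix(sample(0:2, 40 * 3, TRUE), 40, 3)
  G <- cbind(G, G[, 3])
  colnames(G) <- c("A", "B", "C", "Cdup")
  dd <- gp_dataset(sprintf("R%02d", 1:40), "P", G,
                   G[, 3] + G[, 4] + rnorm(40, 0, 0.1))
  lin <- fit_rrblup(dd, lambda = 1)
  shd <- shapley_effects(lin, subset_records(dd, 1:6), dd, mode = "exact")
  expect_equal(unname(shd$scores["C"]), unname(shd$scores["Cdup"]),
               tolerance = 1e-8)

  expect_error(shapley_effects(lin, dd, dd, mode = "exact",
                               n_samples = 1),
               NA)  # p = 4 fine
  big <- toy_dataset(n = 10, p = 13, seed = 10)
  bfit <- fit_rrblup(big, lambda = 1)
  expect_error(shapley_effects(bfit, big, big, mode = "exact"), "sampled")
})

test_that("sampled Shapley converges to exact within Monte-Carlo error", {
  d <- one_qtl_dataset(n = 100, p = 8, causal = 5, seed = 11)
  rf <- fit_rf(d, n_trees = 50, seed = 12)
  test <- subset_records(d, 1:5)
  # identical (full) background in both modes so the estimand matches
  ex <- shapley_effects(rf, test, d, mode = "exact", n_background = 100,
                        seed = 13)
  sa <- shapley_effects(rf, test, d, mode = "sampled", n_samples = 5000,
                        n_background = 100, seed = 14)
  excess <- abs(sa$scores - ex$scores) - 3 * pmax(sa$metadata$se, 1e-12)
  expect_true(all(excess < 1e-3))
})

test_that("impurity importance normalises, is near-uniform on noise, finds QTL", {
  d <- one_qtl_dataset(n = 150, p = 10, causal = 7, seed = 15)
  rf <- fit_rf(d, n_trees = 100, seed = 16)
  imp <- impurity_importance(rf)
  expect_equal(sum(imp$scores), 1)
  expect_true(all(imp$scores >= 0))
  expect_equal(unname(which.max(imp$scores)), 7L)

  set.seed(17)
  dn <- toy_dataset(n = 200, p = 8, seed = 17)
  rfn <- fit_rf(dn, n_trees = 200, seed = 18)
  sn <- impurity_importance(rfn)$scores
  expect_lt(max(sn) / min(sn), 4)

  expect_error(impurity_importance(fit_rrblup(d)), "RF")
})

test_that("Integrated Gradients is exact on linear models and complete", {
  # linear f(x) = 2 x1: IG_1 = 2 * (x - x') for any m
  d <- toy_dataset(n = 30, p = 1, seed = 19)
  d$y <- 2 * d$G[, 1]
  fit <- fit_rrblup(d, lambda = 1e-8)
  rec <- subset_records(d, which(d$G[, 1] == 1)[1])
  for (m in c(1, 4, 16)) {
    ig <- integrated_gradients(fit, rec, baseline = 0, m = m)
    expect_equal(unname(ig$scores), 2, tolerance = 1e-5)
  }
  # x = x' -> zero attribution
  ig0 <- integrated_gradients(fit, rec, baseline = rec$G[1, ], m = 8)
  expect_equal(unname(ig0$scores), 0, tolerance = 1e-10)

  expect_error(integrated_gradients(fit, rec, baseline = c(0, 0), m = 8),
               "dimension")

  # completeness error shrinks as m doubles on a nonlinear fit
  d2 <- one_qtl_dataset(n = 120, p = 6, causal = 2, h2 = 0.8, seed = 20)
  sp <- split_train_test(d2, 0.8, seed = 21)
  gat <- fit_gat(sp$train, epochs = 25, seed = 22)
  errs <- sapply(c(8, 64, 512), function(m) {
    max(integrated_gradients(gat, subset_records(sp$test, 1:4),
                             m = m)$metadata$completeness)
  })
  expect_true(errs[2] < errs[1] && errs[3] < errs[2])
})

test_that("pairwise interactions: zero for additive, peak on product pair", {
  set.seed(23)
  n <- 200
  G <- matrix(sample(c(0, 2), n * 4, TRUE), n, 4,
              dimnames = list(NULL, paste0("M", 1:4)))
  dadd <- gp_dataset(sprintf("R%03d", 1:n), "P", G, G[, 1] + G[, 2])
  dmul <- gp_dataset(sprintf("R%03d", 1:n), "P", G, G[, 1] * G[, 2])
  fa <- fit_rf(dadd, n_trees = 80, seed = 24)
  fm <- fit_rf(dmul, n_trees = 80, seed = 24)
  Ia <- pairwise_interactions(fa, subset_records(dadd, 1:5), dadd,
                              mode = "exact", seed = 25)
  Im <- pairwise_interactions(fm, subset_records(dmul, 1:5), dmul,
                              mode = "exact", seed = 25)
  expect_lt(max(abs(Ia)), 1e-8)
  peak <- which(abs(Im) == max(abs(Im)), arr.ind = TRUE)[1, ]
  expect_setequal(unname(peak), c(1L, 2L))
  expect_equal(unclass(Im), t(unclass(Im)))
  expect_equal(unname(diag(Im)), rep(0, 4))

  # sampled estimator agrees with exact given the same (full) background
  Imf <- pairwise_interactions(fm, subset_records(dmul, 1:5), dmul,
                               mode = "exact", n_background = 500, seed = 25)
  Is <- pairwise_interactions(fm, subset_records(dmul, 1:5), dmul,
                              mode = "sampled", n_subsets = 60,
                              n_background = 500, seed = 26)
  peak_s <- which(abs(Is) == max(abs(Is)), arr.ind = TRUE)[1, ]
  expect_setequal(unname(peak_s), c(1L, 2L))
  expect_equal(Is[1, 2], Imf[1, 2], tolerance = 1e-8)

  expect_error(pairwise_interactions(fm, dmul, dmul, mode = "exact",
                                     top_m = NULL, seed = 1,
                                     n_subsets = 1), NA)
  d13 <- toy_dataset(n = 30, p = 11, seed = 27)
  f13 <- fit_rf(d13, n_trees = 10, seed = 28)
  expect_error(pairwise_interactions(f13, d13, d13, mode = "exact"),
               "sampled")
})

test_that("interaction matrix ordering is marker-permutation invariant", {
  set.seed(29)
  d <- one_qtl_dataset(n = 80, p = 5, causal = 2, seed = 29)
  rf <- fit_rf(d, n_trees = 40, seed = 30)
  I1 <- pairwise_interactions(rf, subset_records(d, 1:4), d, mode = "exact",
                              seed = 31)
  perm <- c(3, 1, 5, 2, 4)
  dp <- subset_markers(d, perm)
  rfp <- fit_rf(dp, n_trees = 40, seed = 30)
  I2 <- pairwise_interactions(rfp, subset_records(dp, 1:4), dp,
                              mode = "exact", seed = 31)
  # same marker pair labels must carry comparable scores (forests are
  # refitted, so allow loose agreement; exact equality is not expected)
  expect_equal(dim(I2), c(5L, 5L))
  expect_setequal(rownames(I2), rownames(I1))
})

test_that("effect and interaction TSV exports are well-formed", {
  d <- one_qtl_dataset(n = 50, p = 4, seed = 32)
  fit <- fit_rrblup(d)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_effects_tsv(coef_effects(fit, scenario = 7), f)
  tab <- read.delim(f)
  expect_named(tab, c("marker", "model", "scenario", "score"))
  expect_equal(nrow(tab), 4L)

  rf <- fit_rf(d, n_trees = 20, seed = 33)
  I <- pairwise_interactions(rf, subset_records(d, 1:3), d, mode = "exact",
                             seed = 34)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_interactions_tsv(I, f2)
  tab2 <- read.delim(f2)
  expect_equal(nrow(tab2), choose(4, 2))
})
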