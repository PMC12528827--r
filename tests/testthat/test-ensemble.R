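test_that("build_scenarios enumerates the grid with distinct derived seeds", {
  sc <- build_scenarios(c("A", "B"), c(0.8, 0.5), 3, base_seed = 7)
  expect_equal(nrow(sc), 2 * 2 * 3)
  expect_false(anyDuplicated(sc$seed) > 0)

  sc1 <- build_scenarios("A", 0.5, 1, base_seed = 1)
  expect_equal(nrow(sc1), 1L)

  sc2 <- build_scenarios(c("A", "B"), c(0.8, 0.5), 3, base_seed = 7)
  expect_identical(sc$seed, sc2$seed)

  expect_error(build_scenarios("A", 1.2, 5), "\\(0, 1\\)")
  expect_error(build_scenarios(character(0), 0.5, 5), "empty")
})

test_that("split_train_test uses floor(fraction * N) and is deterministic", {
  d <- toy_dataset(n = 10, seed = 1)
  sp <- split_train_test(d, 0.5, seed = 3)
  expect_equal(n_records_public(sp$train), 5L)
  expect_equal(n_records_public(sp$test), 5L)
  expect_setequal(c(sp$train$ids, sp$test$ids), d$ids)
  expect_length(intersect(sp$train$ids, sp$test$ids), 0)

  sp2 <- split_train_test(d, 0.5, seed = 3)
  expect_identical(sp$train$ids, sp2$train$ids)

  expect_error(split_train_test(d, 0.01, seed = 1), "degenerate")

  # id-grouped option keeps both replicates of a line together
  dr <- concat_replicates(toy_dataset(n = 6, seed = 2),
                          toy_dataset(n = 6, seed = 2))
  spg <- split_train_test(dr, 0.5, seed = 4, by_id = TRUE)
  expect_length(intersect(unique(spg$train$ids), unique(spg$test$ids)), 0)
})

test_that("pearson_r and mse follow their definitions", {
  x <- c(1, 2, 3)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(mse(x, x), 0)
  expect_equal(pearson_r(-(x - 2), x - 2), -1)
  expect_equal(mse(c(1, 2, 3), c(1, 2, 4)), 1 / 3)
  expect_error(pearson_r(x, c(2, 2, 2)), "constant")
  expect_error(mse(x, c(1, 2)), "mismatch")
})

test_that("ensemble_predict is the element-wise equal-weight mean", {
  expect_equal(ensemble_predict(list(2, 4)), 3)
  expect_equal(ensemble_predict(list(c(1, 5))), c(1, 5))
  set.seed(5)
  P <- replicate(6, rnorm(20), simplify = FALSE)
  expect_equal(ensemble_predict(P),
               sapply(1:20, function(i) mean(sapply(P, `[`, i))))
  expect_error(ensemble_predict(list(1:3, 1:4)), "misaligned")
})

test_that("diversity decomposition identity holds exactly", {
  out <- diversity_decomposition(list(2, 4), 3)
  expect_equal(out, list(ensemble_sq_err = 0, mean_individual_sq_err = 1,
                         diversity = 1))

  p <- rnorm(10)
  same <- diversity_decomposition(list(p, p, p), rnorm(10))
  expect_equal(same$diversity, 0)
  expect_equal(same$ensemble_sq_err, same$mean_individual_sq_err)

  for (seed in 1:5) {
    set.seed(seed)
    P <- replicate(6, rnorm(50), simplify = FALSE)
    obs <- rnorm(50)
    dd <- diversity_decomposition(P, obs)
    expect_equal(dd$ensemble_sq_err,
                 dd$mean_individual_sq_err - dd$diversity,
                 tolerance = 1e-10)
    expect_lte(dd$ensemble_sq_err, dd$mean_individual_sq_err + 1e-12)
  }
  expect_error(diversity_decomposition(list(1:3), 1:3), "two models")
})

test_that("normalize_effects maps |score| to min-max [0, 1]", {
  pr <- gp_effects("rrBLUP", c(a = 1, b = 3, c = 5))
  expect_equal(normalize_effects(pr)$scores, c(a = 0, b = 0.5, c = 1))
  prc <- gp_effects("rrBLUP", c(a = 2, b = 2))
  expect_equal(normalize_effects(prc)$scores, c(a = 0, b = 0))
  prs <- gp_effects("rrBLUP", c(a = -5, b = 0, c = 5))
  expect_equal(normalize_effects(prs)$scores, c(a = 1, b = 0, c = 1))
})

test_that("ensemble_effects averages aligned normalised profiles", {
  p1 <- gp_effects("rrBLUP", c(a = 0, b = 1))
  p2 <- gp_effects("RF", c(a = 1, b = 0))
  out <- ensemble_effects(list(p1, p2))
  expect_equal(out$scores, c(a = 0.5, b = 0.5))
  expect_equal(out$model, "Ensemble")

  expect_equal(ensemble_effects(list(p1, p1))$scores, p1$scores)

  set.seed(6)
  profs <- lapply(1:6, function(i)
    gp_effects(paste0("m", i), setNames(runif(4), letters[1:4])))
  out6 <- ensemble_effects(profs)
  brute <- rowMeans(sapply(profs, `[[`, "scores"))
  expect_equal(out6$scores, brute)

  p3 <- gp_effects("SVR", c(a = 1, z = 0))
  expect_error(ensemble_effects(list(p1, p3)), "differ")
})

test_that("aggregate_scenarios means effects with NA-skipping presence", {
  mk_res <- function(scores_rr, scores_rf, ens, inter = NULL) {
    list(effects = list(gp_effects("rrBLUP", scores_rr),
                        gp_effects("RF", scores_rf)),
         ensemble_effect = gp_effects("Ensemble", ens),
         interactions = inter,
         metrics = data.frame(scenario = 1, model = "rrBLUP", r_test = 0.5))
  }
  r1 <- mk_res(c(a = 0.2, b = 0.6), c(a = 0.1, b = 0.2), c(a = 0, b = 1))
  r2 <- mk_res(c(a = 0.4, b = 0.2), c(a = 0.3, b = 0.4), c(a = 1, b = 0))
  agg <- aggregate_scenarios(list(r1, r2))
  expect_equal(agg$effects$rrBLUP[["a"]], 0.3)
  expect_equal(agg$ensemble$scores, c(a = 0.5, b = 0.5))

  # single scenario = identity
  agg1 <- aggregate_scenarios(list(r1))
  expect_equal(agg1$effects$rrBLUP, c(a = 0.2, b = 0.6))

  # marker absent from one scenario: averaged where present, count reported
  r3 <- mk_res(c(a = 0.8), c(a = 0.5), c(a = 1))
  agg2 <- aggregate_scenarios(list(r1, r3))
  expect_equal(agg2$effects$rrBLUP[["b"]], 0.6)
  expect_equal(unname(agg2$presence$rrBLUP["b"]), 1)
  expect_equal(unname(agg2$presence$rrBLUP["a"]), 2)

  # random instance equals brute-force NA-skipping mean
  set.seed(7)
  rs <- lapply(1:10, function(i) {
    keep <- sample(letters[1:5], sample(3:5, 1))
    v <- setNames(runif(length(keep)), keep)
    mk_res(v, v, v)
  })
  agg3 <- aggregate_scenarios(rs)
  mat <- sapply(rs, function(r) {
    out <- setNames(rep(NA_real_, 5), letters[1:5])
    s <- r$effects[[1]]$scores
    out[names(s)] <- s
    out
  })
  expect_equal(agg3$effects$rrBLUP[letters[1:5]],
               rowMeans(mat, na.rm = TRUE))

  expect_error(aggregate_scenarios(list()), "no scenario")
})

test_that("run_scenario produces aligned outputs and the ensemble bound", {
  d <- one_qtl_dataset(n = 80, p = 8, causal = 3, h2 = 0.8, seed = 8)
  cfg <- easigp_config(models = c("rrBLUP", "RF"), ratios = 0.75,
                       rf = list(n_trees = 40),
                       interactions = list(n_subsets = 4, n_background = 10,
                                           top_m = 4, max_records = 3))
  res <- run_scenario(d, 0.75, seed = 9, config = cfg, scenario_id = 1)
  expect_equal(sort(unique(res$metrics$model)),
               sort(c("rrBLUP", "RF", "Ensemble")))
  expect_true(all(is.finite(res$metrics$r_test)))
  expect_lte(res$diversity$ensemble_sq_err,
             res$diversity$mean_individual_sq_err + 1e-12)
  expect_s3_class(res$ensemble_effect, "gp_effects")
  expect_true(!is.null(res$interactions))
})
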