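#' Default EasiGP run configuration
#'
#' Nested list of every tunable in the pipeline, with the published defaults:
#' train fractions 0.8/0.65/0.5, 500 repeats per combination, BayesB chain
#' 12000/2000, RKHS bandwidth 1, 1000 forest trees, GAT 20 channels trained
#' 50 epochs (batch 8, lr 0.005, weight decay 0), LD pruning window 30000 /
#' step 5 / r^2 0.8, sampled-Shapley and interaction sampling sizes.
#'
#' @param ... named overrides, e.g. `easigp_config(n_repeats = 10)` or nested
#'   `easigp_config(rf = list(n_trees = 100))` (lists are merged).
#' @return A list of class `easigp_config`.
#' @export
easigp_config <- function(...) {
  cfg <- list(
    models = c("rrBLUP", "BayesB", "RKHS", "RF", "SVR", "GAT"),
    ratios = c(0.8, 0.65, 0.5),
    n_repeats = 500,
    base_seed = 1,
    ld = list(enabled = TRUE, window = 30000, step = 5, r2_threshold = 0.8),
    impute = list(max_missing_frac = 0.10, per_population = TRUE),
    bayesb = list(n_iter = 12000, burn_in = 2000, df0 = 5),
    rkhs = list(h = 1),
    rf = list(n_trees = 1000, mtry = NULL, min_split = 2, max_depth = 0),
    svr = list(cost = 1, epsilon = 0.1, gamma = NULL),
    gat = list(channels = 20, epochs = 50, batch = 8, lr = 0.005,
               weight_decay = 0),
    shapley = list(n_samples = 2000, n_background = 100, max_records = Inf),
    ig = list(m = 64),
    interactions = list(enabled = TRUE, n_subsets = 30, n_background = 20,
                        top_m = NULL, max_records = 10),
    split_by_id = FALSE)
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  class(cfg) <- "easigp_config"
  cfg
}

#' Read a YAML run configuration
#'
#' Keys mirror [easigp_config()]; unspecified keys keep their defaults.
#'
#' @param path YAML file path.
#' @return An `easigp_config`.
#' @export
read_config <- function(path) {
  do.call(easigp_config, yaml::read_yaml(path))
}

#' @export
print.easigp_config <- function(x, ...) {
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

fit_one_model <- function(tag, train, cfg, seed) {
  switch(tag,
    rrBLUP = fit_rrblup(train),
    BayesB = fit_bayesb(train, n_iter = cfg$bayesb$n_iter,
                        burn_in = cfg$bayesb$burn_in, seed = seed,
                        df0 = cfg$bayesb$df0),
    RKHS = fit_rkhs(train, h = cfg$rkhs$h),
    RF = fit_rf(train, n_trees = cfg$rf$n_trees, mtry = cfg$rf$mtry,
                min_split = cfg$rf$min_split, max_depth = cfg$rf$max_depth,
                seed = seed),
    SVR = fit_svr(train, cost = cfg$svr$cost, epsilon = cfg$svr$epsilon,
                  gamma = cfg$svr$gamma),
    GAT = fit_gat(train, channels = cfg$gat$channels, epochs = cfg$gat$epochs,
                  batch = cfg$gat$batch, lr = cfg$gat$lr,
                  weight_decay = cfg$gat$weight_decay, seed = seed),
    stop("unknown model tag: ", tag))
}

effects_for_model <- function(tag, fit, train, test, cfg, seed, scenario_id) {
  sub <- test
  if (is.finite(cfg$shapley$max_records) &&
      n_records(test) > cfg$shapley$max_records) {
    set.seed(seed)
    sub <- subset_records(test, sort(sample.int(n_records(test),
                                                cfg$shapley$max_records)))
  }
  switch(tag,
    rrBLUP = coef_effects(fit, scenario_id),
    BayesB = coef_effects(fit, scenario_id),
    RF = impurity_importance(fit, scenario_id),
    RKHS = ,
    SVR = shapley_effects(fit, sub, train, mode = "sampled",
                          n_samples = cfg$shapley$n_samples,
                          n_background = cfg$shapley$n_background,
                          seed = seed, scenario = scenario_id),
    GAT = integrated_gradients(fit, sub, m = cfg$ig$m,
                               scenario = scenario_id),
    stop("unknown model tag: ", tag))
}

#' Run one prediction scenario
#'
#' Splits the (single-population) dataset, re-runs LD pruning on the training
#' set, fits the configured models, computes Pearson r and MSE on train and
#' test, infers the per-model marker-effect profiles and the forest's pairwise
#' interaction matrix, and forms the equal-weight ensemble predictions and
#' normalised ensemble effect profile.
#'
#' @param d the population's [gp_dataset()] (imputed, phenotypes complete).
#' @param train_fraction train split fraction.
#' @param seed scenario seed.
#' @param config an [easigp_config()].
#' @param scenario_id scenario identifier carried into the profiles.
#' @return List with `metrics` (data frame), `predictions`, `effects` (list
#'   of [gp_effects()]), `ensemble_effect`, `interactions` (matrix or NULL),
#'   `diversity`.
#' @export
run_scenario <- function(d, train_fraction, seed, config = easigp_config(),
                         scenario_id = NA) {
  cfg <- config
  sp <- split_train_test(d, train_fraction, seed, by_id = cfg$split_by_id)
  train <- sp$train; test <- sp$test
  if (isTRUE(cfg$ld$enabled)) {
    train <- ld_prune(train, cfg$ld$window, cfg$ld$step, cfg$ld$r2_threshold)
    test <- subset_markers(test, train$marker_names)
  }
  preds_test <- list(); preds_train <- list()
  effects <- list(); metrics <- list()
  interactions <- NULL
  for (tag in cfg$models) {
    mseed <- derive_seed(seed, tag)
    fit <- fit_one_model(tag, train, cfg, mseed)
    pt <- predict(fit, test); ptr <- predict(fit, train)
    preds_test[[tag]] <- pt; preds_train[[tag]] <- ptr
    metrics[[tag]] <- data.frame(
      scenario = scenario_id, model = tag,
      r_train = pearson_r(ptr, train$y), mse_train = mse(ptr, train$y),
      r_test = pearson_r(pt, test$y), mse_test = mse(pt, test$y),
      stringsAsFactors = FALSE)
    effects[[tag]] <- effects_for_model(tag, fit, train, test, cfg, mseed,
                                        scenario_id)
    if (tag == "RF" && isTRUE(cfg$interactions$enabled)) {
      interactions <- pairwise_interactions(
        fit, test, train, mode = "sampled",
        n_subsets = cfg$interactions$n_subsets,
        n_background = cfg$interactions$n_background,
        top_m = cfg$interactions$top_m,
        max_records = cfg$interactions$max_records,
        seed = derive_seed(seed, "interactions"))
    }
  }
  ens_test <- ensemble_predict(preds_test)
  ens_train <- ensemble_predict(preds_train)
  metrics$Ensemble <- data.frame(
    scenario = scenario_id, model = "Ensemble",
    r_train = pearson_r(ens_train, train$y),
    mse_train = mse(ens_train, train$y),
    r_test = pearson_r(ens_test, test$y), mse_test = mse(ens_test, test$y),
    stringsAsFactors = FALSE)
  div <- if (length(cfg$models) >= 2L) {
    diversity_decomposition(preds_test, test$y)
  } else NULL
  if (!is.null(div)) {
    stopifnot(div$ensemble_sq_err <= div$mean_individual_sq_err + 1e-8)
  }
  ens_eff <- ensemble_effects(lapply(effects, normalize_effects))
  list(metrics = do.call(rbind, c(metrics, make.row.names = FALSE)),
       predictions = list(test = preds_test, train = preds_train,
                          ensemble_test = ens_test),
       effects = unname(effects), ensemble_effect = ens_eff,
       interactions = interactions, diversity = div)
}

#' Run the full EasiGP scenario grid
#'
#' Drives the population x ratio x repeat grid over a preprocessed dataset
#' and aggregates marker effects, interactions and metrics across scenarios.
#'
#' @param d a preprocessed [gp_dataset()] (may contain several populations).
#' @param config an [easigp_config()].
#' @param verbose print progress.
#' @return List of class `easigp_run` with `aggregate`, `results`,
#'   `scenarios`, `config`.
#' @export
run_easigp <- function(d, config = easigp_config(), verbose = FALSE) {
  cfg <- config
  pops <- unique(d$population)
  scen <- build_scenarios(pops, cfg$ratios, cfg$n_repeats, cfg$base_seed)
  results <- vector("list", nrow(scen))
  for (i in seq_len(nrow(scen))) {
    if (verbose) message("scenario ", i, "/", nrow(scen))
    di <- subset_records(d, which(d$population == scen$population[i]))
    results[[i]] <- run_scenario(di, scen$train_fraction[i], scen$seed[i],
                                 cfg, scenario_id = scen$scenario[i])
  }
  structure(list(aggregate = aggregate_scenarios(results), results = results,
                 scenarios = scen, config = cfg),
            class = "easigp_run")
}

#' Write the standard run outputs
#'
#' `metrics.tsv`, `effects.tsv`, `interactions.tsv`, `scenarios.tsv` and a
#' JSON `manifest.json` (config echo, seeds, package version).
#'
#' @param run an `easigp_run`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  agg <- run$aggregate
  utils::write.table(agg$metrics, file.path(dir, "metrics.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  eff <- do.call(rbind, c(
    lapply(names(agg$effects), function(mod) {
      v <- agg$effects[[mod]]
      data.frame(marker = names(v), model = mod, scenario = "aggregate",
                 score = unname(v), stringsAsFactors = FALSE)
    }),
    list(data.frame(marker = names(agg$ensemble$scores), model = "Ensemble",
                    scenario = "aggregate",
                    score = unname(agg$ensemble$scores),
                    stringsAsFactors = FALSE))))
  eff <- eff[!is.na(eff$score), ]
  utils::write.table(eff, file.path(dir, "effects.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(agg$interactions)) {
    write_interactions_tsv(agg$interactions, file.path(dir, "interactions.tsv"))
  }
  utils::write.table(run$scenarios, file.path(dir, "scenarios.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(package = "easigp",
                   version = as.character(utils::packageVersion("easigp")),
                   config = unclass(run$config),
                   n_scenarios = nrow(run$scenarios))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(dir)
}
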