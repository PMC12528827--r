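# deterministic 31-bit seed derived from the base seed and scenario labels
# (exact integer arithmetic in doubles, so reproducible everywhere)
derive_seed <- function(base_seed, ...) {
  s <- paste(c(base_seed, ...), collapse = "|")
  h <- 5381
  for (cc in utf8ToInt(s)) h <- (h * 33 + cc) %% 2147483647
  as.integer(max(h, 1))
}

#' Build the prediction-scenario grid
#'
#' One scenario per combination of population, train/test ratio and repeat
#' index, each with a deterministic derived seed.
#'
#' @param populations character vector of population labels.
#' @param ratios train fractions, each in (0, 1) (defaults 0.8, 0.65, 0.5).
#' @param n_repeats random splits per combination (default 500).
#' @param base_seed integer base seed.
#' @return Data frame of class `gp_scenarios` with columns `scenario`,
#'   `population`, `train_fraction`, `repeat_index`, `seed`.
#' @export
build_scenarios <- function(populations, ratios = c(0.8, 0.65, 0.5),
                            n_repeats = 500, base_seed = 1) {
  if (!length(populations) || !length(ratios)) stop("empty scenario axis")
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  if (any(ratios <= 0 | ratios >= 1)) stop("train fractions must lie in (0, 1)")
  grid <- expand.grid(repeat_index = seq_len(n_repeats),
                      train_fraction = ratios,
                      population = populations,
                      stringsAsFactors = FALSE)[, 3:1]
  grid$seed <- mapply(function(p, f, r) derive_seed(base_seed, p, f, r),
                      grid$population, grid$train_fraction, grid$repeat_index)
  grid <- cbind(scenario = seq_len(nrow(grid)), grid)
  stopifnot(nrow(grid) ==
              length(populations) * length(ratios) * n_repeats)
  class(grid) <- c("gp_scenarios", class(grid))
  grid
}

#' Random train/test split of a dataset
#'
#' Record-level seeded shuffle: `floor(train_fraction * N)` records train,
#' the complement tests (e.g. 444 records at 0.8 give 355/89).
#'
#' @param d a [gp_dataset()].
#' @param train_fraction fraction in (0, 1).
#' @param seed integer seed.
#' @param by_id if `TRUE`, split whole lines (both replicate records of an id
#'   fall on the same side) instead of records.
#' @return List with elements `train` and `test` ([gp_dataset()]s).
#' @export
split_train_test <- function(d, train_fraction, seed = NULL, by_id = FALSE) {
  n <- n_records(d)
  if (n < 1L) stop("empty dataset")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie in (0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  if (by_id) {
    ids <- unique(d$ids)
    k <- floor(train_fraction * length(ids))
    if (k == 0L || k == length(ids)) stop("degenerate split")
    tr_ids <- sample(ids, k)
    tr <- which(d$ids %in% tr_ids)
  } else {
    k <- floor(train_fraction * n)
    if (k == 0L || k == n) stop("degenerate split")
    tr <- sample.int(n, k)
  }
  list(train = subset_records(d, sort(tr)),
       test = subset_records(d, sort(setdiff(seq_len(n), tr))))
}

#' Pearson correlation between predictions and observations
#' @param pred,obs numeric vectors of equal length (>= 2).
#' @return Correlation coefficient.
#' @export
pearson_r <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("length mismatch")
  if (length(obs) < 2L) stop("need at least 2 observations")
  if (stats::sd(obs) == 0) stop("correlation undefined for constant observations")
  stats::cor(pred, obs)
}

#' Mean squared error
#' @param pred,obs numeric vectors of equal length.
#' @return Mean of squared differences.
#' @export
mse <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("length mismatch")
  mean((pred - obs)^2)
}

#' Naive ensemble-average prediction
#'
#' Equal-weight element-wise mean of the individual models' predictions.
#'
#' @param per_model_predictions list (or matrix with one column per model)
#'   of aligned prediction vectors.
#' @return Numeric mean prediction vector.
#' @export
ensemble_predict <- function(per_model_predictions) {
  P <- if (is.list(per_model_predictions)) {
    lens <- lengths(per_model_predictions)
    if (length(unique(lens)) != 1L) stop("misaligned prediction vectors")
    do.call(cbind, per_model_predictions)
  } else as.matrix(per_model_predictions)
  if (ncol(P) < 1L) stop("need at least one model")
  rowMeans(P)
}

#' Diversity decomposition of the ensemble error
#'
#' For the equal-weight ensemble the identity
#' `ensemble_sq_err = mean_individual_sq_err - diversity` holds exactly,
#' where diversity is the mean squared deviation of the individual
#' predictions from the ensemble prediction. Hence the ensemble squared
#' error never exceeds the models' mean squared error.
#'
#' @param per_model_predictions list/matrix of aligned prediction vectors
#'   (>= 2 models).
#' @param obs observed values.
#' @return List with `ensemble_sq_err`, `mean_individual_sq_err`,
#'   `diversity` (means over records).
#' @export
diversity_decomposition <- function(per_model_predictions, obs) {
  P <- if (is.list(per_model_predictions)) do.call(cbind, per_model_predictions)
  else as.matrix(per_model_predictions)
  if (ncol(P) < 2L) stop("need at least two models")
  ens <- rowMeans(P)
  list(ensemble_sq_err = mean((ens - obs)^2),
       mean_individual_sq_err = mean(colMeans((P - obs)^2)),
       diversity = mean(colMeans((P - ens)^2)))
}

#' Normalise an effect profile within a scenario
#'
#' Scores are mapped to magnitudes and min-max scaled to [0, 1] within the
#' profile, putting signed (coefficients, Shapley, Integrated Gradients) and
#' unsigned (impurity) profiles on a common scale; constant profiles map to
#' all zero.
#'
#' @param profile a [gp_effects()].
#' @return The normalised [gp_effects()].
#' @export
normalize_effects <- function(profile) {
  a <- abs(profile$scores)
  rng <- range(a)
  s <- if (diff(rng) == 0) a * 0 else (a - rng[1L]) / diff(rng)
  gp_effects(profile$model, s, profile$scenario,
             c(profile$metadata, list(normalized = TRUE)))
}

#' Ensemble marker-effect profile
#'
#' Arithmetic mean of the individual models' normalised profiles.
#'
#' @param per_model_normalized_profiles list of [gp_effects()] with aligned
#'   marker sets (normalise first with [normalize_effects()]).
#' @return A [gp_effects()] tagged `"Ensemble"`.
#' @export
ensemble_effects <- function(per_model_normalized_profiles) {
  prof <- per_model_normalized_profiles
  if (!length(prof)) stop("need at least one profile")
  mk <- names(prof[[1L]]$scores)
  for (p in prof) {
    if (!identical(names(p$scores), mk)) stop("marker sets differ across profiles")
  }
  S <- do.call(cbind, lapply(prof, `[[`, "scores"))
  gp_effects("Ensemble", rowMeans(S), prof[[1L]]$scenario,
             list(models = vapply(prof, `[[`, "", "model")))
}

#' Aggregate scenario results into final effects and interactions
#'
#' Per-model per-marker mean raw effect across scenarios, the mean normalised
#' ensemble effect, and the mean interaction matrix; markers absent from some
#' scenarios (pruned away by per-scenario LD filtering) are averaged over the
#' scenarios in which they are present, with presence counts reported.
#'
#' @param results list of per-scenario result lists as produced by
#'   [run_scenario()] (each with `effects`, `ensemble_effect`, `interactions`,
#'   `metrics`).
#' @return List of class `gp_aggregate` with `effects` (per model, named
#'   numeric), `ensemble` ([gp_effects()]), `interactions` (matrix or NULL),
#'   `presence`, `metrics` (data frame).
#' @export
aggregate_scenarios <- function(results) {
  if (!length(results)) stop("no scenario results to aggregate")
  all_markers <- Reduce(union, lapply(results, function(r)
    names(r$ensemble_effect$scores)))
  models <- unique(unlist(lapply(results, function(r)
    vapply(r$effects, `[[`, "", "model"))))

  acc <- function(profiles_per_scenario) {
    sum_v <- stats::setNames(numeric(length(all_markers)), all_markers)
    cnt <- sum_v
    for (pr in profiles_per_scenario) {
      if (is.null(pr)) next
      m <- names(pr$scores)
      sum_v[m] <- sum_v[m] + pr$scores
      cnt[m] <- cnt[m] + 1
    }
    list(mean = ifelse(cnt > 0, sum_v / cnt, NA_real_), count = cnt)
  }

  effects <- lapply(models, function(mod) {
    acc(lapply(results, function(r) {
      hit <- which(vapply(r$effects, `[[`, "", "model") == mod)
      if (length(hit)) r$effects[[hit[1L]]] else NULL
    }))
  })
  names(effects) <- models
  ens <- acc(lapply(results, `[[`, "ensemble_effect"))

  inter <- NULL
  with_int <- Filter(function(r) !is.null(r$interactions), results)
  if (length(with_int)) {
    S <- matrix(0, length(all_markers), length(all_markers),
                dimnames = list(all_markers, all_markers))
    Cnt <- S
    for (r in with_int) {
      m <- rownames(r$interactions)
      S[m, m] <- S[m, m] + r$interactions
      Cnt[m, m] <- Cnt[m, m] + 1
    }
    inter <- ifelse(Cnt > 0, S / Cnt, 0)
    dimnames(inter) <- dimnames(S)
  }

  metrics <- do.call(rbind, lapply(results, `[[`, "metrics"))
  structure(list(effects = lapply(effects, `[[`, "mean"),
                 presence = lapply(effects, `[[`, "count"),
                 ensemble = gp_effects("Ensemble", ens$mean[!is.na(ens$mean)],
                                       "aggregate"),
                 ensemble_presence = ens$count,
                 interactions = inter, metrics = metrics),
            class = "gp_aggregate")
}
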