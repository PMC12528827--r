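#' Per-marker effect profile
#'
#' One signed (coefficients, Shapley, Integrated Gradients) or unsigned
#' (impurity importance) score per marker, for one model in one prediction
#' scenario.
#'
#' @param model model tag, e.g. "rrBLUP".
#' @param scores named numeric vector, one finite score per marker.
#' @param scenario scenario identifier (default `NA`).
#' @param metadata list of estimation metadata (mode, n_samples, seed, ...).
#' @return An object of class `gp_effects`.
#' @export
gp_effects <- function(model, scores, scenario = NA, metadata = list()) {
  if (is.null(names(scores))) stop("scores must be named by marker")
  if (!all(is.finite(scores))) stop("effect scores must be finite")
  structure(list(model = model, scores = scores, scenario = scenario,
                 metadata = metadata), class = "gp_effects")
}

#' @export
print.gp_effects <- function(x, ...) {
  cat(sprintf("gp_effects [%s, scenario %s]: %d markers, |score| in [%.3g, %.3g]\n",
              x$model, as.character(x$scenario), length(x$scores),
              min(abs(x$scores)), max(abs(x$scores))))
  invisible(x)
}

#' Marker effects from linear-model coefficients
#'
#' For rrBLUP and BayesB the allele-substitution effect vector itself is the
#' per-marker effect.
#'
#' @param fit a `gp_rrblup` or `gp_bayesb` model.
#' @param scenario scenario tag.
#' @return A [gp_effects()] profile (markers only; the replicate feature's
#'   coefficient is not a marker effect).
#' @export
coef_effects <- function(fit, scenario = NA) {
  if (!inherits(fit, "gp_linear")) {
    stop("coef_effects applies to rrBLUP/BayesB fits only")
  }
  tag <- if (inherits(fit, "gp_bayesb")) "BayesB" else "rrBLUP"
  gp_effects(tag, fit$beta[fit$marker_names], scenario,
             list(mode = "coefficient"))
}

#' Impurity-based marker importance from a random forest
#'
#' Total variance-reduction attributable to splits on each marker, normalised
#' to sum to one across markers.
#'
#' @param fit a `gp_rf` model.
#' @param scenario scenario tag.
#' @return A [gp_effects()] profile of non-negative scores summing to 1.
#' @export
impurity_importance <- function(fit, scenario = NA) {
  if (!inherits(fit, "gp_rf")) stop("impurity_importance applies to RF fits only")
  imp <- fit$importance_raw[fit$marker_names]
  s <- sum(imp)
  if (s > 0) imp <- imp / s
  gp_effects("RF", imp, scenario, list(mode = "impurity"))
}

# composite rows: background rows with the coalition's marker columns (and
# always the replicate column) overwritten by the instance's values
composite_block <- function(B, x, cols) {
  M <- B
  if (length(cols)) M[, cols] <- rep(x[cols], each = nrow(B))
  M
}

# v(S) for every coalition mask of the p attributed markers, for one record:
# mean model prediction over the background with coalition markers pinned to
# the record. Returns numeric vector indexed by mask + 1.
coalition_values <- function(model, x, B, marker_cols, chunk = 256L) {
  p <- length(marker_cols)
  n_mask <- 2L^p
  b <- nrow(B)
  v <- numeric(n_mask)
  mask_bits <- function(mask) marker_cols[bitwAnd(bitwShiftR(mask, 0:(p - 1)), 1L) == 1L]
  for (lo in seq(0L, n_mask - 1L, by = chunk)) {
    hi <- min(lo + chunk - 1L, n_mask - 1L)
    blocks <- lapply(lo:hi, function(mask) composite_block(B, x, mask_bits(mask)))
    preds <- predict_features(model, do.call(rbind, blocks))
    pm <- matrix(preds, nrow = b)
    v[(lo:hi) + 1L] <- colMeans(pm)
  }
  v
}

# canonical model tags used on circos rings and in exports
model_tag <- function(model) {
  switch(class(model)[1L],
         gp_rrblup = "rrBLUP", gp_bayesb = "BayesB", gp_rkhs = "RKHS",
         gp_rf = "RF", gp_svr = "SVR", gp_gat = "GAT", class(model)[1L])
}

prepare_background <- function(model, background, n_background) {
  B <- if (inherits(background, "gp_dataset")) feature_matrix(background) else
    as.matrix(background)
  B <- B[, model$feature_names, drop = FALSE]
  if (nrow(B) > n_background) {
    rows <- sample.int(nrow(B), n_background)
    B <- B[rows, , drop = FALSE]
  }
  B
}

#' Shapley-value marker effects
#'
#' Per-record Shapley values with absent markers marginalised over a
#' background set (the training genotypes); the profile score per marker is
#' the mean over the test records. Exact mode enumerates all 2^p coalitions
#' (p <= 12); sampled mode uses seeded antithetic permutation sampling and
#' converges to the exact values as `n_samples` grows. The replicate feature
#' is pinned to each test record and not attributed.
#'
#' @param model any fitted `gp_model`.
#' @param test a [gp_dataset()] of records to explain.
#' @param background training [gp_dataset()] (or feature matrix) for the
#'   marginal expectations.
#' @param mode `"exact"` or `"sampled"`.
#' @param n_samples number of permutations in sampled mode (default 2000).
#' @param n_background background rows retained (default up to 100, seeded).
#' @param seed integer seed.
#' @param scenario scenario tag.
#' @return A [gp_effects()] profile; attribute-level detail in
#'   `$metadata` (`per_record` matrix, `baseline` value, per-marker
#'   Monte-Carlo `se` in sampled mode).
#' @export
shapley_effects <- function(model, test, background,
                            mode = c("sampled", "exact"), n_samples = 2000,
                            n_background = 100, seed = NULL, scenario = NA) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  markers <- model$marker_names
  p <- length(markers)
  X <- feature_matrix(test)[, model$feature_names, drop = FALSE]
  marker_cols <- match(markers, model$feature_names)
  B0 <- prepare_background(model, background, n_background)
  n_rec <- nrow(X)

  if (mode == "exact") {
    if (p > 12) stop("exact Shapley limited to p <= 12 markers; use mode = 'sampled'")
    wts <- factorial(0:(p - 1)) * factorial(p - 1 - 0:(p - 1)) / factorial(p)
    per_record <- matrix(0, n_rec, p, dimnames = list(NULL, markers))
    baseline <- numeric(n_rec)
    popcount <- vapply(0:(2L^p - 1L), function(m) sum(bitwAnd(
      bitwShiftR(m, 0:(p - 1)), 1L)), integer(1))
    for (r in seq_len(n_rec)) {
      x <- X[r, ]
      B <- B0; B[, ".replicate"] <- x[".replicate"]
      v <- coalition_values(model, x, B, marker_cols)
      baseline[r] <- v[1L]
      for (mask in 0:(2L^p - 1L)) {
        s <- popcount[mask + 1L]
        for (i in seq_len(p)) {
          bit <- bitwShiftL(1L, i - 1L)
          if (bitwAnd(mask, bit) == 0L) {
            per_record[r, i] <- per_record[r, i] +
              wts[s + 1L] * (v[bitwOr(mask, bit) + 1L] - v[mask + 1L])
          }
        }
      }
    }
    scores <- colMeans(per_record)
    return(gp_effects(model_tag(model), scores, scenario,
                      list(mode = "exact", per_record = per_record,
                           baseline = baseline,
                           fx = predict_features(model, X), seed = seed)))
  }

  # sampled: antithetic permutations; each permutation yields one marginal
  # contribution per marker (averaged over test records)
  n_pairs <- max(1L, ceiling(n_samples / 2))
  contrib <- matrix(0, 2L * n_pairs, p, dimnames = list(NULL, markers))
  Bs <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    Bs[[r]] <- B0
    Bs[[r]][, ".replicate"] <- X[r, ".replicate"]
  }
  b <- nrow(B0)
  row_perm <- 0L
  for (k in seq_len(n_pairs)) {
    perm <- sample.int(p)
    for (pm in list(perm, rev(perm))) {
      row_perm <- row_perm + 1L
      acc <- numeric(p)
      for (r in seq_len(n_rec)) {
        x <- X[r, ]
        M <- Bs[[r]]
        blocks <- vector("list", p + 1L)
        blocks[[1L]] <- M
        for (step in seq_len(p)) {
          M[, marker_cols[pm[step]]] <- x[marker_cols[pm[step]]]
          blocks[[step + 1L]] <- M
        }
        preds <- predict_features(model, do.call(rbind, blocks))
        vs <- colMeans(matrix(preds, nrow = b))
        acc[pm] <- acc[pm] + diff(vs)
      }
      contrib[row_perm, ] <- acc / n_rec
    }
  }
  scores <- colMeans(contrib)
  se <- apply(contrib, 2L, stats::sd) / sqrt(nrow(contrib))
  gp_effects(model_tag(model), scores, scenario,
             list(mode = "sampled", n_samples = 2L * n_pairs, se = se,
                  seed = seed))
}

#' Integrated Gradients marker effects
#'
#' Riemann-sum approximation of the path integral of the model gradient from
#' a baseline genotype to each test record,
#' `IG_j = (x_j - x'_j)/m * sum_{k=1..m} d f / d x_j` evaluated at
#' `x' + (k/m)(x - x')`; gradients are central finite differences (exact for
#' linear models). The profile score is the mean attribution over test
#' records.
#'
#' @param fit a fitted `gp_model` (typically the GAT).
#' @param test a [gp_dataset()] of records to explain.
#' @param baseline baseline dosage vector `x'` (length = marker count);
#'   default is the test-population mean dosage.
#' @param m number of interpolation steps (default 64).
#' @param scenario scenario tag.
#' @return A [gp_effects()] profile; `$metadata$per_record` has per-record
#'   attributions and `$metadata$completeness` the per-record
#'   `|sum IG - (f(x) - f(x'))|` errors.
#' @export
integrated_gradients <- function(fit, test, baseline = NULL, m = 64,
                                 scenario = NA) {
  if (m < 1) stop("m must be >= 1")
  markers <- fit$marker_names
  p <- length(markers)
  X <- feature_matrix(test)[, fit$feature_names, drop = FALSE]
  marker_cols <- match(markers, fit$feature_names)
  if (is.null(baseline)) baseline <- colMeans(X[, marker_cols, drop = FALSE])
  if (length(baseline) != p) stop("baseline dimension mismatch: need ", p)
  h <- 1e-4
  n_rec <- nrow(X)
  per_record <- matrix(0, n_rec, p, dimnames = list(NULL, markers))
  completeness <- numeric(n_rec)
  for (r in seq_len(n_rec)) {
    x <- X[r, ]
    xb <- x; xb[marker_cols] <- baseline
    diffv <- x[marker_cols] - baseline
    # all path points, then +/- h on every marker at every point
    steps <- (seq_len(m)) / m
    P <- matrix(rep(xb, each = m), nrow = m,
                dimnames = list(NULL, names(x)))
    P[, marker_cols] <- P[, marker_cols] +
      outer(steps, diffv)
    rows <- vector("list", 2L * p)
    for (j in seq_len(p)) {
      Pp <- P; Pp[, marker_cols[j]] <- Pp[, marker_cols[j]] + h
      Pm <- P; Pm[, marker_cols[j]] <- Pm[, marker_cols[j]] - h
      rows[[2L * j - 1L]] <- Pp
      rows[[2L * j]] <- Pm
    }
    preds <- predict_features(fit, do.call(rbind, rows))
    pm <- matrix(preds, nrow = m)     # columns alternate +h, -h per marker
    for (j in seq_len(p)) {
      grads <- (pm[, 2L * j - 1L] - pm[, 2L * j]) / (2 * h)
      per_record[r, j] <- diffv[j] * mean(grads)
    }
    f_ends <- predict_features(fit, rbind(x, xb))
    completeness[r] <- abs(sum(per_record[r, ]) - (f_ends[1L] - f_ends[2L]))
  }
  gp_effects(model_tag(fit), colMeans(per_record), scenario,
             list(mode = "integrated_gradients", m = m,
                  per_record = per_record, completeness = completeness,
                  baseline = baseline))
}

#' Pairwise Shapley interaction effects
#'
#' Shapley interaction index for every unordered marker pair from a random
#' forest: the pair-coalition contribution minus the two singleton
#' contributions, `sum_S w(|S|) [v(S+ij) - v(S+i) - v(S+j) + v(S)]` with
#' `w(s) = s!(p-|S|-2)!/(p-1)!`, marginalised over a background set and
#' averaged over test records. Exact mode enumerates coalitions (p <= 10);
#' sampled mode draws seeded (size-uniform) coalitions per pair and may be
#' screened to the `top_m` markers by impurity importance (unscreened pairs
#' report 0).
#'
#' @param fit a `gp_rf` model.
#' @param test a [gp_dataset()] of records to explain.
#' @param background training [gp_dataset()] or feature matrix.
#' @param mode `"exact"` or `"sampled"`.
#' @param n_subsets coalitions sampled per pair in sampled mode (default 30).
#' @param n_background background rows retained (default 100 exact / 20 sampled).
#' @param top_m screen to this many top-importance markers in sampled mode
#'   (`NULL` = all markers).
#' @param max_records cap on test records averaged in sampled mode (default 10).
#' @param seed integer seed.
#' @return Symmetric markers x markers matrix (class `gp_interactions`),
#'   diagonal zero.
#' @export
pairwise_interactions <- function(fit, test, background,
                                  mode = c("exact", "sampled"),
                                  n_subsets = 30, n_background = NULL,
                                  top_m = NULL, max_records = 10,
                                  seed = NULL) {
  mode <- match.arg(mode)
  if (!inherits(fit, "gp_rf")) {
    stop("pairwise_interactions applies to RF fits only")
  }
  if (!is.null(seed)) set.seed(seed)
  markers <- fit$marker_names
  p <- length(markers)
  if (p < 2L) stop("need at least 2 markers")
  X <- feature_matrix(test)[, fit$feature_names, drop = FALSE]
  marker_cols <- match(markers, fit$feature_names)
  out <- matrix(0, p, p, dimnames = list(markers, markers))

  if (mode == "exact") {
    if (p > 10) stop("exact interactions limited to p <= 10; use mode = 'sampled'")
    if (is.null(n_background)) n_background <- 100
    B0 <- prepare_background(fit, background, n_background)
    wI <- factorial(0:(p - 2)) * factorial(p - 2 - 0:(p - 2)) / factorial(p - 1)
    popcount <- vapply(0:(2L^p - 1L), function(m) sum(bitwAnd(
      bitwShiftR(m, 0:(p - 1)), 1L)), integer(1))
    for (r in seq_len(nrow(X))) {
      x <- X[r, ]
      B <- B0; B[, ".replicate"] <- x[".replicate"]
      v <- coalition_values(fit, x, B, marker_cols)
      for (i in seq_len(p - 1L)) {
        bi <- bitwShiftL(1L, i - 1L)
        for (j in (i + 1L):p) {
          bj <- bitwShiftL(1L, j - 1L)
          acc <- 0
          for (mask in 0:(2L^p - 1L)) {
            if (bitwAnd(mask, bi) != 0L || bitwAnd(mask, bj) != 0L) next
            s <- popcount[mask + 1L]
            acc <- acc + wI[s + 1L] *
              (v[bitwOr(mask, bitwOr(bi, bj)) + 1L] -
                 v[bitwOr(mask, bi) + 1L] - v[bitwOr(mask, bj) + 1L] +
                 v[mask + 1L])
          }
          out[i, j] <- out[i, j] + acc
        }
      }
    }
    out <- (out + t(out)) / nrow(X)
    class(out) <- c("gp_interactions", class(out))
    return(out)
  }

  # sampled mode
  if (is.null(n_background)) n_background <- 20
  B0 <- prepare_background(fit, background, n_background)
  b <- nrow(B0)
  rec <- seq_len(nrow(X))
  if (length(rec) > max_records) rec <- sample(rec, max_records)
  cand <- seq_len(p)
  if (!is.null(top_m) && top_m < p) {
    imp <- impurity_importance(fit)$scores
    cand <- order(imp, decreasing = TRUE)[seq_len(top_m)]
  }
  pairs <- utils::combn(sort(cand), 2L)
  tree_feats <- cpp_forest_features(fit$trees)
  for (q in seq_len(ncol(pairs))) {
    i <- pairs[1L, q]; j <- pairs[2L, q]
    ci <- marker_cols[i]; cj <- marker_cols[j]
    qual <- which(vapply(tree_feats, function(s)
      (ci - 1L) %in% s && (cj - 1L) %in% s, logical(1)))
    if (!length(qual)) next      # no tree uses both markers: interaction 0
    rest <- setdiff(seq_len(p), c(i, j))
    blocks <- vector("list", 4L * n_subsets * length(rec))
    bi <- 0L
    for (s in seq_len(n_subsets)) {
      k <- sample.int(p - 1L, 1L) - 1L          # |S| uniform on 0..p-2
      S <- if (k > 0L) sample(rest, k) else integer(0)
      Sc <- marker_cols[S]
      for (r in rec) {
        x <- X[r, ]
        M <- B0
        M[, ".replicate"] <- x[".replicate"]
        if (length(Sc)) M[, Sc] <- rep(x[Sc], each = b)
        Mij <- M; Mij[, ci] <- x[ci]; Mij[, cj] <- x[cj]
        Mi <- M; Mi[, ci] <- x[ci]
        Mj <- M; Mj[, cj] <- x[cj]
        blocks[bi + 1:4] <- list(Mij, Mi, Mj, M)
        bi <- bi + 4L
      }
    }
    preds <- cpp_forest_predict_subset(fit$trees, do.call(rbind, blocks), qual)
    vs <- colMeans(matrix(preds, nrow = b))     # one value per block
    deltas <- vs[seq(1L, bi, 4L)] - vs[seq(2L, bi, 4L)] -
      vs[seq(3L, bi, 4L)] + vs[seq(4L, bi, 4L)]
    out[i, j] <- out[j, i] <- mean(deltas)
  }
  class(out) <- c("gp_interactions", class(out))
  out
}

#' Export effect profiles as TSV (`marker  model  scenario  score`)
#'
#' @param profiles a [gp_effects()] or list of them.
#' @param path output path.
#' @export
write_effects_tsv <- function(profiles, path) {
  if (inherits(profiles, "gp_effects")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(pr) {
    data.frame(marker = names(pr$scores), model = pr$model,
               scenario = as.character(pr$scenario), score = unname(pr$scores),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export an interaction matrix as TSV (`marker_a  marker_b  score`)
#'
#' @param m symmetric interaction matrix.
#' @param path output path.
#' @export
write_interactions_tsv <- function(m, path) {
  idx <- which(upper.tri(m), arr.ind = TRUE)
  rows <- data.frame(marker_a = rownames(m)[idx[, 1L]],
                     marker_b = colnames(m)[idx[, 2L]],
                     score = m[idx], stringsAsFactors = FALSE)
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
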