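#' Fit a regression random forest
#'
#' Bootstrap-aggregated CART regression trees with variance-reduction splits.
#' Defaults mirror the scikit-learn regressor convention the ensemble was
#' specified against: all features considered at every split
#' (`mtry =` feature count), unbounded depth, minimum split size 2.
#'
#' @param train a [gp_dataset()].
#' @param n_trees number of trees (default 1000).
#' @param mtry features sampled per split; `NULL` = all features.
#' @param min_split minimum node size eligible for splitting (default 2).
#' @param max_depth maximum tree depth, 0 = unbounded.
#' @param bootstrap resample records with replacement per tree (default TRUE).
#' @param seed integer seed (R RNG).
#' @return An object of class `c("gp_rf", "gp_model")` carrying the tree
#'   ensemble and raw impurity-decrease totals per feature.
#' @export
fit_rf <- function(train, n_trees = 1000, mtry = NULL, min_split = 2,
                   max_depth = 0, bootstrap = TRUE, seed = NULL) {
  X <- feature_matrix(train)
  if (is.null(mtry)) mtry <- ncol(X)
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_grow_forest(X, train$y, as.integer(n_trees), as.integer(mtry),
                         as.integer(min_split), as.integer(max_depth),
                         bootstrap)
  fit <- list(trees = res$trees,
              importance_raw = stats::setNames(res$importance, colnames(X)),
              n_trees = n_trees, feature_names = colnames(X),
              marker_names = train$marker_names)
  class(fit) <- c("gp_rf", "gp_model")
  fit
}

#' @export
predict_features.gp_rf <- function(model, X, ...) {
  cpp_forest_predict(model$trees, X[, model$feature_names, drop = FALSE])
}

#' Fit epsilon-insensitive support vector regression (RBF kernel)
#'
#' Kernel SVR solved in the primal on the dual expansion
#' `f(x) = sum_i alpha_i K(x_i, x) + b`, minimising
#' `0.5 alpha' K alpha + C * sum L_eps(y_i - f(x_i))` with a lightly smoothed
#' epsilon-insensitive loss (quasi-Newton optimisation). Defaults follow the
#' common library convention: `C = 1`, `epsilon = 0.1`,
#' `gamma = 1 / (p * var(X))` ("scale").
#'
#' @param train a [gp_dataset()].
#' @param cost regularisation constant C.
#' @param epsilon half-width of the insensitive tube (trait units).
#' @param gamma RBF kernel coefficient; `NULL` = `1 / (p * var(X))`.
#' @return An object of class `c("gp_svr", "gp_model")`.
#' @export
fit_svr <- function(train, cost = 1, epsilon = 0.1, gamma = NULL) {
  X <- feature_matrix(train)
  y <- train$y
  n <- nrow(X)
  if (is.null(gamma)) {
    vX <- stats::var(as.vector(X))
    gamma <- if (vX > 0) 1 / (ncol(X) * vX) else 1
  }
  sq <- outer(rowSums(X^2), rowSums(X^2), `+`) - 2 * tcrossprod(X)
  sq[sq < 0] <- 0
  K <- exp(-gamma * sq)
  delta <- 1e-3 * max(stats::sd(y), 1e-6)   # loss smoothing width

  dloss <- function(r) {
    a <- abs(r)
    out <- numeric(length(r))
    tr <- a > epsilon & a <= epsilon + delta
    out[tr] <- sign(r[tr]) * (a[tr] - epsilon) / delta
    out[a > epsilon + delta] <- sign(r[a > epsilon + delta])
    out
  }
  loss <- function(r) {
    a <- abs(r)
    out <- numeric(length(r))
    tr <- a > epsilon & a <= epsilon + delta
    out[tr] <- (a[tr] - epsilon)^2 / (2 * delta)
    big <- a > epsilon + delta
    out[big] <- a[big] - epsilon - delta / 2
    out
  }
  obj <- function(par) {
    alpha <- par[1:n]; b <- par[n + 1L]
    f <- drop(K %*% alpha) + b
    0.5 * sum(alpha * (K %*% alpha)) + cost * sum(loss(y - f))
  }
  grd <- function(par) {
    alpha <- par[1:n]; b <- par[n + 1L]
    f <- drop(K %*% alpha) + b
    g <- dloss(y - f)
    c(drop(K %*% alpha) - cost * drop(K %*% g), -cost * sum(g))
  }
  par0 <- c(rep(0, n), mean(y))
  opt <- stats::optim(par0, obj, grd, method = "L-BFGS-B",
                      control = list(maxit = 500))
  fit <- list(alpha = opt$par[1:n], b = opt$par[n + 1L], gamma = gamma,
              epsilon = epsilon, cost = cost, X_train = X,
              feature_names = colnames(X), marker_names = train$marker_names)
  class(fit) <- c("gp_svr", "gp_model")
  fit
}

#' @export
predict_features.gp_svr <- function(model, X, ...) {
  X <- X[, model$feature_names, drop = FALSE]
  sq <- outer(rowSums(X^2), rowSums(model$X_train^2), `+`) -
    2 * tcrossprod(X, model$X_train)
  sq[sq < 0] <- 0
  drop(exp(-model$gamma * sq) %*% model$alpha) + model$b
}
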