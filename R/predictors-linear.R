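#' @useDynLib easigp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# REML for y = 1*mu + g + e, g ~ N(0, sigma2_u * K), e ~ N(0, sigma2_e * I),
# profiled over the variance ratio lambda = sigma2_e / sigma2_u via the
# eigendecomposition of K. Returns the GLS intercept and variance components.
reml_kernel <- function(K, y, lambda = NULL, interval = c(-12, 12)) {
  n <- length(y)
  eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  a <- drop(crossprod(U, y))
  b <- drop(crossprod(U, rep(1, n)))

  pieces <- function(lam) {
    w <- 1 / (d + lam)
    oVo <- sum(b * b * w)
    oVy <- sum(a * b * w)
    yVy <- sum(a * a * w)
    list(w = w, oVo = oVo, oVy = oVy, yPy = yVy - oVy^2 / oVo)
  }
  negll <- function(loglam) {
    lam <- exp(loglam)
    pc <- pieces(lam)
    s2u <- pc$yPy / (n - 1)
    if (s2u <= 0) return(1e10)
    0.5 * ((n - 1) * log(s2u) + sum(log(d + lam)) + log(pc$oVo) +
             (n - 1))
  }
  if (is.null(lambda)) {
    opt <- stats::optimize(negll, interval = interval)
    lambda <- exp(opt$minimum)
  }
  pc <- pieces(lambda)
  sigma2_u <- max(pc$yPy / (n - 1), 1e-12)
  mu <- pc$oVy / pc$oVo
  # (K + lambda I)^{-1} (y - mu)
  alpha <- drop(U %*% (pc$w * (a - mu * b)))
  list(mu = mu, lambda = lambda, sigma2_u = sigma2_u,
       sigma2_e = lambda * sigma2_u, alpha = alpha)
}

#' Fit ridge-regression BLUP (rrBLUP)
#'
#' Linear mixed model `y = 1 mu + X beta + e` with `beta ~ N(0, I sigma2_beta)`.
#' The variance ratio `lambda = sigma2_e / sigma2_beta` is estimated by REML
#' on the equivalent GBLUP model (kernel `X X'`); marker effects are recovered
#' through the ridge identity `beta = X'(XX' + lambda I)^{-1}(y - mu)`.
#' Deterministic given the data.
#'
#' @param train a [gp_dataset()] with at least 2 records and 1 marker.
#' @param lambda optional fixed variance ratio; `NULL` (default) = REML.
#' @return An object of class `c("gp_rrblup", "gp_linear", "gp_model")` with
#'   elements `mu`, `beta` (named per feature), `sigma2_beta`, `sigma2_eps`.
#' @export
fit_rrblup <- function(train, lambda = NULL) {
  X <- feature_matrix(train)
  y <- train$y
  if (nrow(X) < 2L) stop("rrBLUP needs at least 2 records")
  if (ncol(train$G) < 1L) stop("rrBLUP needs at least 1 marker")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  if (stats::var(y) == 0) {
    beta <- stats::setNames(rep(0, ncol(X)), colnames(X))
    fit <- list(mu = y[1L], beta = beta, sigma2_beta = 0, sigma2_eps = 0,
                lambda = Inf, centers = ctr, feature_names = colnames(X),
                marker_names = train$marker_names)
    class(fit) <- c("gp_rrblup", "gp_linear", "gp_model")
    return(fit)
  }
  K <- tcrossprod(Xc)
  rk <- reml_kernel(K, y, lambda = lambda)
  beta <- drop(crossprod(Xc, rk$alpha))
  names(beta) <- colnames(X)
  fit <- list(mu = rk$mu, beta = beta, sigma2_beta = rk$sigma2_u,
              sigma2_eps = rk$sigma2_e, lambda = rk$lambda, centers = ctr,
              feature_names = colnames(X), marker_names = train$marker_names)
  class(fit) <- c("gp_rrblup", "gp_linear", "gp_model")
  fit
}

#' Fit BayesB by Gibbs sampling
#'
#' Spike-and-slab marker-effect model: each effect is zero with probability
#' `1 - pi`, otherwise drawn from a normal slab whose marker-specific variance
#' carries a scaled-inverse-chi-square prior (df `df0`, scale solved from an
#' assumed prior heritability of 0.5); `pi` carries a uniform Beta prior
#' (prior mean 0.5). Reported effects are posterior means over post-burn-in
#' samples.
#'
#' @param train a [gp_dataset()].
#' @param n_iter,burn_in Gibbs chain length and burn-in (defaults 12000/2000).
#' @param seed integer seed for the chain (uses R's RNG).
#' @param df0 slab variance prior degrees of freedom (default 5).
#' @param pi fixed inclusion probability, or `NULL` (default) to sample it.
#' @param sigma2_beta,sigma2_e optional fixed variance components; when both
#'   are fixed and `pi = 1` the posterior mean equals the ridge solution with
#'   `lambda = sigma2_e / sigma2_beta` (up to Monte-Carlo error).
#' @return An object of class `c("gp_bayesb", "gp_linear", "gp_model")` with
#'   `beta`, `inclusion_prob`, `mu`, `pi`, `sigma2_eps`.
#' @export
fit_bayesb <- function(train, n_iter = 12000, burn_in = 2000, seed = NULL,
                       df0 = 5, pi = NULL, sigma2_beta = NULL,
                       sigma2_e = NULL) {
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in")
  X <- feature_matrix(train)
  y <- train$y
  if (nrow(X) < 2L) stop("BayesB needs at least 2 records")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  if (stats::var(y) == 0) {
    beta <- stats::setNames(rep(0, ncol(X)), colnames(X))
    fit <- list(mu = y[1L], beta = beta,
                inclusion_prob = stats::setNames(rep(0, ncol(X)), colnames(X)),
                pi = 0, sigma2_eps = 0, centers = ctr,
                feature_names = colnames(X), marker_names = train$marker_names)
    class(fit) <- c("gp_bayesb", "gp_linear", "gp_model")
    return(fit)
  }
  vy <- stats::var(y)
  msx <- sum(apply(Xc, 2L, stats::var))
  if (msx == 0) msx <- 1
  pi0 <- if (is.null(pi)) 0.5 else pi
  h2_prior <- 0.5
  s2b_prior <- h2_prior * vy / (pi0 * msx)
  S0 <- s2b_prior * (df0 + 2) / df0        # prior mode at s2b_prior
  dfe <- 5
  Se <- (1 - h2_prior) * vy * (dfe + 2) / dfe
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_bayesb_gibbs(Xc, y, as.integer(n_iter), as.integer(burn_in),
                          df0, S0, dfe, Se,
                          ifelse(is.null(pi), -1, pi),
                          ifelse(is.null(sigma2_beta), -1, sigma2_beta),
                          ifelse(is.null(sigma2_e), -1, sigma2_e))
  beta <- stats::setNames(res$beta, colnames(X))
  fit <- list(mu = res$mu, beta = beta,
              inclusion_prob = stats::setNames(res$inclusion_prob, colnames(X)),
              pi = res$pi, sigma2_eps = res$sigma2_e, centers = ctr,
              feature_names = colnames(X), marker_names = train$marker_names)
  class(fit) <- c("gp_bayesb", "gp_linear", "gp_model")
  fit
}

#' @export
predict_features.gp_linear <- function(model, X, ...) {
  Xc <- sweep(X[, model$feature_names, drop = FALSE], 2L, model$centers)
  drop(model$mu + Xc %*% model$beta)
}

#' Predict phenotypes from a fitted model
#'
#' @param model a fitted `gp_model`.
#' @param X numeric feature matrix with the model's feature columns
#'   (markers plus `.replicate`).
#' @param ... unused.
#' @return Numeric prediction vector, one value per row of `X`.
#' @export
predict_features <- function(model, X, ...) UseMethod("predict_features")

#' @export
predict.gp_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "gp_dataset")) feature_matrix(newdata) else
    as.matrix(newdata)
  predict_features(object, X)
}
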