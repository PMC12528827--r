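#' Gaussian kernel on allele-dosage rows
#'
#' `K[i, i'] = exp(-h * mean_k (x_ik - x_i'k)^2)`: the mean squared Euclidean
#' distance between two genotypes, damped by the bandwidth `h`. Values lie in
#' (0, 1] and equal 1 exactly on identical genotypes.
#'
#' @param G1,G2 dosage/feature matrices with the same number of columns.
#' @param h bandwidth (> 0); larger `h` means faster decay of covariance
#'   with genetic distance.
#' @return `nrow(G1) x nrow(G2)` kernel matrix.
#' @export
gaussian_kernel <- function(G1, G2, h = 1) {
  G1 <- as.matrix(G1); G2 <- as.matrix(G2)
  p <- ncol(G1)
  if (p == 0L) stop("kernel needs at least one marker")
  if (ncol(G2) != p) stop("marker counts differ")
  if (h <= 0) stop("bandwidth h must be positive")
  sq <- outer(rowSums(G1^2), rowSums(G2^2), `+`) - 2 * tcrossprod(G1, G2)
  sq[sq < 0] <- 0
  exp(-h * sq / p)
}

#' Fit Gaussian-kernel RKHS regression
#'
#' Kernel mixed model `y = 1 mu + u + e` with `u ~ N(0, K sigma2_u)` for the
#' Gaussian kernel `K` of [gaussian_kernel()]. Solved through the equivalent
#' kernel-ridge system `(K + lambda I) alpha = y - mu` with
#' `lambda = sigma2_e / sigma2_u` estimated by REML; new genotypes are
#' predicted through the cross-kernel against the training set.
#'
#' @param train a [gp_dataset()].
#' @param h kernel bandwidth (default 1).
#' @param lambda optional fixed variance ratio; `NULL` (default) = REML.
#' @return An object of class `c("gp_rkhs", "gp_model")`.
#' @export
fit_rkhs <- function(train, h = 1, lambda = NULL) {
  X <- feature_matrix(train)
  y <- train$y
  K <- gaussian_kernel(X, X, h)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) stop("kernel matrix is not PSD")
  if (stats::var(y) == 0) {
    fit <- list(mu = y[1L], alpha = rep(0, length(y)), h = h, lambda = Inf,
                sigma2_u = 0, sigma2_eps = 0, X_train = X, K = K,
                feature_names = colnames(X), marker_names = train$marker_names)
    class(fit) <- c("gp_rkhs", "gp_model")
    return(fit)
  }
  rk <- reml_kernel(K, y, lambda = lambda)
  fit <- list(mu = rk$mu, alpha = rk$alpha, h = h, lambda = rk$lambda,
              sigma2_u = rk$sigma2_u, sigma2_eps = rk$sigma2_e,
              X_train = X, K = K, feature_names = colnames(X),
              marker_names = train$marker_names)
  class(fit) <- c("gp_rkhs", "gp_model")
  fit
}

#' @export
predict_features.gp_rkhs <- function(model, X, ...) {
  Kx <- gaussian_kernel(X[, model$feature_names, drop = FALSE],
                        model$X_train, model$h)
  drop(model$mu + Kx %*% model$alpha)
}
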