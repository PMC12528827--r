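#' Fit a bipartite graph attention network
#'
#' Each record is a star graph: one node per genomic marker plus one node for
#' the replicate factor, all with directed edges into a single phenotype node
#' and no marker-marker edges. Marker identity enters through a one-hot node
#' embedding scaled by the allele dosage (the standard encoding of discrete
#' node identity in a graph network), so the shared linear transform `W`
#' contributes one learnable column per node. The attention layer then
#' reduces to a closed form: logits `e_k = LeakyReLU((a' W[,k]) x_k)`,
#' coefficients `alpha = softmax(e)` (non-negative, summing to 1 over the
#' phenotype node's incoming edges), pooled message
#' `h = sum_k alpha_k x_k W[,k] + c`, and readout `y = v' ELU(h) + b` with
#' `channels` hidden units. Trained by minibatch MSE with hand-derived
#' gradients under Adam with decoupled weight decay (weight decay 0 = plain
#' Adam). The response is standardised internally for optimisation stability;
#' predictions return on the trait scale.
#'
#' @param train a [gp_dataset()].
#' @param channels hidden channels (default 20).
#' @param epochs training epochs (default 50).
#' @param batch minibatch size (default 8).
#' @param lr learning rate (default 0.005).
#' @param weight_decay decoupled weight decay (default 0).
#' @param seed integer seed for initialisation and batch shuffling.
#' @return An object of class `c("gp_gat", "gp_model")`; element `history`
#'   holds the per-epoch training MSE (standardised scale).
#' @export
fit_gat <- function(train, channels = 20, epochs = 50, batch = 8,
                    lr = 0.005, weight_decay = 0, seed = NULL) {
  X <- feature_matrix(train)
  n <- nrow(X)
  f <- ncol(X)
  C <- channels
  y_mean <- mean(train$y)
  y_sd <- stats::sd(train$y)
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  ys <- (train$y - y_mean) / y_sd

  if (!is.null(seed)) set.seed(seed)
  par <- c(stats::rnorm(C * f, 0, sqrt(2 / (f + C))),  # W (C x f)
           stats::rnorm(C, 0, sqrt(2 / (C + 1))),      # a
           rep(0, C),                                  # c (conv bias)
           stats::rnorm(C, 0, sqrt(2 / (C + 1))),      # v (readout)
           0)                                          # b
  np <- length(par)
  iW <- 1:(C * f); ia <- C * f + 1:C; ic <- C * f + C + 1:C
  iv <- C * f + 2 * C + 1:C; ib <- np

  gat_forward <- function(par, Xb) {
    W <- matrix(par[iW], C, f)
    a <- par[ia]; cc <- par[ic]; v <- par[iv]; b <- par[ib]
    g <- drop(a %*% W)                       # per-node attention slope
    Q <- sweep(Xb, 2L, g, `*`)               # logits before activation
    E <- ifelse(Q > 0, Q, 0.2 * Q)
    E <- E - apply(E, 1L, max)
    A <- exp(E); A <- A / rowSums(A)
    P <- A * Xb                              # alpha_k * x_k
    H <- P %*% t(W) + matrix(cc, nrow(Xb), C, byrow = TRUE)
    Z <- ifelse(H > 0, H, exp(H) - 1)
    yhat <- drop(Z %*% v) + b
    list(yhat = yhat, A = A, P = P, H = H, Z = Z, Q = Q, W = W, g = g)
  }
  gat_backward <- function(par, Xb, yb, fw) {
    a <- par[ia]; v <- par[iv]
    nb <- nrow(Xb)
    dy <- 2 * (fw$yhat - yb) / nb
    dv <- drop(crossprod(fw$Z, dy))
    db <- sum(dy)
    dZ <- tcrossprod(dy, v)
    dH <- dZ * ifelse(fw$H > 0, 1, exp(fw$H))
    dc <- colSums(dH)
    dW <- crossprod(dH, fw$P)                # C x f, message path
    dP <- dH %*% fw$W                        # n x f
    dA <- dP * Xb
    rs <- rowSums(fw$A * dA)
    dE <- fw$A * (dA - rs)
    dQ <- dE * ifelse(fw$Q > 0, 1, 0.2)
    dg <- colSums(dQ * Xb)                   # attention path per node
    dW <- dW + outer(a, dg)
    da <- drop(fw$W %*% dg)
    g <- numeric(np)
    g[iW] <- dW; g[ia] <- da; g[ic] <- dc; g[iv] <- dv; g[ib] <- db
    g
  }

  m <- numeric(np); vv <- numeric(np)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batch)) {
      rows <- ord[start:min(start + batch - 1L, n)]
      Xb <- X[rows, , drop = FALSE]
      fw <- gat_forward(par, Xb)
      if (!all(is.finite(fw$yhat))) stop("GAT training diverged (non-finite loss)")
      gr <- gat_backward(par, Xb, ys[rows], fw)
      t <- t + 1L
      m <- b1 * m + (1 - b1) * gr
      vv <- b2 * vv + (1 - b2) * gr^2
      mh <- m / (1 - b1^t); vh <- vv / (1 - b2^t)
      par <- par - lr * (mh / (sqrt(vh) + eps) + weight_decay * par)
    }
    fw <- gat_forward(par, X)
    history[ep] <- mean((fw$yhat - ys)^2)
    if (!is.finite(history[ep])) stop("GAT training diverged (non-finite loss)")
  }

  fit <- list(par = par, channels = C, y_mean = y_mean, y_sd = y_sd,
              history = history, forward = gat_forward,
              feature_names = colnames(X), marker_names = train$marker_names,
              config = list(channels = channels, epochs = epochs,
                            batch = batch, lr = lr,
                            weight_decay = weight_decay, seed = seed))
  class(fit) <- c("gp_gat", "gp_model")
  fit
}

#' @export
predict_features.gp_gat <- function(model, X, ...) {
  fw <- model$forward(model$par, X[, model$feature_names, drop = FALSE])
  model$y_mean + model$y_sd * fw$yhat
}

#' Attention coefficients of a fitted graph attention network
#'
#' @param fit a `gp_gat` model.
#' @param X feature matrix (rows = records).
#' @return Matrix of attention coefficients (rows sum to 1), one column per
#'   incoming edge of the phenotype node (markers plus the replicate node).
#' @export
gat_attention <- function(fit, X) {
  fw <- fit$forward(fit$par, as.matrix(X)[, fit$feature_names, drop = FALSE])
  colnames(fw$A) <- fit$feature_names
  fw$A
}
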