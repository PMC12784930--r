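# Feedforward-net learner: a multilayer perceptron for scalar regression
# (ReLU hidden layers, linear output) trained with Adam on mean squared error
# plus an L2 weight penalty, with early stopping on a held-out validation
# fraction. Inputs are standardized internally with training moments, and the
# target is centred/scaled for conditioning; predictions are returned on the
# original scale.

fit_mlp <- function(X, y, config) {
  widths <- config$hidden_widths
  stopifnot(length(widths) >= 1L)
  n <- nrow(X); p <- ncol(X)

  x_mu <- colMeans(X); x_sd <- apply(X, 2, stats::sd); x_sd[x_sd == 0] <- 1
  y_mu <- mean(y); y_sd <- stats::sd(y); if (y_sd == 0) y_sd <- 1
  Xs <- sweep(sweep(X, 2, x_mu), 2, x_sd, "/")
  ys <- (y - y_mu) / y_sd

  sizes <- c(p, widths, 1L)
  L <- length(sizes) - 1L

  with_seed(config$seed, {
    W <- lapply(seq_len(L), function(l)
      matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                          sd = sqrt(2 / sizes[l])), sizes[l], sizes[l + 1L]))
    b <- lapply(seq_len(L), function(l) numeric(sizes[l + 1L]))

    # validation split: random 10% held out for early stopping
    n_val <- max(1L, floor(config$validation_frac * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    if (!length(tr_idx)) { tr_idx <- seq_len(n); val_idx <- seq_len(n) }

    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0L

    forward <- function(Xb) {
      A <- vector("list", L + 1L); A[[1L]] <- Xb
      for (l in seq_len(L)) {
        Z <- A[[l]] %*% W[[l]]
        Z <- sweep(Z, 2, b[[l]], "+")
        A[[l + 1L]] <- if (l < L) pmax(Z, 0) else Z
      }
      A
    }

    val_loss <- function() {
      pred <- forward(Xs[val_idx, , drop = FALSE])[[L + 1L]]
      mean((pred - ys[val_idx])^2)
    }

    best <- list(W = W, b = b, loss = Inf)
    wait <- 0L
    B <- config$batch_size
    for (epoch in seq_len(config$epochs)) {
      perm <- sample(tr_idx)
      for (s in seq(1L, length(perm), by = B)) {
        rows <- perm[s:min(s + B - 1L, length(perm))]
        A <- forward(Xs[rows, , drop = FALSE])
        m <- length(rows)
        delta <- 2 * (A[[L + 1L]] - ys[rows]) / m
        for (l in rev(seq_len(L))) {
          gW <- crossprod(A[[l]], delta) + 2 * config$l2 * W[[l]]
          gb <- colSums(delta)
          if (l > 1L)
            delta <- (delta %*% t(W[[l]])) * (A[[l]] > 0)
          step <- step + 1L
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          corr1 <- 1 - beta1^step; corr2 <- 1 - beta2^step
          W[[l]] <- W[[l]] - config$learning_rate *
            (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
          b[[l]] <- b[[l]] - config$learning_rate *
            (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
        }
      }
      vl <- val_loss()
      if (vl < best$loss - config$tol) {
        best <- list(W = W, b = b, loss = vl)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    structure(list(W = best$W, b = best$b, sizes = sizes,
                   x_mu = x_mu, x_sd = x_sd, y_mu = y_mu, y_sd = y_sd,
                   config = config, features = colnames(X)),
              class = c("fp_mlp", "fp_regressor"))
  })
}

#' @export
predict.fp_mlp <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata, object$features)
  A <- sweep(sweep(X, 2, object$x_mu), 2, object$x_sd, "/")
  L <- length(object$W)
  for (l in seq_len(L)) {
    A <- sweep(A %*% object$W[[l]], 2, object$b[[l]], "+")
    if (l < L) A <- pmax(A, 0)
  }
  drop(A) * object$y_sd + object$y_mu
}
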