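# Minimal feed-forward regressor: fully-connected ReLU layers with inverted
# dropout, Adam updates, mean-squared-error loss, and per-epoch held-out MSE
# tracking with best-epoch weight snapshots. Matrix-algebra only; sized for
# tabular gene-level features.

mlp_init <- function(d_in, hidden) {
  dims <- c(d_in, hidden, 1L)
  lapply(seq_len(length(dims) - 1L), function(l) {
    list(W = matrix(stats::rnorm(dims[l] * dims[l + 1L],
                                 sd = sqrt(2 / dims[l])),
                    dims[l], dims[l + 1L]),
         b = numeric(dims[l + 1L]))
  })
}

mlp_forward <- function(layers, x, dropout = 0, train = FALSE) {
  L <- length(layers)
  acts <- vector("list", L + 1L)
  masks <- vector("list", L)
  acts[[1L]] <- x
  for (l in seq_len(L)) {
    z <- sweep(acts[[l]] %*% layers[[l]]$W, 2L, layers[[l]]$b, `+`)
    if (l < L) {
      z <- pmax(z, 0)
      if (train && dropout > 0) {
        m <- matrix(stats::runif(length(z)) >= dropout, nrow(z), ncol(z))
        z <- z * m / (1 - dropout)
        masks[[l]] <- m
      }
    }
    acts[[l + 1L]] <- z
  }
  list(acts = acts, masks = masks)
}

mlp_backward <- function(layers, fwd, y, dropout) {
  L <- length(layers)
  n <- length(y)
  grads <- vector("list", L)
  delta <- 2 * (fwd$acts[[L + 1L]] - y) / n
  for (l in rev(seq_len(L))) {
    a_prev <- fwd$acts[[l]]
    grads[[l]] <- list(W = crossprod(a_prev, delta),
                       b = colSums(delta))
    if (l > 1L) {
      delta <- delta %*% t(layers[[l]]$W)
      act <- fwd$acts[[l]]
      delta <- delta * (act > 0)
      if (!is.null(fwd$masks[[l - 1L]])) {
        delta <- delta * fwd$masks[[l - 1L]] / (1 - dropout)
      }
    }
  }
  grads
}

#' @keywords internal
mlp_fit <- function(x, y, x_val, y_val, hidden = c(64, 32, 16),
                    dropout = 0.2, epochs = 50, batch = 128, lr = 1e-3) {
  xc <- colMeans(x)
  xs <- apply(x, 2, stats::sd)
  xs[xs == 0 | !is.finite(xs)] <- 1
  xz <- sweep(sweep(x, 2, xc), 2, xs, `/`)
  xvz <- sweep(sweep(x_val, 2, xc), 2, xs, `/`)
  yc <- mean(y); ys <- stats::sd(y)
  if (!is.finite(ys) || ys == 0) ys <- 1
  yz <- matrix((y - yc) / ys, ncol = 1)
  yvz <- matrix((y_val - yc) / ys, ncol = 1)

  layers <- mlp_init(ncol(x), hidden)
  mom <- lapply(layers, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                         mb = l$b * 0, vb = l$b * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t_step <- 0
  n <- nrow(xz)
  best <- list(mse = Inf, epoch = 0L, layers = layers)
  history <- numeric(epochs)

  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    starts <- seq(1, n, by = batch)
    for (s in starts) {
      rows <- idx[s:min(s + batch - 1, n)]
      fwd <- mlp_forward(layers, xz[rows, , drop = FALSE], dropout,
                         train = TRUE)
      grads <- mlp_backward(layers, fwd, yz[rows, , drop = FALSE], dropout)
      t_step <- t_step + 1
      for (l in seq_along(layers)) {
        mom[[l]]$mW <- b1 * mom[[l]]$mW + (1 - b1) * grads[[l]]$W
        mom[[l]]$vW <- b2 * mom[[l]]$vW + (1 - b2) * grads[[l]]$W^2
        mom[[l]]$mb <- b1 * mom[[l]]$mb + (1 - b1) * grads[[l]]$b
        mom[[l]]$vb <- b2 * mom[[l]]$vb + (1 - b2) * grads[[l]]$b^2
        mhW <- mom[[l]]$mW / (1 - b1^t_step)
        vhW <- mom[[l]]$vW / (1 - b2^t_step)
        mhb <- mom[[l]]$mb / (1 - b1^t_step)
        vhb <- mom[[l]]$vb / (1 - b2^t_step)
        layers[[l]]$W <- layers[[l]]$W - lr * mhW / (sqrt(vhW) + eps)
        layers[[l]]$b <- layers[[l]]$b - lr * mhb / (sqrt(vhb) + eps)
      }
    }
    pred_val <- mlp_forward(layers, xvz)$acts[[length(layers) + 1L]]
    mse <- mean((pred_val - yvz)^2)
    history[ep] <- mse
    if (mse < best$mse) best <- list(mse = mse, epoch = ep, layers = layers)
  }
  list(layers = best$layers, best_epoch = best$epoch, history = history,
       x_center = xc, x_scale = xs, y_center = yc, y_scale = ys,
       hidden = hidden, dropout = dropout)
}

#' @keywords internal
mlp_predict <- function(fit, x) {
  xz <- sweep(sweep(x, 2, fit$x_center), 2, fit$x_scale, `/`)
  out <- mlp_forward(fit$layers, xz)$acts[[length(fit$layers) + 1L]]
  as.numeric(out) * fit$y_scale + fit$y_center
}
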