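# Independent oracles used across the suite. These deliberately use naive
# loops / direct arithmetic so they share no code with the implementation.

# Direct-loop 2D convolution (stride, symmetric zero padding).
conv2d_loop_oracle <- function(x, w, stride, pad) {
  d <- dim(x)
  wd <- dim(w)
  k <- wd[1]
  Ho <- (d[1] + 2 * pad - k) / stride + 1
  Wo <- (d[2] + 2 * pad - k) / stride + 1
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  y <- array(0, c(Ho, Wo, wd[4], d[4]))
  for (n in seq_len(d[4])) for (co in seq_len(wd[4]))
    for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
      acc <- 0
      for (ci in seq_len(d[3])) for (i in seq_len(k)) for (j in seq_len(k))
        acc <- acc + xp[(ho - 1) * stride + i, (wo - 1) * stride + j, ci, n] *
          w[i, j, ci, co]
      y[ho, wo, co, n] <- acc
    }
  y
}

# Pixel-by-pixel confusion counting.
confusion_loop_oracle <- function(pred, target) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && target[i] == 1) tp <- tp + 1L
    else if (pred[i] == 1 && target[i] == 0) fp <- fp + 1L
    else if (pred[i] == 0 && target[i] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Central finite differences of a scalar-valued function of an array.
numeric_gradient <- function(f, x, eps = 1e-6) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small fixed-dimension helpers.
tiny_net_config <- function(depth = 2, base = 4) {
  network_config(depth = depth, in_channels = 1, base_channels = base)
}

random_mask_pair <- function(H = 8, W = 8, p = 0.3) {
  list(pred = matrix(rbinom(H * W, 1, p), H, W),
       target = matrix(rbinom(H * W, 1, p), H, W))
}

# Connected-component count with 8-connectivity (flood fill); independent of
# any image package.
count_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nlab <- 0L
  for (i0 in seq_len(H)) for (j0 in seq_len(W)) {
    if (mask[i0, j0] == 1 && lab[i0, j0] == 0L) {
      nlab <- nlab + 1L
      queue <- list(c(i0, j0))
      lab[i0, j0] <- nlab
      while (length(queue)) {
        ij <- queue[[length(queue)]]
        queue[[length(queue)]] <- NULL
        for (di in -1:1) for (dj in -1:1) {
          i <- ij[1] + di; j <- ij[2] + dj
          if (i >= 1 && i <= H && j >= 1 && j <= W &&
              mask[i, j] == 1 && lab[i, j] == 0L) {
            lab[i, j] <- nlab
            queue[[length(queue) + 1L]] <- c(i, j)
          }
        }
      }
    }
  }
  nlab
}
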