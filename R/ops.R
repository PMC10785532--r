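# Differentiable operators over [H, W, C, N] activation arrays.
# Convolutions dispatch to the C++ im2col kernels; everything else is
# vectorised R. Each operator returns a new tensor node whose backward
# closure captures exactly the values needed for the gradient.

# ---- broadcasting helpers -------------------------------------------------

# Sum over H, W, N for each channel; x is [H, W, C, N].
.channel_sum <- function(x) {
  d <- dim(x)
  cs <- colSums(matrix(x, nrow = d[1] * d[2]))        # length C*N, c fastest
  rowSums(matrix(cs, nrow = d[3]))
}

# Replicate a length-C vector over [H, W, C, N] (relies on recycling over N).
.bc_ch <- function(v, d) rep(v, each = d[1] * d[2])

.as_batch <- function(x, what = "input") {
  if (!is.array(x)) stop(what, " must be an array", call. = FALSE)
  d <- dim(x)
  if (length(d) == 2L) {
    dim(x) <- c(d, 1L, 1L)
  } else if (length(d) == 3L) {
    dim(x) <- c(d, 1L)
  } else if (length(d) != 4L) {
    stop(what, " must have 2-4 dimensions [height, width, channels, batch]",
         call. = FALSE)
  }
  x
}

# ---- convolution ----------------------------------------------------------

op_conv2d <- function(x, w, stride, pad) {
  xv <- x$value
  wv <- w$value
  yv <- cpp_conv2d_forward(xv, wv, as.integer(stride), as.integer(pad))
  new_tensor(yv, list(x, w), function(g) {
    dim(g) <- dim(yv)
    r <- cpp_conv2d_backward(xv, wv, g, as.integer(stride), as.integer(pad))
    list(r$gx, r$gw)
  })
}

op_convt <- function(x, w, stride, pad) {
  xv <- x$value
  wv <- w$value
  yv <- cpp_convt_forward(xv, wv, as.integer(stride), as.integer(pad))
  new_tensor(yv, list(x, w), function(g) {
    dim(g) <- dim(yv)
    r <- cpp_convt_backward(xv, wv, g, as.integer(stride), as.integer(pad))
    list(r$gx, r$gw)
  })
}

# ---- batch normalisation --------------------------------------------------

# state: environment with running_mean, running_var, momentum, eps.
# Training mode uses batch statistics (population variance) and updates the
# running estimates; evaluation mode uses the running estimates.
op_batchnorm <- function(x, gamma, beta, state, training) {
  xv <- x$value
  d <- dim(xv)
  M <- d[1] * d[2] * d[4]
  gv <- gamma$value
  bv <- beta$value
  eps <- state$eps
  if (training) {
    if (M < 2) stop("batch normalisation needs more than one value per channel",
                    call. = FALSE)
    mu <- .channel_sum(xv) / M
    xc <- xv - .bc_ch(mu, d)
    va <- .channel_sum(xc * xc) / M
    inv <- 1 / sqrt(va + eps)
    xhat <- xc * .bc_ch(inv, d)
    mom <- state$momentum
    state$running_mean <- (1 - mom) * state$running_mean + mom * mu
    state$running_var <- (1 - mom) * state$running_var + mom * va
  } else {
    inv <- 1 / sqrt(state$running_var + eps)
    xhat <- (xv - .bc_ch(state$running_mean, d)) * .bc_ch(inv, d)
  }
  yv <- xhat * .bc_ch(gv, d) + .bc_ch(bv, d)
  dim(yv) <- d
  new_tensor(yv, list(x, gamma, beta), function(g) {
    dim(g) <- d
    gg <- .channel_sum(g * xhat)
    gb <- .channel_sum(g)
    gxhat <- g * .bc_ch(gv, d)
    if (training) {
      s1 <- .channel_sum(gxhat)
      s2 <- .channel_sum(gxhat * xhat)
      gx <- (gxhat - .bc_ch(s1 / M, d) - xhat * .bc_ch(s2 / M, d)) * .bc_ch(inv, d)
    } else {
      gx <- gxhat * .bc_ch(inv, d)
    }
    dim(gx) <- d
    list(gx, gg, gb)
  })
}

new_bn_state <- function(channels, momentum = 0.1, eps = 1e-5) {
  s <- new.env(parent = emptyenv())
  s$running_mean <- numeric(channels)
  s$running_var <- rep(1, channels)
  s$momentum <- momentum
  s$eps <- eps
  s
}

# ---- activations ----------------------------------------------------------

op_leaky_relu <- function(x, slope = 0) {
  xv <- x$value
  yv <- pmax(xv, 0) + slope * pmin(xv, 0)
  dim(yv) <- dim(xv)
  new_tensor(yv, list(x), function(g) {
    gx <- g * ifelse(xv > 0, 1, slope)
    dim(gx) <- dim(xv)
    list(gx)
  })
}

op_relu <- function(x) op_leaky_relu(x, 0)

op_sigmoid <- function(x) {
  yv <- 1 / (1 + exp(-x$value))
  dim(yv) <- dim(x$value)
  new_tensor(yv, list(x), function(g) {
    gx <- g * yv * (1 - yv)
    dim(gx) <- dim(yv)
    list(gx)
  })
}

# ---- arithmetic / structural ---------------------------------------------

op_add <- function(x, y) {
  stopifnot(identical(dim(x$value), dim(y$value)))
  new_tensor(x$value + y$value, list(x, y), function(g) list(g, g))
}

op_concat_ch <- function(a, b) {
  da <- dim(a$value)
  db <- dim(b$value)
  if (!identical(da[c(1, 2, 4)], db[c(1, 2, 4)]))
    stop("concatenation requires matching height, width and batch", call. = FALSE)
  d <- c(da[1], da[2], da[3] + db[3], da[4])
  yv <- array(0, d)
  yv[, , seq_len(da[3]), ] <- a$value
  yv[, , da[3] + seq_len(db[3]), ] <- b$value
  new_tensor(yv, list(a, b), function(g) {
    dim(g) <- d
    ga <- g[, , seq_len(da[3]), , drop = FALSE]
    gb <- g[, , da[3] + seq_len(db[3]), , drop = FALSE]
    list(ga, gb)
  })
}

# Multiply x [H,W,C,N] by a single-channel spatial coefficient map a [H,W,1,N],
# broadcast over channels.
op_scale_spatial <- function(x, a) {
  d <- dim(x$value)
  da <- dim(a$value)
  if (da[3] != 1 || !identical(d[c(1, 2, 4)], da[c(1, 2, 4)]))
    stop("coefficient map must be [H, W, 1, N] matching x", call. = FALSE)
  aexp <- a$value[, , rep(1L, d[3]), , drop = FALSE]
  yv <- x$value * aexp
  new_tensor(yv, list(x, a), function(g) {
    dim(g) <- d
    gx <- g * aexp
    ga <- rowSums(aperm(g * x$value, c(1, 2, 4, 3)), dims = 3)
    dim(ga) <- da
    list(gx, ga)
  })
}

# Multiply x [H,W,C,N] by per-channel, per-sample weights s [C,N].
op_scale_channel <- function(x, s) {
  d <- dim(x$value)
  sv <- s$value
  if (!identical(as.integer(dim(sv)), as.integer(d[c(3, 4)])))
    stop("channel weights must be [channels, batch]", call. = FALSE)
  HW <- d[1] * d[2]
  sexp <- rep(as.vector(sv), each = HW)
  yv <- x$value * sexp
  dim(yv) <- d
  new_tensor(yv, list(x, s), function(g) {
    dim(g) <- d
    gx <- g * sexp
    dim(gx) <- d
    gs <- colSums(matrix(g * x$value, nrow = HW))
    dim(gs) <- dim(sv)
    list(gx, gs)
  })
}

# Global average pooling: [H,W,C,N] -> [C,N].
op_global_mean_pool <- function(x) {
  d <- dim(x$value)
  HW <- d[1] * d[2]
  yv <- colSums(matrix(x$value, nrow = HW)) / HW
  dim(yv) <- c(d[3], d[4])
  new_tensor(yv, list(x), function(g) {
    gx <- rep(as.vector(g), each = HW) / HW
    dim(gx) <- d
    list(gx)
  })
}

# Fully connected: W [out,in] %*% x [in,N] + b [out].
op_fc <- function(W, x, b) {
  Wv <- W$value
  xv <- x$value
  yv <- Wv %*% xv + b$value
  new_tensor(yv, list(W, x, b), function(g) {
    dim(g) <- dim(yv)
    list(g %*% t(xv), t(Wv) %*% g, rowSums(g))
  })
}

# Per-channel bias for the 1x1 output head (the only conv not followed by BN).
op_add_channel_bias <- function(x, b) {
  d <- dim(x$value)
  yv <- x$value + .bc_ch(b$value, d)
  dim(yv) <- d
  new_tensor(yv, list(x, b), function(g) {
    dim(g) <- d
    list(g, .channel_sum(g))
  })
}

# ---- loss kernels ---------------------------------------------------------

# Mean Bernoulli cross-entropy with probability clamping; t is a constant
# {0,1} array of the same shape as p.
op_bce <- function(p, t, eps = 1e-7) {
  pv <- p$value
  pc <- pmin(pmax(pv, eps), 1 - eps)
  n <- length(pv)
  val <- -sum(t * log(pc) + (1 - t) * log(1 - pc)) / n
  new_tensor(val, list(p), function(g) {
    inside <- (pv > eps) & (pv < 1 - eps)
    gp <- g * inside * (-(t / pc) + (1 - t) / (1 - pc)) / n
    dim(gp) <- dim(pv)
    list(gp)
  })
}

# Soft Tversky index over pooled soft confusion counts:
#   TP = sum(p*t), FP = sum(p*(1-t)), FN = sum((1-p)*t)
#   index = (TP + s) / (TP + alpha*FP + beta*FN + s)
op_tversky_index <- function(p, t, alpha, beta, smooth) {
  pv <- p$value
  TP <- sum(pv * t)
  FP <- sum(pv * (1 - t))
  FN <- sum((1 - pv) * t)
  D <- TP + alpha * FP + beta * FN + smooth
  val <- (TP + smooth) / D
  new_tensor(val, list(p), function(g) {
    dd <- t + alpha * (1 - t) - beta * t     # d D / d p
    gp <- g * (t * D - (TP + smooth) * dd) / (D * D)
    dim(gp) <- dim(pv)
    list(gp)
  })
}

# Scalar combinators for assembling the hybrid objective.
op_scalar_add <- function(x, y) {
  new_tensor(x$value + y$value, list(x, y), function(g) list(g, g))
}

op_scalar_scale <- function(x, k) {
  new_tensor(k * x$value, list(x), function(g) list(k * g))
}

op_one_minus <- function(x) {
  new_tensor(1 - x$value, list(x), function(g) list(-g))
}
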