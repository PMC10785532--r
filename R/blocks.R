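# Neural building blocks: strided convolution block, deconvolution upsampler,
# attention gate, squeeze-and-excitation module, and SE-Res block.
#
# Each constructor returns an environment holding its parameter tensors (under
# $params, named hierarchically) plus any batch-norm running-state. Blocks are
# applied with the forward() generic and accept either plain arrays
# ([H, W, C] or [H, W, C, N]) or tensors; they return tensors so that
# gradients can flow through composed blocks.

.he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

.pad_for_kernel <- function(k) {
  switch(as.character(k), "1" = 0L, "3" = 1L, "4" = 1L,
         stop("kernel_size must be one of 1, 3, 4", call. = FALSE))
}

.check_channels <- function(x, expected, who) {
  d <- dim(x)
  if (d[3] != expected)
    stop(sprintf("%s: channel dimension is %d but %d expected", who, d[3], expected),
         call. = FALSE)
  invisible(d)
}

.new_block <- function(class) {
  b <- new.env(parent = emptyenv())
  class(b) <- c(class, "seanet_block")
  b
}

#' Apply a block or model to an input
#'
#' @param object A block created by [conv_block()], [deconv_upsample()],
#'   [attention_gate()], [se_module()], [se_res_block()], or a model from
#'   [build_model()].
#' @param input Input feature map: array `[H, W, C]` / `[H, W, C, N]` or a
#'   tensor.
#' @param ... Further arguments passed to methods (e.g. `gating` for the
#'   attention gate, `training` everywhere).
#' @return A `seanet_tensor` holding the output feature map.
#' @export
forward <- function(object, input, ...) UseMethod("forward")

# ---- conv block -----------------------------------------------------------

#' Strided convolution block (conv + BN + leaky ReLU)
#'
#' The encoder's downsampling unit: a bias-free convolution followed by batch
#' normalisation and a leaky rectified activation. With `kernel_size = 4`,
#' `stride = 2` and symmetric padding 1 the spatial dimensions are halved
#' exactly, which is why stride-2 inputs must have even height and width.
#'
#' @param in_channels,out_channels Channel counts.
#' @param kernel_size One of 1, 3, 4.
#' @param stride 1 or 2.
#' @param negative_slope Leaky-ReLU slope in `[0, 1)` (default 0.2).
#' @param name Prefix for parameter names.
#' @return A block object; apply it with [forward()].
#' @export
conv_block <- function(in_channels, out_channels, kernel_size = 4, stride = 2,
                       negative_slope = 0.2, name = "conv_block") {
  stopifnot(in_channels >= 1, out_channels >= 1)
  if (!kernel_size %in% c(1, 3, 4))
    stop("kernel_size must be one of 1, 3, 4", call. = FALSE)
  if (!stride %in% c(1, 2)) stop("stride must be 1 or 2", call. = FALSE)
  if (negative_slope < 0 || negative_slope >= 1)
    stop("negative_slope must lie in [0, 1)", call. = FALSE)
  b <- .new_block("conv_block")
  b$in_channels <- in_channels
  b$out_channels <- out_channels
  b$kernel_size <- kernel_size
  b$stride <- stride
  b$pad <- .pad_for_kernel(kernel_size)
  b$negative_slope <- negative_slope
  b$w <- param_tensor(
    .he_init(c(kernel_size, kernel_size, in_channels, out_channels),
             kernel_size^2 * in_channels),
    paste0(name, ".w"))
  b$gamma <- param_tensor(rep(1, out_channels), paste0(name, ".bn.gamma"))
  b$beta <- param_tensor(numeric(out_channels), paste0(name, ".bn.beta"))
  b$bn <- new_bn_state(out_channels)
  b$params <- stats::setNames(list(b$w, b$gamma, b$beta),
                              c(b$w$name, b$gamma$name, b$beta$name))
  b
}

#' @export
forward.conv_block <- function(object, input, training = FALSE, ...) {
  x <- as_tensor(.wrap_input(input))
  d <- .check_channels(x$value, object$in_channels, "conv_block")
  if (object$stride == 2) {
    if (d[1] %% 2 != 0)
      stop(sprintf("conv_block: stride-2 needs even height, got %d", d[1]),
           call. = FALSE)
    if (d[2] %% 2 != 0)
      stop(sprintf("conv_block: stride-2 needs even width, got %d", d[2]),
           call. = FALSE)
  }
  y <- op_conv2d(x, object$w, object$stride, object$pad)
  y <- op_batchnorm(y, object$gamma, object$beta, object$bn, training)
  op_leaky_relu(y, object$negative_slope)
}

.wrap_input <- function(input) {
  if (inherits(input, "seanet_tensor")) {
    input$value <- .as_batch(input$value)
    input
  } else {
    .as_batch(input)
  }
}

# ---- deconv upsampler -----------------------------------------------------

#' Transposed-convolution upsampler (deconv + BN + ReLU)
#'
#' Kernel 4, stride 2, padding 1: output spatial dimensions are exactly double
#' the input's. Used to expand the deep feature map into the gating signal G
#' of the next attention stage.
#'
#' @inheritParams conv_block
#' @return A block object.
#' @export
deconv_upsample <- function(in_channels, out_channels, name = "deconv") {
  stopifnot(in_channels >= 1, out_channels >= 1)
  b <- .new_block("deconv_upsample")
  b$in_channels <- in_channels
  b$out_channels <- out_channels
  b$w <- param_tensor(.he_init(c(4, 4, out_channels, in_channels),
                               16 * in_channels),
                      paste0(name, ".w"))
  b$gamma <- param_tensor(rep(1, out_channels), paste0(name, ".bn.gamma"))
  b$beta <- param_tensor(numeric(out_channels), paste0(name, ".bn.beta"))
  b$bn <- new_bn_state(out_channels)
  b$params <- stats::setNames(list(b$w, b$gamma, b$beta),
                              c(b$w$name, b$gamma$name, b$beta$name))
  b
}

#' @export
forward.deconv_upsample <- function(object, input, training = FALSE, ...) {
  x <- as_tensor(.wrap_input(input))
  d <- .check_channels(x$value, object$in_channels, "deconv_upsample")
  if (d[1] < 1 || d[2] < 1)
    stop("deconv_upsample: spatial dimensions must be positive", call. = FALSE)
  y <- op_convt(x, object$w, 2L, 1L)
  y <- op_batchnorm(y, object$gamma, object$beta, object$bn, training)
  op_relu(y)
}

# ---- attention gate -------------------------------------------------------

#' Attention gate
#'
#' Computes a single-channel spatial coefficient map
#' `a = sigmoid(convBN(relu(convBN(x) + convBN(G))))` from the shallow feature
#' map `x` and the (already upsampled) deep gating map `G`, then rescales `x`
#' elementwise by `a` (broadcast over channels). Every coefficient lies
#' strictly in (0, 1). The 1x1 convolutions on `x` and `G` both map to
#' `x_channels` intermediate channels.
#'
#' @param x_channels Channels of the shallow feature map.
#' @param g_channels Channels of the gating map.
#' @param name Prefix for parameter names.
#' @return A block object; apply with `forward(gate, x, gating = G)`.
#' @export
attention_gate <- function(x_channels, g_channels, name = "attention_gate") {
  b <- .new_block("attention_gate")
  b$x_channels <- x_channels
  b$g_channels <- g_channels
  b$wx <- param_tensor(.he_init(c(1, 1, x_channels, x_channels), x_channels),
                       paste0(name, ".wx"))
  b$wg <- param_tensor(.he_init(c(1, 1, g_channels, x_channels), g_channels),
                       paste0(name, ".wg"))
  b$psi <- param_tensor(.he_init(c(1, 1, x_channels, 1), x_channels),
                        paste0(name, ".psi"))
  b$gx <- param_tensor(rep(1, x_channels), paste0(name, ".bnx.gamma"))
  b$bx <- param_tensor(numeric(x_channels), paste0(name, ".bnx.beta"))
  b$gg <- param_tensor(rep(1, x_channels), paste0(name, ".bng.gamma"))
  b$bg <- param_tensor(numeric(x_channels), paste0(name, ".bng.beta"))
  b$gp <- param_tensor(rep(1, 1), paste0(name, ".bnp.gamma"))
  b$bp <- param_tensor(numeric(1), paste0(name, ".bnp.beta"))
  b$bnx <- new_bn_state(x_channels)
  b$bng <- new_bn_state(x_channels)
  b$bnp <- new_bn_state(1)
  ps <- list(b$wx, b$wg, b$psi, b$gx, b$bx, b$gg, b$bg, b$gp, b$bp)
  b$params <- stats::setNames(ps, vapply(ps, function(p) p$name, character(1)))
  b
}

#' @export
forward.attention_gate <- function(object, input, gating, training = FALSE, ...) {
  x <- as_tensor(.wrap_input(input))
  G <- as_tensor(.wrap_input(gating))
  dx <- .check_channels(x$value, object$x_channels, "attention_gate (x)")
  dg <- .check_channels(G$value, object$g_channels, "attention_gate (G)")
  if (dx[1] != dg[1] || dx[2] != dg[2])
    stop(sprintf(
      "attention_gate: x is %dx%d but G is %dx%d; upsample G first",
      dx[1], dx[2], dg[1], dg[2]), call. = FALSE)
  hx <- op_batchnorm(op_conv2d(x, object$wx, 1L, 0L),
                     object$gx, object$bx, object$bnx, training)
  hg <- op_batchnorm(op_conv2d(G, object$wg, 1L, 0L),
                     object$gg, object$bg, object$bng, training)
  h <- op_relu(op_add(hx, hg))
  a <- op_sigmoid(op_batchnorm(op_conv2d(h, object$psi, 1L, 0L),
                               object$gp, object$bp, object$bnp, training))
  object$last_attention <- a
  op_scale_spatial(x, a)
}

# ---- squeeze-and-excitation -----------------------------------------------

#' Squeeze-and-excitation module
#'
#' Per-channel global average pooling ("squeeze") followed by a two-layer
#' bottleneck (`n -> max(1, n %/% reduction) -> n`, integer division) ending in
#' a sigmoid ("excitation"); the resulting per-channel weights in (0, 1)
#' rescale the input channels, so the output is an exact per-channel scalar
#' multiple of the input.
#'
#' @param channels Channel count of the input.
#' @param reduction Bottleneck reduction factor (default 8).
#' @param name Prefix for parameter names.
#' @return A block object.
#' @export
se_module <- function(channels, reduction = 8, name = "se") {
  stopifnot(channels >= 1, reduction >= 1)
  b <- .new_block("se_module")
  b$channels <- channels
  b$reduced <- max(1L, channels %/% reduction)
  b$w1 <- param_tensor(.he_init(c(b$reduced, channels), channels),
                       paste0(name, ".fc1.w"))
  # small positive bias keeps the (often single-unit) bottleneck ReLU alive
  # at initialisation
  b$b1 <- param_tensor(rep(0.1, b$reduced), paste0(name, ".fc1.b"))
  b$w2 <- param_tensor(.he_init(c(channels, b$reduced), b$reduced),
                       paste0(name, ".fc2.w"))
  b$b2 <- param_tensor(numeric(channels), paste0(name, ".fc2.b"))
  ps <- list(b$w1, b$b1, b$w2, b$b2)
  b$params <- stats::setNames(ps, vapply(ps, function(p) p$name, character(1)))
  b
}

#' @export
forward.se_module <- function(object, input, training = FALSE, ...) {
  x <- as_tensor(.wrap_input(input))
  .check_channels(x$value, object$channels, "se_module")
  z <- op_global_mean_pool(x)
  h <- op_relu(op_fc(object$w1, z, object$b1))
  s <- op_sigmoid(op_fc(object$w2, h, object$b2))
  object$last_weights <- s
  op_scale_channel(x, s)
}

# ---- SE-Res block ---------------------------------------------------------

#' Squeeze-and-excitation residual block
#'
#' Convolution path `[1x1 conv + BN + ReLU] -> [3x3 conv (pad 1) + BN + ReLU]
#' -> [1x1 conv + BN]` (no activation after the last BN), then the SE module
#' rescales the channels, and the shortcut adds the input back before a final
#' ReLU: `out = relu(x + SE(branch(x)))`. Channel count and spatial dimensions
#' are preserved.
#'
#' @param channels Channel width of the block.
#' @param se_reduction Reduction factor of the embedded SE module.
#' @param name Prefix for parameter names.
#' @return A block object.
#' @export
se_res_block <- function(channels, se_reduction = 8, name = "se_res") {
  b <- .new_block("se_res_block")
  b$channels <- channels
  conv_bn <- function(k, tag) {
    w <- param_tensor(.he_init(c(k, k, channels, channels), k^2 * channels),
                      paste0(name, ".", tag, ".w"))
    g <- param_tensor(rep(1, channels), paste0(name, ".", tag, ".bn.gamma"))
    be <- param_tensor(numeric(channels), paste0(name, ".", tag, ".bn.beta"))
    list(w = w, gamma = g, beta = be, bn = new_bn_state(channels), k = k,
         pad = .pad_for_kernel(k))
  }
  b$c1 <- conv_bn(1, "conv1")
  b$c2 <- conv_bn(3, "conv2")
  b$c3 <- conv_bn(1, "conv3")
  b$se <- se_module(channels, se_reduction, name = paste0(name, ".se"))
  ps <- c(list(b$c1$w, b$c1$gamma, b$c1$beta,
               b$c2$w, b$c2$gamma, b$c2$beta,
               b$c3$w, b$c3$gamma, b$c3$beta),
          unname(b$se$params))
  b$params <- stats::setNames(ps, vapply(ps, function(p) p$name, character(1)))
  b
}

#' @export
forward.se_res_block <- function(object, input, training = FALSE, ...) {
  x <- as_tensor(.wrap_input(input))
  .check_channels(x$value, object$channels, "se_res_block")
  step <- function(h, cb, activate) {
    h <- op_conv2d(h, cb$w, 1L, cb$pad)
    h <- op_batchnorm(h, cb$gamma, cb$beta, cb$bn, training)
    if (activate) op_relu(h) else h
  }
  h <- step(x, object$c1, TRUE)
  h <- step(h, object$c2, TRUE)
  h <- step(h, object$c3, FALSE)
  h <- forward(object$se, h, training = training)
  op_relu(op_add(x, h))
}
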