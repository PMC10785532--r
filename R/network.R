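# Full network assembly: encoder stages, the spiral decoder path, the output
# head, padding helpers and checkpointing.

#' Network configuration
#'
#' @param depth Number of down/up-sampling stages (default 8; input height and
#'   width must be divisible by `2^depth`).
#' @param in_channels Channels of the input images (1 grayscale, 3 RGB).
#' @param base_channels Channel width of the first encoder stage; level `i`
#'   uses `min(base_channels * 2^(i-1), max_channels)` channels.
#' @param max_channels Cap on the channel schedule.
#' @param negative_slope Leaky-ReLU slope used by the encoder blocks.
#' @param se_reduction Reduction factor of the SE modules.
#' @return An object of class `network_config`.
#' @export
network_config <- function(depth = 8, in_channels = 1, base_channels = 32,
                           max_channels = 512, negative_slope = 0.2,
                           se_reduction = 8) {
  stopifnot(depth >= 1, in_channels >= 1, base_channels >= 1,
            max_channels >= base_channels, se_reduction >= 1)
  if (negative_slope < 0 || negative_slope >= 1)
    stop("negative_slope must lie in [0, 1)", call. = FALSE)
  structure(list(depth = as.integer(depth),
                 in_channels = as.integer(in_channels),
                 base_channels = as.integer(base_channels),
                 max_channels = as.integer(max_channels),
                 negative_slope = negative_slope,
                 se_reduction = as.integer(se_reduction)),
            class = "network_config")
}

#' Channel width at an encoder level
#'
#' Level 0 is the input image; level `i >= 1` is the output of the i-th
#' downsampling stage.
#' @param config A [network_config()].
#' @param level Integer in `0:depth`.
#' @return Channel count.
#' @export
channels_at <- function(config, level) {
  if (level == 0) return(config$in_channels)
  min(config$base_channels * 2^(level - 1), config$max_channels)
}

#' Build the segmentation model
#'
#' Constructs `depth` encoder stages (each a stride-2 [conv_block()]) and
#' `depth` decoder stages wired as a closed spiral: at each level, the
#' upsampled deep map G gates the same-level shallow feature through an
#' attention gate while an SE-Res block recalibrates its channels; the two
#' outputs are concatenated and upsampled to become the G of the next,
#' shallower level. The shallow features reach the decoder only through the
#' gate and the SE-Res block, never by direct concatenation. The final
#' full-resolution concatenation passes through a 1x1 convolution and a
#' sigmoid, yielding a per-pixel foreground probability map.
#'
#' @param config A [network_config()].
#' @param seed Optional integer; when given, parameter initialisation is
#'   seeded so that two builds are identical.
#' @return An object of class `seanet_model`.
#' @export
build_model <- function(config, seed = NULL) {
  stopifnot(inherits(config, "network_config"))
  if (!is.null(seed)) set.seed(seed)
  d <- config$depth
  encoders <- vector("list", d)
  for (l in seq_len(d)) {
    encoders[[l]] <- conv_block(channels_at(config, l - 1), channels_at(config, l),
                                kernel_size = 4, stride = 2,
                                negative_slope = config$negative_slope,
                                name = sprintf("enc%d", l))
  }
  levels <- seq(d - 1, 0)            # decoder stages, deepest first
  decoders <- vector("list", d)
  wiring <- list()
  for (k in seq_along(levels)) {
    l <- levels[k]
    up_in <- if (k == 1) channels_at(config, d) else 2 * channels_at(config, l + 1)
    st <- list(
      level = l,
      deconv = deconv_upsample(up_in, channels_at(config, l),
                               name = sprintf("dec%d.up", l)),
      gate = attention_gate(channels_at(config, l), channels_at(config, l),
                            name = sprintf("dec%d.gate", l)),
      se_res = se_res_block(channels_at(config, l), config$se_reduction,
                            name = sprintf("dec%d.seres", l))
    )
    decoders[[k]] <- st
    src <- if (k == 1) sprintf("x%d", d) else sprintf("concat%d", levels[k - 1])
    xl <- sprintf("x%d", l)
    wiring[[length(wiring) + 1L]] <- data.frame(
      from = c(src, xl, sprintf("G%d", l), xl,
               sprintf("gate%d", l), sprintf("seres%d", l)),
      op = c("deconv_upsample", "attention_gate", "attention_gate",
             "se_res_block", "concat", "concat"),
      to = c(sprintf("G%d", l), sprintf("gate%d", l), sprintf("gate%d", l),
             sprintf("seres%d", l), sprintf("concat%d", l), sprintf("concat%d", l)),
      stringsAsFactors = FALSE)
  }
  head_w <- param_tensor(.he_init(c(1, 1, 2 * config$in_channels, 1),
                                  2 * config$in_channels), "head.w")
  head_b <- param_tensor(numeric(1), "head.b")
  params <- list()
  for (e in encoders) params <- c(params, e$params)
  for (st in decoders)
    params <- c(params, st$deconv$params, st$gate$params, st$se_res$params)
  params <- c(params, stats::setNames(list(head_w, head_b),
                                      c("head.w", "head.b")))
  m <- structure(list(config = config, encoders = encoders, decoders = decoders,
                      head_w = head_w, head_b = head_b, params = params,
                      wiring = do.call(rbind, wiring)),
                 class = "seanet_model")
  m
}

#' @export
print.seanet_model <- function(x, ...) {
  cfg <- x$config
  np <- sum(vapply(x$params, function(p) length(p$value), numeric(1)))
  cat(sprintf("SEA-Net model: depth %d, in_channels %d, base %d (%d parameters)\n",
              cfg$depth, cfg$in_channels, cfg$base_channels, np))
  invisible(x)
}

#' Named trainable parameters of a model
#' @param model A `seanet_model`.
#' @return Named list of parameter tensors.
#' @export
named_parameters <- function(model) model$params

#' Wiring graph of the decoder
#'
#' One row per edge (`from`, `op`, `to`); usable to verify that encoder
#' features never reach a concatenation except through an attention gate or an
#' SE-Res block.
#' @param model A `seanet_model`.
#' @return A data frame of edges.
#' @export
model_wiring <- function(model) model$wiring

#' @export
forward.seanet_model <- function(object, input, training = FALSE, ...) {
  cfg <- object$config
  x0 <- as_tensor(.wrap_input(input))
  d <- dim(x0$value)
  .check_channels(x0$value, cfg$in_channels, "model")
  div <- 2^cfg$depth
  if (d[1] %% div != 0 || d[2] %% div != 0)
    stop(sprintf(paste0(
      "input %dx%d is not divisible by 2^depth = %d; ",
      "pad it first with pad_to_valid()"), d[1], d[2], div), call. = FALSE)
  xs <- vector("list", cfg$depth + 1)   # xs[[l + 1]] is the level-l feature
  xs[[1]] <- x0
  for (l in seq_len(cfg$depth))
    xs[[l + 1]] <- forward(object$encoders[[l]], xs[[l]], training = training)
  prev <- xs[[cfg$depth + 1]]           # bottleneck: deepest encoder output
  for (st in object$decoders) {
    G <- forward(st$deconv, prev, training = training)
    xdot <- forward(st$gate, xs[[st$level + 1]], gating = G, training = training)
    xddot <- forward(st$se_res, xs[[st$level + 1]], training = training)
    prev <- op_concat_ch(xdot, xddot)
  }
  logits <- op_add_channel_bias(op_conv2d(prev, object$head_w, 1L, 0L),
                                object$head_b)
  op_sigmoid(logits)
}

#' Run the model on a batch of images
#'
#' Convenience wrapper around [forward()] returning the probability map as a
#' numeric array.
#' @param model A `seanet_model`.
#' @param images Array `[H, W, C]` or `[H, W, C, N]`.
#' @param training Use batch statistics and record the graph (TRUE) or run in
#'   deterministic evaluation mode (FALSE, default).
#' @return Probability array `[H, W, 1, N]` with values in (0, 1).
#' @export
model_forward <- function(model, images, training = FALSE) {
  tensor_value(forward(model, images, training = training))
}

# ---- padding --------------------------------------------------------------

#' Pad an image so its dimensions divide 2^depth
#'
#' Zero-pads on the right and bottom up to the next multiple of `2^depth` and
#' returns a crop record with which [crop_to_original()] restores the original
#' dimensions exactly.
#'
#' @param image Array `[H, W]`, `[H, W, C]` or `[H, W, C, N]`.
#' @param depth Network depth.
#' @return `list(image = padded array, crop = list(height, width))`.
#' @export
pad_to_valid <- function(image, depth) {
  x <- .as_batch(image, "image")
  d <- dim(x)
  m <- 2^depth
  Hp <- ceiling(d[1] / m) * m
  Wp <- ceiling(d[2] / m) * m
  crop <- list(height = d[1], width = d[2])
  if (Hp == d[1] && Wp == d[2]) return(list(image = x, crop = crop))
  out <- array(0, c(Hp, Wp, d[3], d[4]))
  out[seq_len(d[1]), seq_len(d[2]), , ] <- x
  list(image = out, crop = crop)
}

#' Restore the original dimensions after prediction
#' @param x Array `[H, W, C, N]` (e.g. a probability map on the padded grid).
#' @param crop Crop record from [pad_to_valid()].
#' @return The array cropped back to the original height and width.
#' @export
crop_to_original <- function(x, crop) {
  x <- .as_batch(x)
  x[seq_len(crop$height), seq_len(crop$width), , , drop = FALSE]
}

# ---- checkpointing --------------------------------------------------------

.bn_states <- function(model) {
  states <- list()
  add <- function(tag, s) states[[tag]] <<- list(running_mean = s$running_mean,
                                                 running_var = s$running_var)
  for (i in seq_along(model$encoders)) add(sprintf("enc%d", i), model$encoders[[i]]$bn)
  for (st in model$decoders) {
    l <- st$level
    add(sprintf("dec%d.up", l), st$deconv$bn)
    add(sprintf("dec%d.bnx", l), st$gate$bnx)
    add(sprintf("dec%d.bng", l), st$gate$bng)
    add(sprintf("dec%d.bnp", l), st$gate$bnp)
    add(sprintf("dec%d.c1", l), st$se_res$c1$bn)
    add(sprintf("dec%d.c2", l), st$se_res$c2$bn)
    add(sprintf("dec%d.c3", l), st$se_res$c3$bn)
  }
  states
}

.restore_bn_states <- function(model, states) {
  put <- function(tag, s) {
    st <- states[[tag]]
    s$running_mean <- st$running_mean
    s$running_var <- st$running_var
  }
  for (i in seq_along(model$encoders)) put(sprintf("enc%d", i), model$encoders[[i]]$bn)
  for (st in model$decoders) {
    l <- st$level
    put(sprintf("dec%d.up", l), st$deconv$bn)
    put(sprintf("dec%d.bnx", l), st$gate$bnx)
    put(sprintf("dec%d.bng", l), st$gate$bng)
    put(sprintf("dec%d.bnp", l), st$gate$bnp)
    put(sprintf("dec%d.c1", l), st$se_res$c1$bn)
    put(sprintf("dec%d.c2", l), st$se_res$c2$bn)
    put(sprintf("dec%d.c3", l), st$se_res$c3$bn)
  }
  invisible(model)
}

#' Snapshot all model state (parameters + BN running statistics)
#' @param model A `seanet_model`.
#' @return A plain list, suitable for saving.
#' @export
model_state <- function(model) {
  list(config = unclass(model$config),
       params = lapply(model$params, tensor_value),
       bn = .bn_states(model))
}

#' Load a state snapshot into a model
#' @param model A `seanet_model` built from the same configuration.
#' @param state A snapshot from [model_state()].
#' @return The model, invisibly.
#' @export
load_model_state <- function(model, state) {
  stopifnot(identical(sort(names(model$params)), sort(names(state$params))))
  for (nm in names(state$params)) {
    v <- state$params[[nm]]
    cur <- model$params[[nm]]$value
    dim(v) <- dim(cur)
    model$params[[nm]]$value <- v
  }
  .restore_bn_states(model, state$bn)
  invisible(model)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single archive holding the configuration and every
#' parameter array plus batch-norm running statistics; `save -> load` gives a
#' bit-identical evaluation-mode forward pass.
#' @param model A `seanet_model`.
#' @param path File path.
#' @return `save_checkpoint`: the path, invisibly. `load_checkpoint`: a
#'   rebuilt `seanet_model`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model_state(model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  state <- readRDS(path)
  config <- do.call(network_config, state$config)
  model <- build_model(config)
  load_model_state(model, state)
  model
}

# ---- optimiser ------------------------------------------------------------

#' Adam optimiser
#'
#' Defaults follow the training recipe used throughout the package:
#' `beta1 = 0`, `beta2 = 0.9`, learning rate `1e-4`.
#'
#' @param params Named list of parameter tensors.
#' @param lr Learning rate.
#' @param beta1,beta2 Exponential decay rates of the moment estimates.
#' @param eps Numerical stabiliser.
#' @return An optimiser environment with a `$step()` function.
#' @export
adam_optimizer <- function(params, lr = 1e-4, beta1 = 0, beta2 = 0.9,
                           eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$params <- params
  opt$m <- lapply(params, function(p) p$value * 0)
  opt$v <- opt$m
  opt$t <- 0L
  opt$step <- function() {
    opt$t <- opt$t + 1L
    bc1 <- 1 - beta1^opt$t
    bc2 <- 1 - beta2^opt$t
    for (nm in names(opt$params)) {
      p <- opt$params[[nm]]
      g <- p$grad
      if (is.null(g)) next
      opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
      opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
      mhat <- opt$m[[nm]] / bc1
      vhat <- opt$v[[nm]] / bc2
      p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  opt
}

`%||%` <- function(a, b) if (is.null(a)) b else a
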