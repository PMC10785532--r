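# Data loading, the seeded training loop, prediction and evaluation.

#' Training configuration
#'
#' Optimiser defaults are the package's standard recipe: Adam with
#' `beta1 = 0`, `beta2 = 0.9` and learning rate `1e-4`.
#'
#' @param epochs Number of passes over the dataset.
#' @param batch_size Images per update (must be at least 2: batch
#'   normalisation needs batch statistics).
#' @param learning_rate,adam_beta1,adam_beta2 Adam settings.
#' @param tversky A [tversky_params()] object (set `lambda_weight = 0` for a
#'   cross-entropy-only objective).
#' @param network A [network_config()] object.
#' @param seed Integer seed controlling initialisation and data order.
#' @param checkpoint_path Optional path; when given, the best-by-training-Dice
#'   state is saved there.
#' @param log_interval Steps between progress messages.
#' @param max_steps Optional hard cap on the number of optimisation steps.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 10, batch_size = 4, learning_rate = 1e-4,
                         adam_beta1 = 0, adam_beta2 = 0.9,
                         tversky = tversky_params(),
                         network = network_config(),
                         seed = 0, checkpoint_path = NULL,
                         log_interval = 50, max_steps = NULL) {
  stopifnot(epochs >= 1, batch_size >= 2, learning_rate > 0,
            inherits(tversky, "tversky_params"),
            inherits(network, "network_config"))
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, tversky = tversky, network = network,
                 seed = as.integer(seed), checkpoint_path = checkpoint_path,
                 log_interval = as.integer(log_interval),
                 max_steps = if (is.null(max_steps)) NULL else as.integer(max_steps)),
            class = "train_config")
}

#' Load a segmentation dataset
#'
#' `"png_pairs"` pairs `image_*.png` with `mask_*.png` by filename suffix; an
#' image without its mask (or vice versa) is a hard error naming the orphan.
#' `"nifti_volume"` reads `image.nii[.gz]` and `mask.nii[.gz]` from the
#' directory, slices both along `slice_axis`, min-max normalises each image
#' slice to `[0, 1]` (constant slices map to 0) and binarises mask slices at
#' `> 0`.
#'
#' @param path Directory containing the files.
#' @param kind `"png_pairs"` or `"nifti_volume"`.
#' @param slice_axis Axis along which volumes are sliced (default 3, the last).
#' @return A list of [segmentation_sample()] objects.
#' @export
load_dataset <- function(path, kind = c("png_pairs", "nifti_volume"),
                         slice_axis = 3) {
  kind <- match.arg(kind)
  if (!dir.exists(path)) stop("dataset path does not exist: ", path, call. = FALSE)
  if (kind == "png_pairs") {
    imgs <- sort(list.files(path, pattern = "^image_.*\\.png$"))
    msks <- sort(list.files(path, pattern = "^mask_.*\\.png$"))
    suf <- function(x, pre) sub("\\.png$", "", sub(pre, "", x))
    is <- suf(imgs, "^image_")
    ms <- suf(msks, "^mask_")
    orphans <- c(paste0("image_", setdiff(is, ms), ".png", recycle0 = TRUE),
                 paste0("mask_", setdiff(ms, is), ".png", recycle0 = TRUE))
    if (length(orphans))
      stop("unpaired files in ", path, ": ", paste(orphans, collapse = ", "),
           call. = FALSE)
    lapply(seq_along(imgs), function(i) {
      img <- png::readPNG(file.path(path, imgs[i]))
      if (length(dim(img)) == 2) dim(img) <- c(dim(img), 1L)
      if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]  # drop alpha
      msk <- png::readPNG(file.path(path, msks[i]))
      if (length(dim(msk)) == 3) msk <- msk[, , 1]
      if (!identical(dim(img)[1:2], dim(msk)[1:2]))
        stop(sprintf("dimension mismatch between %s and %s", imgs[i], msks[i]),
             call. = FALSE)
      segmentation_sample(img, (msk > 0) * 1, is[i])
    })
  } else {
    find1 <- function(stem) {
      hits <- list.files(path, pattern = paste0("^", stem, "\\.nii(\\.gz)?$"),
                         full.names = TRUE)
      if (!length(hits))
        stop("no ", stem, ".nii[.gz] in ", path, call. = FALSE)
      hits[1]
    }
    vol <- as.array(RNifti::readNifti(find1("image")))
    msk <- as.array(RNifti::readNifti(find1("mask")))
    if (!identical(dim(vol), dim(msk)))
      stop("image and mask volumes have different dimensions", call. = FALSE)
    nd <- length(dim(vol))
    stopifnot(slice_axis >= 1, slice_axis <= nd)
    n <- dim(vol)[slice_axis]
    lapply(seq_len(n), function(s) {
      idx <- rep(list(quote(expr = )), nd)
      idx[[slice_axis]] <- s
      sl <- do.call(`[`, c(list(vol), idx))
      ml <- do.call(`[`, c(list(msk), idx))
      rg <- range(sl)
      sl <- if (diff(rg) > 0) (sl - rg[1]) / diff(rg) else sl * 0
      dim(sl) <- c(dim(sl), 1L)
      segmentation_sample(sl, (ml > 0) * 1, sprintf("slice_%03d", s))
    })
  }
}

#' Split samples into training and test sets
#'
#' Whole-image split at the given ratio (default 3:1 train:test), seeded and
#' deterministic.
#' @param samples List of samples.
#' @param train_fraction Fraction assigned to training (default 0.75).
#' @param seed Integer seed.
#' @return `list(train = ..., test = ...)`.
#' @export
split_samples <- function(samples, train_fraction = 0.75, seed = 0) {
  set.seed(seed)
  n <- length(samples)
  ntr <- max(1, round(train_fraction * n))
  ord <- sample.int(n)
  list(train = samples[sort(ord[seq_len(ntr)])],
       test = samples[sort(ord[setdiff(seq_len(n), seq_len(ntr))])])
}

.stack_batch <- function(samples, idx) {
  d <- dim(samples[[idx[1]]]$image)
  x <- array(0, c(d[1], d[2], d[3], length(idx)))
  t <- array(0, c(d[1], d[2], 1L, length(idx)))
  for (j in seq_along(idx)) {
    s <- samples[[idx[j]]]
    if (!identical(dim(s$image), d))
      stop("batches of unequal image sizes are rejected; pad the images first",
           call. = FALSE)
    x[, , , j] <- s$image
    t[, , 1, j] <- s$mask
  }
  list(x = x, t = t)
}

#' Train a segmentation model
#'
#' Minimises the hybrid objective with Adam, fully seeded (initialisation and
#' data order). Logs per-step loss components and training Dice (computed on
#' the binarised training-mode predictions of each batch), tracks the
#' best-by-training-Dice state in memory and, when `checkpoint_path` is set,
#' on disk. Aborts with batch diagnostics on a non-finite loss.
#'
#' @param config A [train_config()].
#' @param dataset Nonempty list of [segmentation_sample()] objects with equal
#'   dimensions; `batch_size` must not exceed the dataset size.
#' @param quiet Suppress progress messages.
#' @return An object of class `seanet_fit`: `model` (final state), `history`
#'   (one row per step), `best_dice`, `best_step`, `best_state` (snapshot at
#'   the best step) and `config`.
#' @export
train <- function(config, dataset, quiet = FALSE) {
  stopifnot(inherits(config, "train_config"), length(dataset) >= 1)
  if (config$batch_size > length(dataset))
    stop("batch_size exceeds dataset size", call. = FALSE)
  set.seed(config$seed)
  if (!quiet) message(sprintf("training with seed %d", config$seed))
  model <- build_model(config$network)
  opt <- adam_optimizer(model$params, lr = config$learning_rate,
                        beta1 = config$adam_beta1, beta2 = config$adam_beta2)
  n <- length(dataset)
  step <- 0L
  best_dice <- -Inf
  best_step <- NA_integer_
  best_state <- NULL
  hist <- list()
  done <- FALSE
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    nb <- n %/% config$batch_size
    for (bi in seq_len(max(1, nb))) {
      idx <- ord[((bi - 1) * config$batch_size + 1):min(bi * config$batch_size, n)]
      if (length(idx) < 2) next
      batch <- .stack_batch(dataset, idx)
      out <- forward(model, batch$x, training = TRUE)
      loss <- hybrid_loss(out, batch$t, config$tversky)
      tot <- tensor_value(loss$total)
      if (!is.finite(tot)) {
        stop(sprintf(paste0(
          "non-finite loss at step %d (ce %.4g, tversky %.4g; ",
          "batch prob range [%.4g, %.4g])"),
          step + 1L, tensor_value(loss$ce_component),
          tensor_value(loss$tversky_component),
          min(tensor_value(out)), max(tensor_value(out))), call. = FALSE)
      }
      zero_grad(model$params)
      backward(loss$total)
      opt$step()
      step <- step + 1L
      bd <- dice(confusion_counts(binarize(tensor_value(out)), batch$t))
      hist[[step]] <- data.frame(step = step, epoch = epoch, total = tot,
                                 ce = tensor_value(loss$ce_component),
                                 tversky = tensor_value(loss$tversky_component),
                                 dice = bd)
      if (bd > best_dice) {
        best_dice <- bd
        best_step <- step
        best_state <- model_state(model)
        if (!is.null(config$checkpoint_path))
          saveRDS(best_state, config$checkpoint_path)
      }
      if (!quiet && step %% config$log_interval == 0)
        message(sprintf("step %4d  loss %.4f (ce %.4f, tversky %.4f)  dice %.4f",
                        step, tot, tensor_value(loss$ce_component),
                        tensor_value(loss$tversky_component), bd))
      if (!is.null(config$max_steps) && step >= config$max_steps) {
        done <- TRUE
        break
      }
    }
    if (done) break
  }
  structure(list(model = model, history = do.call(rbind, hist),
                 best_dice = best_dice, best_step = best_step,
                 best_state = best_state, config = config),
            class = "seanet_fit")
}

#' @export
print.seanet_fit <- function(x, ...) {
  cat(sprintf("seanet fit: %d steps, best training Dice %.4f at step %d\n",
              nrow(x$history), x$best_dice, x$best_step))
  invisible(x)
}

#' Restore the best-by-training-Dice state into the fitted model
#' @param fit A `seanet_fit`.
#' @return The model with the best state loaded, invisibly.
#' @export
restore_best <- function(fit) {
  load_model_state(fit$model, fit$best_state)
  invisible(fit$model)
}

#' Predict masks for a set of images
#'
#' Pads each image to the next valid size with [pad_to_valid()], runs an
#' evaluation-mode forward pass, crops back, and binarises at `threshold`.
#' When `out_dir` is given, masks are written as 0/255 PNG files.
#'
#' @param model A `seanet_model`.
#' @param images List of [segmentation_sample()] objects or arrays.
#' @param threshold Binarisation threshold.
#' @param out_dir Optional output directory for PNG masks.
#' @return A list with one element per image: `list(prob, mask, id)`.
#' @export
predict_masks <- function(model, images, threshold = 0.5, out_dir = NULL) {
  if (inherits(images, "segmentation_sample") || is.array(images))
    images <- list(images)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  lapply(seq_along(images), function(i) {
    im <- images[[i]]
    id <- if (inherits(im, "segmentation_sample")) im$id else sprintf("image_%03d", i)
    arr <- if (inherits(im, "segmentation_sample")) im$image else im
    arr <- .as_batch(arr, "image")
    if (dim(arr)[3] != model$config$in_channels)
      stop(sprintf("image has %d channels but the model expects %d",
                   dim(arr)[3], model$config$in_channels), call. = FALSE)
    padded <- pad_to_valid(arr, model$config$depth)
    prob <- model_forward(model, padded$image, training = FALSE)
    prob <- crop_to_original(prob, padded$crop)[, , 1, 1]
    mask <- binarize(prob, threshold)
    if (!is.null(out_dir))
      png::writePNG(mask, file.path(out_dir, paste0(id, "_mask.png")))
    list(prob = prob, mask = mask, id = id)
  })
}

#' Evaluate a model on a labelled dataset
#'
#' Per-image Dice, sensitivity, specificity and accuracy via [metric_table()],
#' plus the summary row; optionally written as CSV.
#'
#' @param model A `seanet_model`.
#' @param dataset Nonempty list of [segmentation_sample()] objects.
#' @param threshold Binarisation threshold.
#' @param aggregate `"per_image"` or `"pooled"` (see [metric_table()]).
#' @param csv_path Optional CSV output path.
#' @return The metric data frame.
#' @export
evaluate_model <- function(model, dataset, threshold = 0.5,
                           aggregate = "per_image", csv_path = NULL) {
  if (!length(dataset)) stop("empty dataset", call. = FALSE)
  preds <- predict_masks(model, dataset, threshold = threshold)
  metric_table(lapply(preds, `[[`, "mask"),
               lapply(dataset, `[[`, "mask"),
               ids = vapply(dataset, `[[`, character(1), "id"),
               aggregate = aggregate, csv_path = csv_path)
}
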