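# Training objectives: pixelwise cross-entropy, the soft Tversky index, and
# the hybrid objective total = CE + lambda * (1 - Tversky index).
#
# All three accept either plain numeric arrays (returning numbers) or tensors
# (returning differentiable tensor nodes); both paths share the same fused
# kernels in ops.R.

#' Tversky loss parameters
#'
#' `alpha` weights false positives and `beta` false negatives in the soft
#' Tversky index `(TP + s) / (TP + alpha*FP + beta*FN + s)`; at
#' `alpha = beta = 0.5` the index is the Dice coefficient, at
#' `alpha = beta = 1` the Jaccard coefficient. The defaults `alpha = 0.3`,
#' `beta = 0.7` weight recall more heavily, the usual choice for small-target
#' class-imbalanced masks. `lambda_weight` scales the Tversky term in the
#' hybrid objective (default 10, the brain-MRI setting). The smoothing
#' constant makes empty-vs-empty masks score index 1 (loss 0) instead of 0/0.
#'
#' @param alpha,beta Non-negative trade-off weights.
#' @param smooth Small positive smoothing constant.
#' @param lambda_weight Non-negative weight of the Tversky component.
#' @return An object of class `tversky_params`.
#' @export
tversky_params <- function(alpha = 0.3, beta = 0.7, smooth = 1e-6,
                           lambda_weight = 10) {
  stopifnot(alpha >= 0, beta >= 0, smooth > 0, lambda_weight >= 0)
  if (alpha + beta == 0 && !(alpha == 0 && beta == 0))
    stop("alpha + beta must be positive, or both exactly zero", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, smooth = smooth,
                 lambda_weight = lambda_weight),
            class = "tversky_params")
}

.check_shapes <- function(probs, target) {
  dp <- dim(probs) %||% length(probs)
  dt <- dim(target) %||% length(target)
  if (!identical(as.integer(dp), as.integer(dt)))
    stop(sprintf("probability map [%s] and mask [%s] have different shapes",
                 paste(dp, collapse = "x"), paste(dt, collapse = "x")),
         call. = FALSE)
  invisible(TRUE)
}

.loss_inputs <- function(probs, target) {
  tv <- if (inherits(target, "seanet_tensor")) target$value else target
  pv <- if (inherits(probs, "seanet_tensor")) probs$value else probs
  .check_shapes(pv, tv)
  list(p = as_tensor(probs), t = tv, tensor_in = inherits(probs, "seanet_tensor"))
}

#' Pixelwise Bernoulli cross-entropy
#'
#' Mean over all pixels and samples of `-(t*log(p) + (1-t)*log(1-p))`, with
#' probabilities clamped to `[1e-7, 1 - 1e-7]` before the logarithm.
#'
#' @param probs Predicted probabilities in (0, 1): numeric array or tensor.
#' @param target Binary mask of the same shape.
#' @return A non-negative number, or a scalar tensor when `probs` is a tensor.
#' @export
cross_entropy_loss <- function(probs, target) {
  li <- .loss_inputs(probs, target)
  out <- op_bce(li$p, li$t)
  if (li$tensor_in) out else tensor_value(out)
}

#' Soft Tversky index
#'
#' Soft confusion counts `TP = sum(p*t)`, `FP = sum(p*(1-t))`,
#' `FN = sum((1-p)*t)` pooled over the whole input give
#' `(TP + s) / (TP + alpha*FP + beta*FN + s)`.
#'
#' @inheritParams cross_entropy_loss
#' @param params A [tversky_params()] object.
#' @return A number in `[0, 1]`, or a scalar tensor when `probs` is a tensor.
#' @export
tversky_index <- function(probs, target, params = tversky_params()) {
  li <- .loss_inputs(probs, target)
  out <- op_tversky_index(li$p, li$t, params$alpha, params$beta, params$smooth)
  if (li$tensor_in) out else tensor_value(out)
}

#' Hybrid cross-entropy + Tversky objective
#'
#' `total = CE + lambda * (1 - tversky_index)`. The cross-entropy term drives
#' fast early convergence; the Tversky term keeps gradient mass on scarce
#' foreground pixels once CE has shrunk.
#'
#' @inheritParams tversky_index
#' @return A list of class `loss_value` with `total`, `ce_component` and
#'   `tversky_component` (`tversky_component = 1 - index`). Components are
#'   scalar tensors when `probs` is a tensor, numbers otherwise; the invariant
#'   `total == ce_component + lambda_weight * tversky_component` holds either
#'   way.
#' @export
hybrid_loss <- function(probs, target, params = tversky_params()) {
  li <- .loss_inputs(probs, target)
  ce <- op_bce(li$p, li$t)
  idx <- op_tversky_index(li$p, li$t, params$alpha, params$beta, params$smooth)
  tv <- op_one_minus(idx)
  total <- op_scalar_add(ce, op_scalar_scale(tv, params$lambda_weight))
  out <- list(total = total, ce_component = ce, tversky_component = tv)
  if (!li$tensor_in) out <- lapply(out, tensor_value)
  structure(out, class = "loss_value")
}
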