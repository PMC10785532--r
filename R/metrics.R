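# Binary-mask evaluation: exact confusion counts and the four reported
# metrics (Dice, sensitivity, specificity, accuracy).

#' Pixelwise confusion counts
#'
#' Exact integer counts from comparing two strictly binary masks of identical
#' shape. No thresholding happens here; binarize probabilities first with
#' [binarize()].
#'
#' @param pred_mask,target Binary arrays (values 0/1) of identical shape.
#' @return An object of class `confusion_counts` with fields `tp`, `fp`,
#'   `fn`, `tn`; they always sum to the total pixel count.
#' @export
confusion_counts <- function(pred_mask, target) {
  .check_shapes(pred_mask, target)
  if (!all(pred_mask == 0 | pred_mask == 1))
    stop("pred_mask is not binary; apply binarize() first", call. = FALSE)
  if (!all(target == 0 | target == 1))
    stop("target mask is not binary", call. = FALSE)
  p <- pred_mask != 0
  t <- target != 0
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 fn = sum(!p & t), tn = sum(!p & !t)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP %d  FP %d  FN %d  TN %d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Dice coefficient
#'
#' `2*TP / (2*TP + FP + FN)`; defined as 1 when both masks are empty.
#' @param c A [confusion_counts()] object.
#' @return A number in `[0, 1]`.
#' @export
dice <- function(c) {
  den <- 2 * c$tp + c$fp + c$fn
  if (den == 0) return(1)
  2 * c$tp / den
}

#' Sensitivity (true-positive rate)
#'
#' `TP / (TP + FN)`; defined as 1 (with a warning) when the target has no
#' foreground.
#' @inheritParams dice
#' @return A number in `[0, 1]`.
#' @export
sensitivity <- function(c) {
  den <- c$tp + c$fn
  if (den == 0) {
    warning("no foreground pixels in target; sensitivity defined as 1")
    return(1)
  }
  c$tp / den
}

#' Specificity (true-negative rate)
#'
#' `TN / (TN + FP)`; defined as 1 (with a warning) when the target has no
#' background.
#' @inheritParams dice
#' @return A number in `[0, 1]`.
#' @export
specificity <- function(c) {
  den <- c$tn + c$fp
  if (den == 0) {
    warning("no background pixels in target; specificity defined as 1")
    return(1)
  }
  c$tn / den
}

#' Accuracy
#'
#' Proportion of correctly classified pixels, `(TP + TN) / (TP + TN + FP + FN)`.
#' @inheritParams dice
#' @return A number in `[0, 1]`.
#' @export
accuracy <- function(c) {
  den <- c$tp + c$tn + c$fp + c$fn
  if (den == 0) {
    warning("empty masks; accuracy defined as 1")
    return(1)
  }
  (c$tp + c$tn) / den
}

#' Threshold a probability map into a binary mask
#'
#' Pixels with `p >= threshold` become 1.
#' @param probs Numeric array of probabilities.
#' @param threshold Threshold in (0, 1), default 0.5.
#' @return A binary array of the same shape.
#' @export
binarize <- function(probs, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  out <- (probs >= threshold) * 1
  dim(out) <- dim(probs)
  out
}

#' Per-image metric table
#'
#' Computes Dice, sensitivity, specificity and accuracy per image and appends
#' a summary row. Per-image averaging (`aggregate = "per_image"`) matches the
#' usual dataset-level reporting; `"pooled"` instead sums the confusion counts
#' over all images and derives the metrics from the pooled counts.
#'
#' @param pred_masks,targets Lists of binary masks (pairwise identical shapes).
#' @param ids Character identifiers, one per image.
#' @param aggregate `"per_image"` (default) or `"pooled"`.
#' @param csv_path Optional path; when given the table is written as CSV.
#' @return A data frame with one row per image plus a `mean` (or `pooled`)
#'   row.
#' @export
metric_table <- function(pred_masks, targets, ids = NULL,
                         aggregate = c("per_image", "pooled"),
                         csv_path = NULL) {
  aggregate <- match.arg(aggregate)
  n <- length(pred_masks)
  stopifnot(n >= 1, length(targets) == n)
  if (is.null(ids)) ids <- sprintf("image_%03d", seq_len(n))
  rows <- vector("list", n)
  counts <- list(tp = 0, fp = 0, fn = 0, tn = 0)
  for (i in seq_len(n)) {
    cc <- confusion_counts(pred_masks[[i]], targets[[i]])
    counts <- Map(`+`, counts, cc[c("tp", "fp", "fn", "tn")])
    rows[[i]] <- data.frame(id = ids[i], dice = dice(cc),
                            sensitivity = suppressWarnings(sensitivity(cc)),
                            specificity = suppressWarnings(specificity(cc)),
                            accuracy = accuracy(cc),
                            stringsAsFactors = FALSE)
  }
  tbl <- do.call(rbind, rows)
  if (aggregate == "per_image") {
    summary_row <- data.frame(id = "mean", dice = mean(tbl$dice),
                              sensitivity = mean(tbl$sensitivity),
                              specificity = mean(tbl$specificity),
                              accuracy = mean(tbl$accuracy),
                              stringsAsFactors = FALSE)
  } else {
    pc <- structure(counts, class = "confusion_counts")
    summary_row <- data.frame(id = "pooled", dice = dice(pc),
                              sensitivity = suppressWarnings(sensitivity(pc)),
                              specificity = suppressWarnings(specificity(pc)),
                              accuracy = accuracy(pc),
                              stringsAsFactors = FALSE)
  }
  tbl <- rbind(tbl, summary_row)
  if (!is.null(csv_path)) utils::write.csv(tbl, csv_path, row.names = FALSE)
  tbl
}
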