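#' @useDynLib seanet, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Reverse-mode differentiation core.
#
# A tensor node is an environment holding a numeric value, an accumulated
# gradient, references to its parent nodes, and a backward closure returning
# the gradients with respect to each parent. Node ids increase monotonically
# with creation, so the reverse creation order of the nodes reachable from a
# loss is a valid topological order for backpropagation.

.seanet <- new.env(parent = emptyenv())
.seanet$next_id <- 1L

.next_id <- function() {
  id <- .seanet$next_id
  .seanet$next_id <- id + 1L
  id
}

#' Create a tensor node
#'
#' Tensors carry the activations flowing through the network ("feature maps",
#' stored as `[height, width, channels, batch]` arrays) as well as scalar loss
#' values. Nodes created by operators record how to propagate gradients back
#' to their parents.
#'
#' @param value Numeric array or scalar.
#' @param parents List of parent tensors (empty for leaves).
#' @param backward_fn Closure mapping the output gradient to a list of parent
#'   gradients (aligned with `parents`), or `NULL` for leaves.
#' @param name Optional diagnostic name.
#' @return An object of class `seanet_tensor`.
#' @export
new_tensor <- function(value, parents = list(), backward_fn = NULL, name = NULL) {
  t <- new.env(parent = emptyenv())
  t$value <- value
  t$grad <- NULL
  t$parents <- parents
  t$backward_fn <- backward_fn
  t$requires_grad <- !is.null(backward_fn) &&
    any(vapply(parents, function(p) isTRUE(p$requires_grad), logical(1)))
  t$id <- .next_id()
  t$name <- name
  t$is_param <- FALSE
  class(t) <- "seanet_tensor"
  t
}

#' Create a trainable parameter tensor
#'
#' @param value Initial numeric value.
#' @param name Parameter name (used in gradient-coverage diagnostics and
#'   checkpoints).
#' @return A `seanet_tensor` with `requires_grad = TRUE`.
#' @export
param_tensor <- function(value, name) {
  t <- new_tensor(value, name = name)
  t$requires_grad <- TRUE
  t$is_param <- TRUE
  t
}

#' Coerce to tensor
#'
#' Arrays pass through as constant (non-differentiable) leaves; tensors are
#' returned unchanged.
#' @param x Numeric array or `seanet_tensor`.
#' @return A `seanet_tensor`.
#' @export
as_tensor <- function(x) {
  if (inherits(x, "seanet_tensor")) x else new_tensor(x)
}

#' Extract the numeric value of a tensor
#' @param x A `seanet_tensor`.
#' @return The underlying numeric array or scalar.
#' @export
tensor_value <- function(x) x$value

#' @export
print.seanet_tensor <- function(x, ...) {
  d <- dim(x$value)
  cat("<seanet_tensor",
      if (is.null(d)) sprintf("scalar %.6g", x$value[1])
      else paste0("[", paste(d, collapse = "x"), "]"),
      if (isTRUE(x$is_param)) paste0("param '", x$name, "'") else "",
      ">\n")
  invisible(x)
}

#' Backpropagate gradients from a scalar loss
#'
#' Accumulates gradients into every upstream tensor with `requires_grad`,
#' including all parameter leaves.
#'
#' @param loss A scalar `seanet_tensor`.
#' @param grad Seed gradient (default 1).
#' @return The loss tensor, invisibly.
#' @export
backward <- function(loss, grad = 1) {
  seen <- new.env(parent = emptyenv())
  nodes <- vector("list", 64L)
  nn <- 0L
  stack <- list(loss)
  while (length(stack)) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$id)
    if (exists(key, envir = seen, inherits = FALSE)) next
    assign(key, TRUE, envir = seen)
    nn <- nn + 1L
    if (nn > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[nn]] <- n
    for (p in n$parents) {
      if (isTRUE(p$requires_grad)) stack[[length(stack) + 1L]] <- p
    }
  }
  nodes <- nodes[seq_len(nn)]
  ids <- vapply(nodes, function(n) n$id, integer(1))
  nodes <- nodes[order(ids, decreasing = TRUE)]

  loss$grad <- grad
  for (n in nodes) {
    if (is.null(n$backward_fn) || is.null(n$grad)) next
    gs <- n$backward_fn(n$grad)
    for (i in seq_along(n$parents)) {
      p <- n$parents[[i]]
      if (!isTRUE(p$requires_grad) || is.null(gs[[i]])) next
      p$grad <- if (is.null(p$grad)) gs[[i]] else p$grad + gs[[i]]
    }
  }
  invisible(loss)
}

#' Reset accumulated gradients
#' @param params Named list of parameter tensors.
#' @return Invisibly, `params`.
#' @export
zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}
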