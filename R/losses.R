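#' Per-sample loss functions
#'
#' DP-SGD needs one scalar loss per sample before any reduction over the
#' batch — clipping acts on each sample's own gradient. A loss object
#' therefore exposes `per_sample(pred, y)`, returning a length-B vector,
#' and `grad(pred, y)`, returning d(loss_i)/d(pred_i) with the shape of
#' `pred`. The engine rejects losses that return a pre-reduced scalar.
#'
#' `loss_bce_logits` is binary cross-entropy on logits with optional
#' per-class weights (for imbalanced data, e.g. `class_weights()` output);
#' `loss_bce_pixel` averages the same criterion over the pixels of a
#' predicted logit map against a binary mask; `loss_mse` is half squared
#' error.
#'
#' @param weights length-2 numeric, loss weight for class 0 and class 1.
#' @return a loss object (list with `per_sample` and `grad`).
#' @name losses
NULL

#' @rdname losses
#' @export
loss_bce_logits <- function(weights = c(1, 1)) {
  stopifnot(length(weights) == 2, all(weights > 0))
  structure(list(
    per_sample = function(pred, y) {
      p <- as.numeric(pred); y <- as.numeric(y)
      w <- weights[y + 1]
      # stable: log(1 + e^p) - y p = max(p,0) + log1p(e^{-|p|}) - y p
      w * (pmax(p, 0) + log1p(exp(-abs(p))) - y * p)
    },
    grad = function(pred, y) {
      p <- as.numeric(pred); y <- as.numeric(y)
      g <- weights[y + 1] * (1 / (1 + exp(-p)) - y)
      dim(g) <- dim(pred)
      g
    }), class = "dp_loss")
}

#' @rdname losses
#' @export
loss_bce_pixel <- function() {
  structure(list(
    per_sample = function(pred, y) {
      stopifnot(identical(dim(pred), dim(y)))
      B <- dim(pred)[1]
      npix <- prod(dim(pred)[-1])
      p <- matrix(pred, B); yy <- matrix(y, B)
      rowSums(pmax(p, 0) + log1p(exp(-abs(p))) - yy * p) / npix
    },
    grad = function(pred, y) {
      npix <- prod(dim(pred)[-1])
      g <- (1 / (1 + exp(-pred)) - y) / npix
      dim(g) <- dim(pred)
      g
    }), class = "dp_loss")
}

#' @rdname losses
#' @export
loss_mse <- function() {
  structure(list(
    per_sample = function(pred, y) {
      p <- if (is.matrix(pred)) pred else matrix(pred, ncol = 1)
      yy <- matrix(as.numeric(y), nrow(p))
      0.5 * rowSums((p - yy)^2)
    },
    grad = function(pred, y) {
      g <- pred - array(as.numeric(y), dim(pred))
      dim(g) <- dim(pred)
      g
    }), class = "dp_loss")
}
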