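#' First-order optimisers
#'
#' Plain SGD (with optional momentum) and Adam, operating on the flat
#' parameter vector. DP correctness does not depend on the optimiser: the
#' gradient it consumes has already been clipped and noised, so any
#' first-order update rule preserves the guarantee.
#'
#' An optimiser object has a `step(model, grad)` function applying one
#' update in place (through the shared parameter store), and fields `lr`
#' (mutable, for schedulers) and `name`.
#'
#' @param lr learning rate.
#' @param momentum SGD momentum coefficient in `[0, 1)`.
#' @param beta1,beta2,eps Adam moment decay rates and stabiliser.
#' @return an optimiser object of class `dp_optimiser`.
#' @name optimisers
NULL

#' @rdname optimisers
#' @export
opt_sgd <- function(lr = 0.01, momentum = 0) {
  e <- new.env()
  e$lr <- lr; e$v <- NULL
  e$name <- "sgd"
  e$step <- function(model, grad) {
    if (momentum > 0) {
      if (is.null(e$v)) e$v <- numeric(length(grad))
      e$v <- momentum * e$v + grad
      grad <- e$v
    }
    params_set_flat(model, params_get_flat(model) - e$lr * grad)
    invisible(NULL)
  }
  class(e) <- "dp_optimiser"
  e
}

#' @rdname optimisers
#' @export
opt_adam <- function(lr = 0.001, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  e <- new.env()
  e$lr <- lr; e$m <- NULL; e$v <- NULL; e$t <- 0L
  e$name <- "adam"
  e$step <- function(model, grad) {
    if (is.null(e$m)) { e$m <- numeric(length(grad)); e$v <- numeric(length(grad)) }
    e$t <- e$t + 1L
    e$m <- beta1 * e$m + (1 - beta1) * grad
    e$v <- beta2 * e$v + (1 - beta2) * grad^2
    mhat <- e$m / (1 - beta1^e$t)
    vhat <- e$v / (1 - beta2^e$t)
    params_set_flat(model,
                    params_get_flat(model) - e$lr * mhat / (sqrt(vhat) + eps))
    invisible(NULL)
  }
  class(e) <- "dp_optimiser"
  e
}

make_optimiser <- function(name = c("sgd", "adam"), lr) {
  name <- match.arg(name)
  if (name == "sgd") opt_sgd(lr) else opt_adam(lr)
}
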