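#' Wrap a model for per-sample gradient computation
#'
#' Creates the minibatch execution wrapper: B replicas of the model that
#' are views over the one shared parameter store (replication allocates no
#' parameter memory — a replica is a reference to the weights, not a copy).
#' A write through the base store is immediately observable through every
#' replica. `wrap_model(model, 1)` behaves identically to the plain model.
#'
#' Wrapping is gated on DP-compatibility: a model still carrying
#' cross-sample state (batch-norm running statistics) is rejected with the
#' surgery report naming the offending layers; run [fix_model()] first.
#'
#' @param model a [dp_model()], surgery-compliant.
#' @param B minibatch size, >= 1.
#' @return an object of class `wrapped_model` with elements `model`,
#'   `replicas` (B views sharing `model$params`) and `B`.
#' @export
wrap_model <- function(model, B) {
  stopifnot(inherits(model, "dp_model"), B >= 1)
  validate_model(model)
  replicas <- lapply(seq_len(B), function(i) {
    structure(list(layers = model$layers, params = model$params,
                   buffers = model$buffers, replica_id = i),
              class = c("dp_model_view", "dp_model"))
  })
  structure(list(model = model, replicas = replicas, B = as.integer(B)),
            class = "wrapped_model")
}

#' @export
print.wrapped_model <- function(x, ...) {
  cat(sprintf("wrapped model: %d weight-sharing replicas over %d parameters\n",
              x$B, n_params(x$model)))
  invisible(x)
}

#' Parallel per-sample forward pass
#'
#' Applies each replica to its sample. Because every compliant layer is
#' per-sample pure, the B replica passes are executed as one batched
#' dispatch; the result is contractually identical to running the plain
#' model on each sample alone, independent of scheduling order.
#'
#' @param wrapped a [wrap_model()] result.
#' @param X batch with first dimension `B`.
#' @param train training mode flag.
#' @return list of class `dp_forward` with `out` (per-sample outputs,
#'   sample-first) and the backward cache.
#' @export
parallel_forward <- function(wrapped, X, train = TRUE) {
  stopifnot(inherits(wrapped, "wrapped_model"))
  bdim <- if (is.matrix(X)) nrow(X) else dim(X)[1]
  if (bdim != wrapped$B)
    stop(sprintf("shape error: batch has %d samples but wrapper expects %d",
                 bdim, wrapped$B), call. = FALSE)
  r <- nn_forward(wrapped$model, X, train = train)
  structure(list(out = r$out, caches = r$caches), class = "dp_forward")
}

#' Per-sample gradients
#'
#' Computes d(loss_i)/d(parameters) for every sample i in the batch: the
#' forward pass runs through the weight-sharing replicas and the backward
#' pass keeps the per-sample rows separate instead of summing them. The
#' loss must be per-sample (a length-B vector before any reduction); a
#' pre-reduced scalar loss cannot be attributed to samples and is refused.
#'
#' @param wrapped a [wrap_model()] result.
#' @param X input batch (first dimension B).
#' @param y per-sample targets.
#' @param loss a loss object from [loss_bce_logits()] and friends.
#' @param forward optionally, an already-computed [parallel_forward()]
#'   result for `X` (avoids recomputing).
#' @return object of class `per_sample_grads`: list with `values`
#'   (`B x P` matrix), `per_sample_norms` (length-B L2 norms), `losses`
#'   (per-sample losses) and `out` (the forward output).
#' @export
per_sample_grads <- function(wrapped, X, y, loss, forward = NULL) {
  stopifnot(inherits(wrapped, "wrapped_model"), inherits(loss, "dp_loss"))
  if (is.null(forward)) forward <- parallel_forward(wrapped, X)
  losses <- loss$per_sample(forward$out, y)
  if (length(losses) != wrapped$B)
    stop(paste("misuse: loss must return one scalar per sample",
               "(got length", length(losses), "for batch", wrapped$B, ");",
               "reduction must not be applied before clipping"), call. = FALSE)
  dOut <- loss$grad(forward$out, y)
  values <- nn_backward(wrapped$model, forward$caches, dOut, per_sample = TRUE)
  structure(list(values = values,
                 per_sample_norms = sqrt(rowSums(values^2)),
                 losses = losses, out = forward$out),
            class = "per_sample_grads")
}

#' Clip per-sample gradients to an L2 norm bound
#'
#' Each sample's full flattened gradient is rescaled by
#' `min(1, C / max(norm_i, 1e-12))`: rows already within the bound pass
#' unchanged, longer rows are shrunk onto the sphere of radius C with their
#' direction preserved, and all-zero rows pass through without a division
#' failure. Clipping is idempotent. The clip is global over the whole
#' parameter vector (one norm per sample, not per layer).
#'
#' @param grads a [per_sample_grads()] object.
#' @param C clipping norm, > 0.
#' @return list with `grads` (clipped, same class) and `report` (class
#'   `clip_report`: `pre_norms`, `clip_factors` in (0, 1], `clip_norm`).
#' @export
clip_grads <- function(grads, C) {
  stopifnot(inherits(grads, "per_sample_grads"), C > 0)
  pre <- grads$per_sample_norms
  factors <- pmin(1, C / pmax(pre, 1e-12))
  clipped <- grads
  clipped$values <- grads$values * factors
  clipped$per_sample_norms <- pre * factors
  report <- structure(list(pre_norms = pre, clip_factors = factors,
                           clip_norm = C), class = "clip_report")
  list(grads = clipped, report = report)
}

#' Aggregate clipped gradients and add calibrated Gaussian noise
#'
#' Sums the clipped per-sample rows, adds isotropic Gaussian noise with
#' per-coordinate standard deviation `sigma * C` (the DP-SGD calibration:
#' noise is matched to the sum's per-sample sensitivity C), then divides by
#' B for mean reduction. With mean reduction the effective per-coordinate
#' noise on the update is therefore `sigma * C / B`. With `sigma = 0` the
#' result is the exact clipped mean (or sum).
#'
#' @param clipped clipped [per_sample_grads()] (from [clip_grads()]).
#' @param C clipping norm used (scales the noise).
#' @param sigma noise multiplier, >= 0.
#' @param reduction `"mean"` (default) or `"sum"`. The mean divides by the
#'   nominal batch size B (the expected size under Poisson sampling).
#' @param noise_source a function `(length, std) -> vector`, e.g.
#'   [secure_noise_source()] (default) or [insecure_noise_source()] in
#'   tests.
#' @return the aggregated, noised flat gradient (length P).
#' @export
aggregate_and_noise <- function(clipped, C, sigma,
                                reduction = c("mean", "sum"),
                                noise_source = secure_noise_source()) {
  stopifnot(inherits(clipped, "per_sample_grads"), sigma >= 0, C > 0)
  reduction <- match.arg(reduction)
  B <- nrow(clipped$values)
  P <- ncol(clipped$values)
  g <- colSums(clipped$values)
  if (sigma > 0) {
    noise <- noise_source(P, sigma * C)
    if (length(noise) != P)
      stop("shape error: noise source returned wrong length", call. = FALSE)
    g <- g + noise
  }
  if (reduction == "mean") g <- g / B
  g
}

#' One full DP-SGD step
#'
#' Convenience composition of the algorithm: per-sample forward/backward
#' through the replicas, per-sample clipping to C, aggregation with
#' calibrated noise, and one optimiser update through the shared store.
#'
#' @inheritParams per_sample_grads
#' @inheritParams aggregate_and_noise
#' @param optimiser a [opt_sgd()] / [opt_adam()] object.
#' @return invisibly, list with `mean_loss`, `grad` (the noised update
#'   direction) and the `clip_report`.
#' @export
dp_step <- function(wrapped, X, y, loss, C, sigma, optimiser,
                    reduction = "mean",
                    noise_source = secure_noise_source()) {
  ps <- per_sample_grads(wrapped, X, y, loss)
  cl <- clip_grads(ps, C)
  g <- aggregate_and_noise(cl$grads, C, sigma, reduction, noise_source)
  optimiser$step(wrapped$model, g)
  invisible(list(mean_loss = mean(ps$losses), grad = g, clip_report = cl$report))
}

#' Serial per-sample gradient oracle
#'
#' The definitional reference: loops over the batch one sample at a time,
#' running an ordinary single-sample forward and backward pass, and stacks
#' the resulting gradients. Used in tests as the equivalence oracle for the
#' parallel engine; it shares no batching code path with it.
#'
#' @param model a [dp_model()] (compliance is the caller's concern here).
#' @param X input batch.
#' @param y per-sample targets.
#' @param loss a loss object.
#' @return object of class `per_sample_grads` (as [per_sample_grads()]).
#' @export
serial_oracle <- function(model, X, y, loss) {
  B <- if (is.matrix(X)) nrow(X) else dim(X)[1]
  P <- n_params(model)
  values <- matrix(0, B, P)
  losses <- numeric(B)
  for (b in seq_len(B)) {
    Xb <- batch_slice(X, b)
    yb <- target_slice(y, b)
    fw <- nn_forward(model, Xb, train = TRUE)
    losses[b] <- loss$per_sample(fw$out, yb)
    dOut <- loss$grad(fw$out, yb)
    values[b, ] <- nn_backward(model, fw$caches, dOut, per_sample = FALSE)
  }
  structure(list(values = values, per_sample_norms = sqrt(rowSums(values^2)),
                 losses = losses, out = NULL),
            class = "per_sample_grads")
}

batch_slice <- function(X, idx) {
  if (is.matrix(X)) return(X[idx, , drop = FALSE])
  d <- length(dim(X))
  if (d == 4) return(X[idx, , , , drop = FALSE])
  stop("unsupported input rank", call. = FALSE)
}

target_slice <- function(y, idx) {
  if (is.null(dim(y))) return(y[idx])
  if (is.matrix(y)) return(y[idx, , drop = FALSE])
  if (length(dim(y)) == 4) return(y[idx, , , , drop = FALSE])
  stop("unsupported target rank", call. = FALSE)
}
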