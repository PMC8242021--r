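#' Run configuration
#'
#' Collects everything a training run needs. Private runs are validated
#' eagerly: they require a positive noise multiplier and clipping norm, a
#' delta, and the secure RNG; an explicit global seed together with
#' `secure_rng = TRUE` is refused outright (a seeded run cannot draw its
#' DP noise securely). Tests opt into the clearly-labelled insecure mode
#' by setting `secure_rng = FALSE` with `insecure_ok = TRUE`.
#'
#' @param task `"classification"` or `"segmentation"`.
#' @param model a surgery-compliant [dp_model()].
#' @param schedule a [training_schedule()].
#' @param optimiser `"sgd"` or `"adam"` (paper defaults: SGD private
#'   classification, Adam otherwise).
#' @param lr initial learning rate.
#' @param eps_budget privacy budget ceiling (may be `Inf`).
#' @param mode accounting mode, see [audit()].
#' @param sampler `"uniform"` or `"poisson"` minibatching.
#' @param secure_rng draw DP noise from the OS CSPRNG (default TRUE).
#' @param insecure_ok explicit opt-in to the insecure seeded noise path.
#' @param seed seed for data order (and, in insecure mode, noise).
#' @param class_weighting weight the classification loss by one minus
#'   each class's dataset proportion.
#' @param lr_patience epochs of stagnating validation loss before the
#'   learning rate is halved (plateau scheduling).
#' @param lr_threshold relative improvement below which an epoch counts
#'   as stagnation.
#' @return list of class `run_config`.
#' @export
run_config <- function(task = c("classification", "segmentation"),
                       model, schedule, optimiser = c("sgd", "adam"),
                       lr = 0.01, eps_budget = Inf,
                       mode = c("gdp-poisson", "gdp-uniform", "rdp"),
                       sampler = c("uniform", "poisson"),
                       secure_rng = TRUE, insecure_ok = FALSE, seed = NULL,
                       class_weighting = TRUE,
                       lr_patience = 2, lr_threshold = 1e-3) {
  task <- match.arg(task); mode <- match.arg(mode)
  optimiser <- match.arg(optimiser); sampler <- match.arg(sampler)
  stopifnot(inherits(model, "dp_model"), inherits(schedule, "dp_schedule"),
            eps_budget > 0)
  if (secure_rng && !is.null(seed))
    stop(paste("refusing to run with a global seed while secure_rng is true;",
               "drop the seed or explicitly opt into the insecure mode"),
         call. = FALSE)
  if (!secure_rng && !insecure_ok)
    stop(paste("insecure RNG requested for private training; this voids the",
               "privacy guarantee. Set insecure_ok = TRUE (tests only) to",
               "proceed."), call. = FALSE)
  structure(list(task = task, model = model, schedule = schedule,
                 optimiser = optimiser, lr = lr, eps_budget = eps_budget,
                 mode = mode, sampler = sampler, secure_rng = secure_rng,
                 insecure_ok = insecure_ok, seed = seed,
                 class_weighting = class_weighting,
                 lr_patience = lr_patience, lr_threshold = lr_threshold),
            class = "run_config")
}

#' Invert the accountant: last step within a budget
#'
#' Epsilon is non-decreasing in the step count, so the largest step count
#' whose budget does not exceed `eps_budget` is found by bisection on the
#' accountant itself. This is the analytic form of the training watchdog:
#' a private run performs exactly this many optimiser steps.
#'
#' @param schedule a [training_schedule()].
#' @param eps_budget budget ceiling.
#' @param mode accounting mode.
#' @return integer step count in `[0, schedule$total_steps]`.
#' @export
steps_within_budget <- function(schedule, eps_budget,
                                mode = "gdp-poisson") {
  if (!is.finite(eps_budget)) return(schedule$total_steps)
  eps_at <- function(s) audit(schedule, mode, steps = s)$epsilon
  lo <- 0L; hi <- schedule$total_steps
  if (eps_at(hi) <= eps_budget) return(hi)
  if (eps_at(1L) > eps_budget) return(0L)
  while (hi - lo > 1L) {           # invariant: eps(lo) <= budget < eps(hi)
    mid <- (lo + hi) %/% 2L
    if (eps_at(mid) <= eps_budget) lo <- mid else hi <- mid
  }
  lo
}

#' Differentially private training
#'
#' The DP-SGD loop: per epoch, minibatches are drawn by the configured
#' sampler; each step computes per-sample gradients through the
#' weight-sharing replicas, clips them to C, aggregates with calibrated
#' Gaussian noise and applies one optimiser update. Accounting is
#' prospective — before each step the accountant evaluates the budget the
#' step *would* bring the run to, and the loop halts (halt reason
#' `budget_exhausted`) if it would exceed `eps_budget`, so the budget is
#' never overrun. Validation loss is evaluated each epoch and drives
#' plateau learning-rate halving.
#'
#' @param config a [run_config()].
#' @param data list with `x` (training batch array), `y` or `masks`, and
#'   optionally `val` (same structure) for validation-driven scheduling
#'   and metrics — as produced by [load_images()].
#' @return object of class `run_trace`: per-step log (`step`, `loss`,
#'   `eps`, `lr`), `final_privacy` ([audit()] result at the halt step),
#'   `halt_reason` (`completed` / `budget_exhausted`), `occurrences`, and
#'   validation `metric` (ROC-AUC or Dice) when validation data is given.
#' @export
train_private <- function(config, data) {
  stopifnot(inherits(config, "run_config"))
  validate_model(config$model)
  sch <- config$schedule
  noise_source <- if (config$secure_rng) secure_noise_source()
                  else insecure_noise_source(config$seed %||% 0L)
  n <- dim(data$x)[1]
  if (n != sch$n)
    stop(sprintf("invalid config: schedule n = %d but data has %d records",
                 sch$n, n), call. = FALSE)
  loss <- make_loss(config, data)
  run_loop(config, data, loss, private = TRUE, noise_source = noise_source)
}

#' Non-private reference training
#'
#' The same loop without clipping or noise: ordinary minibatch-mean
#' gradients, identical logging and plateau scheduling, privacy reported
#' as `epsilon = Inf`.
#'
#' @inheritParams train_private
#' @return a `run_trace` with `final_privacy$epsilon = Inf`.
#' @export
train_nonprivate <- function(config, data) {
  stopifnot(inherits(config, "run_config"))
  loss <- make_loss(config, data)
  run_loop(config, data, loss, private = FALSE, noise_source = NULL)
}

make_loss <- function(config, data) {
  if (config$task == "classification") {
    w <- if (isTRUE(config$class_weighting)) {
      cnt <- table(data$y)
      cw <- class_weights(stats::setNames(as.numeric(cnt), names(cnt)))
      as.numeric(cw[c("0", "1")])
    } else c(1, 1)
    loss_bce_logits(w)
  } else {
    loss_bce_pixel()
  }
}

targets_of <- function(data, task) if (task == "classification") data$y else data$masks

run_loop <- function(config, data, loss, private, noise_source) {
  sch <- config$schedule
  B <- sch$batch_size
  n <- dim(data$x)[1]
  epochs <- sch$epochs %||% ceiling(sch$total_steps / max(1, ceiling(n / B)))
  opt <- make_optimiser(config$optimiser, config$lr)
  y_all <- targets_of(data, config$task)
  max_steps <- if (private) steps_within_budget(sch, config$eps_budget, config$mode)
               else sch$total_steps
  steps_per_epoch <- ceiling(n / B)
  trace <- list(); step <- 0L; halt <- "completed"
  occurrence_log <- list()
  best_val <- Inf; stagnant <- 0L
  data_seed <- (config$seed %||% 20260919L)
  for (ep in seq_len(epochs)) {
    batches <- if (config$sampler == "uniform") {
      uniform_batches(n, B, seed = data_seed + ep)
    } else {
      poisson_batches(n, sch$q, steps_per_epoch, seed = data_seed + ep)
    }
    for (bi in seq_along(batches)) {
      if (step + 1L > max_steps) { if (private) halt <- "budget_exhausted"; break }
      idx <- batches[[bi]]
      step <- step + 1L
      occurrence_log[[step]] <- idx
      if (length(idx) == 0) {          # empty Poisson batch: noise-only step
        g <- gaussian_noise_update(config, n_params(config$model), noise_source)
        opt$step(config$model, g)
        loss_val <- NA_real_
      } else if (private) {
        # pad short uniform tail batches by wrapping to the nominal size is
        # NOT done: the wrapper is rebuilt at the realised size, noise stays
        # calibrated to sigma * C and the mean divides by the nominal B.
        wrapped <- wrap_model(config$model, length(idx))
        ps <- per_sample_grads(wrapped, batch_slice(data$x, idx),
                               target_slice(y_all, idx), loss)
        cl <- clip_grads(ps, sch$clip_norm)
        g <- aggregate_and_noise(cl$grads, sch$clip_norm, sch$sigma,
                                 reduction = "sum",
                                 noise_source = noise_source) / B
        opt$step(config$model, g)
        loss_val <- mean(ps$losses)
      } else {
        fw <- nn_forward(config$model, batch_slice(data$x, idx))
        yb <- target_slice(y_all, idx)
        per <- loss$per_sample(fw$out, yb)
        dOut <- loss$grad(fw$out, yb) / length(idx)
        g <- nn_backward(config$model, fw$caches, dOut, per_sample = FALSE)
        opt$step(config$model, g)
        loss_val <- mean(per)
      }
      eps_now <- if (private) audit(sch, config$mode, steps = step)$epsilon else Inf
      trace[[step]] <- data.frame(step = step, loss = loss_val,
                                  eps = eps_now, lr = opt$lr)
    }
    if (halt != "completed") break
    # plateau scheduler on validation loss
    if (!is.null(data$val)) {
      vl <- eval_loss(config$model, data$val, loss, config$task)
      if (vl < best_val * (1 - config$lr_threshold)) {
        best_val <- vl; stagnant <- 0L
      } else {
        stagnant <- stagnant + 1L
        if (stagnant >= config$lr_patience) {
          opt$lr <- opt$lr / 2
          stagnant <- 0L
        }
      }
    }
  }
  steps_log <- if (length(trace)) do.call(rbind, trace)
               else data.frame(step = integer(0), loss = numeric(0),
                               eps = numeric(0), lr = numeric(0))
  final_privacy <- if (private) audit(sch, config$mode, steps = step)
                   else structure(list(mu = NA_real_, epsilon = Inf,
                                       delta = sch$delta,
                                       steps_accounted = step,
                                       mode = "nonprivate", best_order = NULL),
                                  class = "privacy_spent")
  metric <- if (!is.null(data$val)) eval_metric(config$model, data$val, config$task)
  structure(list(steps = steps_log, final_privacy = final_privacy,
                 halt_reason = halt, n_steps = step,
                 occurrences = count_occurrences(occurrence_log, n),
                 metric = metric),
            class = "run_trace")
}

gaussian_noise_update <- function(config, P, noise_source) {
  sch <- config$schedule
  noise_source(P, sch$sigma * sch$clip_norm) / sch$batch_size
}

eval_loss <- function(model, val, loss, task) {
  fw <- nn_forward(model, val$x, train = FALSE)
  mean(loss$per_sample(fw$out, targets_of(val, task)))
}

eval_metric <- function(model, val, task) {
  fw <- nn_forward(model, val$x, train = FALSE)
  if (task == "classification") {
    roc_auc(as.numeric(fw$out), val$y)
  } else {
    preds <- 1 / (1 + exp(-fw$out))
    mean(vapply(seq_len(dim(preds)[1]), function(i)
      dice(preds[i, , , 1], val$masks[i, , , 1]), numeric(1)))
  }
}

#' @export
print.run_trace <- function(x, ...) {
  cat(sprintf("run trace: %d steps, halt = %s, epsilon = %.4g\n",
              x$n_steps, x$halt_reason, x$final_privacy$epsilon))
  if (!is.null(x$metric)) cat(sprintf("  validation metric = %.4f\n", x$metric))
  invisible(x)
}

#' Timing and memory benchmark harness
#'
#' Times `steps` DP-SGD steps at minibatch size B on random data, repeated
#' `reps` times, reporting each repetition and the median wall time, plus
#' peak resident memory (from the OS accounting of this process). Results
#' are informational only — they depend on the host hardware.
#'
#' @param model a compliant [dp_model()].
#' @param input_dim input shape of one sample (e.g. `c(32, 32, 1)`).
#' @param B minibatch size (default 32).
#' @param steps steps per repetition (default 25).
#' @param reps repetitions (default 5).
#' @param sigma,C noise multiplier and clipping norm used in the steps.
#' @return list with `times` (length `reps`), `median_time`,
#'   `peak_memory_mb`, `B`, `steps`.
#' @export
benchmark_dp <- function(model, input_dim, B = 32, steps = 25, reps = 5,
                         sigma = 1.0, C = 1.0) {
  validate_model(model)
  noise <- insecure_noise_source(1L)
  loss <- loss_mse()
  times <- numeric(reps)
  for (r in seq_len(reps)) {
    X <- array(stats::rnorm(B * prod(input_dim)), c(B, input_dim))
    fw0 <- nn_forward(model, batch_slice(X, 1))   # probe output shape
    y <- matrix(0, B, length(fw0$out))
    wrapped <- wrap_model(model, B)
    opt <- opt_sgd(1e-3)
    times[r] <- system.time(
      for (s in seq_len(steps))
        dp_step(wrapped, X, y, loss, C, sigma, opt, noise_source = noise)
    )[["elapsed"]]
  }
  list(times = times, median_time = stats::median(times),
       peak_memory_mb = peak_memory_mb(), B = B, steps = steps)
}

peak_memory_mb <- function() {
  status <- tryCatch(readLines("/proc/self/status"), error = function(e) character(0))
  line <- grep("^VmHWM:", status, value = TRUE)
  if (length(line) == 1) {
    as.numeric(gsub("[^0-9]", "", line)) / 1024
  } else {
    sum(gc()[, "max used"] * c(56, 8)) / 2^20  # cells + Vcells fallback
  }
}

#' Small reference architectures
#'
#' `tiny_cnn()` is a compact convolutional classifier (conv -> relu ->
#' avgpool -> flatten -> dense logit) for the synthetic classification
#' fixture; `tiny_segnet()` is a two-convolution per-pixel logit model for
#' the synthetic segmentation fixture. `with_batch_norm` inserts a
#' batch-norm layer with running statistics enabled — i.e. a model that
#' needs surgery before private training.
#'
#' @param input_size image side length.
#' @param channels convolution width.
#' @param with_batch_norm include an (unrepaired) batch-norm layer.
#' @return a [dp_model()].
#' @export
tiny_cnn <- function(input_size, channels = 4, with_batch_norm = FALSE) {
  pooled <- (input_size - 2) %/% 2
  layers <- list(layer_conv2d(1, channels, 3))
  if (with_batch_norm) layers <- c(layers, list(layer_batch_norm2d(channels)))
  layers <- c(layers, list(layer_relu(), layer_avgpool2d(2), layer_flatten(),
                           layer_dense(pooled^2 * channels, 1)))
  do.call(dp_model, layers)
}

#' @rdname tiny_cnn
#' @export
tiny_segnet <- function(channels = 8, with_batch_norm = FALSE) {
  layers <- list(layer_conv2d(1, channels, 3, padding = "same"))
  if (with_batch_norm) layers <- c(layers, list(layer_batch_norm2d(channels)))
  layers <- c(layers, list(layer_relu(),
                           layer_conv2d(channels, 1, 3, padding = "same")))
  do.call(dp_model, layers)
}

#' Save a checkpoint
#'
#' Serialises the model (layers + parameter values) together with its
#' surgery report and the privacy spent so far.
#'
#' @param model a [dp_model()].
#' @param path output file (RDS).
#' @param privacy optional [audit()] result to embed.
#' @export
save_checkpoint <- function(model, path, privacy = NULL) {
  saveRDS(list(layers = model$layers,
               params = as.list(model$params),
               buffers = as.list(model$buffers),
               surgery = scan_model(model), privacy = privacy), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  params <- list2env(ck$params, parent = emptyenv())
  buffers <- list2env(ck$buffers, parent = emptyenv())
  model <- structure(list(layers = ck$layers, params = params,
                          buffers = buffers), class = "dp_model")
  list(model = model, surgery = ck$surgery, privacy = ck$privacy)
}

#' Run a training job from a YAML config
#'
#' Thin config-file front end over [train_private()] /
#' [train_nonprivate()] used by the command-line script. See the package
#' README for the schema (task, data, model, schedule, training keys).
#'
#' @param path YAML config file.
#' @return the `run_trace`.
#' @export
run_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  manifest <- read_manifest(cfg$data$manifest)
  train <- load_images(manifest, split = "train")
  val <- tryCatch(load_images(manifest, split = "val"), error = function(e) NULL)
  train$val <- val
  input_size <- dim(train$x)[2]
  model <- switch(cfg$model$kind %||% "tiny_cnn",
    tiny_cnn = tiny_cnn(input_size, cfg$model$channels %||% 4,
                        isTRUE(cfg$model$batch_norm)),
    tiny_segnet = tiny_segnet(cfg$model$channels %||% 8,
                              isTRUE(cfg$model$batch_norm)),
    stop("unknown model kind", call. = FALSE))
  if (!scan_model(model)$compliant) model <- fix_model(model)$model
  sch <- training_schedule(
    n = dim(train$x)[1], batch_size = cfg$schedule$batch_size %||% 32,
    epochs = cfg$schedule$epochs %||% 5,
    sigma = cfg$schedule$sigma %||% 1.0,
    clip_norm = cfg$schedule$clip_norm %||% 1.0,
    delta = cfg$schedule$delta %||% 1e-5)
  config <- run_config(
    task = cfg$task %||% "classification", model = model, schedule = sch,
    optimiser = cfg$training$optimiser %||% "sgd",
    lr = cfg$training$lr %||% 0.01,
    eps_budget = cfg$training$eps_budget %||% Inf,
    mode = cfg$training$mode %||% "gdp-poisson",
    sampler = cfg$training$sampler %||% "uniform",
    secure_rng = !isFALSE(cfg$privacy$secure_rng),
    insecure_ok = isTRUE(cfg$privacy$insecure_ok),
    seed = cfg$training$seed)
  if (isTRUE(cfg$training$private %||% TRUE)) train_private(config, train)
  else train_nonprivate(config, train)
}

#' Write a run trace as JSON lines
#'
#' One JSON object per training step (`step`, `loss`, `eps`, `lr`),
#' followed by no summary line; the final summary is available from the
#' trace object itself.
#'
#' @param trace a `run_trace`.
#' @param path output file.
#' @export
write_trace_jsonl <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(trace$steps))) {
    writeLines(jsonlite::toJSON(as.list(trace$steps[i, ]),
                                auto_unbox = TRUE, digits = NA, na = "null"),
               con)
  }
  invisible(path)
}
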