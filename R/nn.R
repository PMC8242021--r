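#' Minimal neural-network layers with exact batched backpropagation
#'
#' The package ships a small, self-contained layer library so that the
#' per-sample gradient engine has a concrete substrate. Every layer is
#' per-sample pure (its output for sample i depends only on sample i) with
#' the sole exception of batch normalisation with running statistics, which
#' is exactly the case the model-surgery module detects and repairs.
#'
#' Tensor conventions: image tensors are `(B, H, W, C)` arrays (sample
#' first, channel last); dense inputs are `(B, D)` matrices. Convolutions
#' are stride-1 with `"valid"` or `"same"` zero padding.
#'
#' @param in_features,out_features dense layer fan-in / fan-out.
#' @param in_channels,out_channels,kernel,padding convolution geometry.
#' @param factor non-overlapping average-pooling window size.
#' @param channels normalised channel count.
#' @param groups number of normalisation groups (must divide `channels`).
#' @param track_running_stats keep (non-private!) running mean/variance
#'   buffers across batches. Models carrying such layers are rejected by
#'   [wrap_model()] until repaired by [fix_model()].
#' @return a layer description for [dp_model()].
#' @name layers
NULL

#' @rdname layers
#' @export
layer_dense <- function(in_features, out_features) {
  structure(list(type = "dense", inf = as.integer(in_features),
                 outf = as.integer(out_features)), class = "dp_layer")
}

#' @rdname layers
#' @export
layer_relu <- function() structure(list(type = "relu"), class = "dp_layer")

#' @rdname layers
#' @export
layer_sigmoid <- function() structure(list(type = "sigmoid"), class = "dp_layer")

#' @rdname layers
#' @export
layer_flatten <- function() structure(list(type = "flatten"), class = "dp_layer")

#' @rdname layers
#' @export
layer_conv2d <- function(in_channels, out_channels, kernel = 3,
                         padding = c("valid", "same")) {
  padding <- match.arg(padding)
  if (padding == "same" && kernel %% 2 == 0)
    stop("same padding requires an odd kernel", call. = FALSE)
  structure(list(type = "conv2d", cin = as.integer(in_channels),
                 cout = as.integer(out_channels), k = as.integer(kernel),
                 padding = padding), class = "dp_layer")
}

#' @rdname layers
#' @export
layer_avgpool2d <- function(factor = 2) {
  structure(list(type = "avgpool2d", f = as.integer(factor)), class = "dp_layer")
}

#' @rdname layers
#' @export
layer_batch_norm2d <- function(channels, track_running_stats = TRUE) {
  structure(list(type = "batch_norm2d", channels = as.integer(channels),
                 track_running_stats = isTRUE(track_running_stats),
                 eps = 1e-5, momentum = 0.1), class = "dp_layer")
}

#' @rdname layers
#' @export
layer_group_norm <- function(channels, groups = 1) {
  channels <- as.integer(channels); groups <- as.integer(groups)
  if (channels %% groups != 0)
    stop("groups must divide channels", call. = FALSE)
  structure(list(type = "group_norm", channels = channels, groups = groups,
                 eps = 1e-5), class = "dp_layer")
}

#' Build a model from layers
#'
#' Assembles layers into a sequential model and allocates its parameters
#' once, in a single parameter store (an environment). All views of the
#' model — including the weight-sharing replicas created by [wrap_model()]
#' — alias this one store, so parameter memory never scales with the
#' minibatch size. Weights are He-initialised from R's current RNG state;
#' seed before construction for reproducible weights.
#'
#' @param ... layer descriptions from the `layer_*` constructors.
#' @return an object of class `dp_model`.
#' @examples
#' set.seed(1)
#' m <- dp_model(layer_dense(4, 8), layer_relu(), layer_dense(8, 1))
#' n_params(m)
#' @export
dp_model <- function(...) {
  layers <- list(...)
  stopifnot(length(layers) > 0, all(vapply(layers, inherits, TRUE, "dp_layer")))
  params <- new.env(parent = emptyenv())
  buffers <- new.env(parent = emptyenv())
  for (i in seq_along(layers)) init_layer(layers[[i]], layer_id(i), params, buffers)
  structure(list(layers = layers, params = params, buffers = buffers),
            class = "dp_model")
}

layer_id <- function(i) sprintf("L%02d", i)

init_layer <- function(layer, id, params, buffers) {
  switch(layer$type,
    dense = {
      params[[paste0(id, ".W")]] <-
        matrix(stats::rnorm(layer$inf * layer$outf, sd = sqrt(2 / layer$inf)),
               layer$inf, layer$outf)
      params[[paste0(id, ".b")]] <- numeric(layer$outf)
    },
    conv2d = {
      fan_in <- layer$k^2 * layer$cin
      params[[paste0(id, ".W")]] <-
        array(stats::rnorm(layer$k^2 * layer$cin * layer$cout,
                           sd = sqrt(2 / fan_in)),
              c(layer$k, layer$k, layer$cin, layer$cout))
      params[[paste0(id, ".b")]] <- numeric(layer$cout)
    },
    batch_norm2d = {
      params[[paste0(id, ".gamma")]] <- rep(1, layer$channels)
      params[[paste0(id, ".beta")]] <- numeric(layer$channels)
      if (layer$track_running_stats) {
        buffers[[paste0(id, ".running_mean")]] <- numeric(layer$channels)
        buffers[[paste0(id, ".running_var")]] <- rep(1, layer$channels)
      }
    },
    group_norm = {
      params[[paste0(id, ".gamma")]] <- rep(1, layer$channels)
      params[[paste0(id, ".beta")]] <- numeric(layer$channels)
    },
    relu = , sigmoid = , flatten = , avgpool2d = NULL,
    stop("unknown layer type: ", layer$type, call. = FALSE))
  invisible(NULL)
}

#' @export
print.dp_model <- function(x, ...) {
  cat(sprintf("dp_model with %d layers, %d parameters\n",
              length(x$layers), n_params(x)))
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    extra <- switch(l$type,
      dense = sprintf(" %d -> %d", l$inf, l$outf),
      conv2d = sprintf(" %dx%d, %d -> %d (%s)", l$k, l$k, l$cin, l$cout, l$padding),
      batch_norm2d = sprintf(" C=%d, running_stats=%s", l$channels,
                             l$track_running_stats),
      group_norm = sprintf(" C=%d, G=%d", l$channels, l$groups),
      avgpool2d = sprintf(" /%d", l$f),
      "")
    cat(sprintf("  %s %s%s\n", layer_id(i), l$type, extra))
  }
  invisible(x)
}

# --- parameter flattening -------------------------------------------------
# A fixed layer-order template maps the parameter store onto one flat
# vector; per-sample gradients are rows in this same coordinate system.

param_template <- function(model) {
  names_ <- character(0)
  for (i in seq_along(model$layers)) {
    id <- layer_id(i)
    l <- model$layers[[i]]
    nm <- switch(l$type,
      dense = , conv2d = paste0(id, c(".W", ".b")),
      batch_norm2d = , group_norm = paste0(id, c(".gamma", ".beta")),
      character(0))
    names_ <- c(names_, nm)
  }
  lens <- vapply(names_, function(n) length(model$params[[n]]), integer(1))
  list(names = names_, lens = lens, offsets = cumsum(c(0L, lens[-length(lens)])),
       total = sum(lens))
}

#' Model parameter access
#'
#' `n_params` counts learnable scalars; `params_get_flat` /
#' `params_set_flat` move parameters between the shared store and a flat
#' vector (the coordinate system of per-sample gradients and optimiser
#' updates).
#'
#' @param model a [dp_model()].
#' @param x flat numeric vector of length `n_params(model)`.
#' @export
n_params <- function(model) param_template(model)$total

#' @rdname n_params
#' @export
params_get_flat <- function(model) {
  tpl <- param_template(model)
  unlist(lapply(tpl$names, function(n) as.numeric(model$params[[n]])),
         use.names = FALSE)
}

#' @rdname n_params
#' @export
params_set_flat <- function(model, x) {
  tpl <- param_template(model)
  stopifnot(length(x) == tpl$total)
  for (j in seq_along(tpl$names)) {
    n <- tpl$names[j]
    cur <- model$params[[n]]
    new <- x[(tpl$offsets[j] + 1):(tpl$offsets[j] + tpl$lens[j])]
    if (!is.null(dim(cur))) dim(new) <- dim(cur)
    model$params[[n]] <- new
  }
  invisible(model)
}

# --- forward --------------------------------------------------------------

#' Batched forward pass
#'
#' Runs the model over a batch (first dimension = samples) and keeps the
#' per-layer caches needed for backpropagation. Since every compliant layer
#' is per-sample pure, the batched pass is exactly equivalent to running
#' each sample alone.
#'
#' @param model a [dp_model()].
#' @param X input batch: `(B, D)` matrix or `(B, H, W, C)` array.
#' @param train training mode (affects only unrepaired batch-norm layers).
#' @return list with `out` (batch output) and `caches` (internal).
#' @export
nn_forward <- function(model, X, train = TRUE) {
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    r <- fwd_layer(model$layers[[i]], layer_id(i), X, model$params,
                   model$buffers, train)
    X <- r$out
    caches[[i]] <- r$cache
  }
  list(out = X, caches = caches)
}

fwd_layer <- function(l, id, X, params, buffers, train) {
  switch(l$type,
    dense = {
      stopifnot(is.matrix(X))
      W <- params[[paste0(id, ".W")]]; b <- params[[paste0(id, ".b")]]
      out <- X %*% W
      out <- out + matrix(b, nrow(out), length(b), byrow = TRUE)
      list(out = out, cache = list(X = X))
    },
    relu = list(out = pmax(X, 0), cache = list(mask = X > 0)),
    sigmoid = {
      s <- 1 / (1 + exp(-X))
      list(out = s, cache = list(s = s))
    },
    flatten = {
      d <- dim(X)
      out <- X
      dim(out) <- c(d[1], prod(d[-1]))
      list(out = out, cache = list(dims = d))
    },
    conv2d = conv2d_forward(l, id, X, params),
    avgpool2d = avgpool_forward(l, X),
    batch_norm2d = bn_forward(l, id, X, params, buffers, train),
    group_norm = gn_forward(l, id, X, params),
    stop("unknown layer type: ", l$type, call. = FALSE))
}

pad4 <- function(X, p) {
  d <- dim(X)
  out <- array(0, c(d[1], d[2] + 2 * p, d[3] + 2 * p, d[4]))
  out[, (p + 1):(p + d[2]), (p + 1):(p + d[3]), ] <- X
  out
}

conv2d_forward <- function(l, id, X, params) {
  stopifnot(length(dim(X)) == 4)
  W <- params[[paste0(id, ".W")]]; b <- params[[paste0(id, ".b")]]
  k <- l$k
  p <- if (l$padding == "same") (k - 1L) %/% 2L else 0L
  if (p > 0) X <- pad4(X, p)
  d <- dim(X); B <- d[1]; H <- d[2]; Wd <- d[3]; Cin <- d[4]
  if (Cin != l$cin) stop("conv2d: channel mismatch", call. = FALSE)
  Ho <- H - k + 1L; Wo <- Wd - k + 1L
  if (Ho < 1 || Wo < 1) stop("conv2d: input smaller than kernel", call. = FALSE)
  patches <- array(0, c(B, Ho, Wo, k, k, Cin))
  for (di in 1:k) for (dj in 1:k)
    patches[, , , di, dj, ] <- X[, di:(di + Ho - 1L), dj:(dj + Wo - 1L), ]
  dim(patches) <- c(B * Ho * Wo, k * k * Cin)
  Wm <- W; dim(Wm) <- c(k * k * Cin, l$cout)
  out <- patches %*% Wm
  out <- out + matrix(b, nrow(out), l$cout, byrow = TRUE)
  dim(out) <- c(B, Ho, Wo, l$cout)
  list(out = out,
       cache = list(Pm = patches, padded_dim = d, p = p, Ho = Ho, Wo = Wo))
}

avgpool_forward <- function(l, X) {
  d <- dim(X); B <- d[1]; H <- d[2]; Wd <- d[3]; C <- d[4]; f <- l$f
  Ho <- H %/% f; Wo <- Wd %/% f
  if (Ho < 1 || Wo < 1) stop("avgpool2d: input smaller than window", call. = FALSE)
  Y <- X[, 1:(Ho * f), 1:(Wo * f), , drop = FALSE]
  dim(Y) <- c(B, f, Ho, f, Wo, C)
  Yp <- aperm(Y, c(1, 3, 5, 6, 2, 4))
  dim(Yp) <- c(B * Ho * Wo * C, f * f)
  out <- rowMeans(Yp)
  dim(out) <- c(B, Ho, Wo, C)
  list(out = out, cache = list(in_dim = d, Ho = Ho, Wo = Wo))
}

# Batch normalisation. Two regimes:
#  * repaired (track_running_stats = FALSE): statistics are computed per
#    sample per channel over the spatial extent, in training and evaluation
#    alike — each sample's output depends on that sample only, which is the
#    property DP per-sample gradients require. For a single sample this is
#    single-sample (instance) statistics, the documented convention.
#  * unrepaired (track_running_stats = TRUE): classic cross-sample batch
#    statistics plus running-average buffers. Supported for completeness in
#    non-private training; the per-sample engine refuses it.
bn_forward <- function(l, id, X, params, buffers, train) {
  d <- dim(X); B <- d[1]; H <- d[2]; Wd <- d[3]; C <- d[4]
  if (C != l$channels) stop("batch_norm2d: channel mismatch", call. = FALSE)
  g <- params[[paste0(id, ".gamma")]]; be <- params[[paste0(id, ".beta")]]
  if (!l$track_running_stats) {
    Xp <- aperm(X, c(2, 3, 1, 4))          # (H, W, B, C)
    dim(Xp) <- c(H * Wd, B * C)            # one column per (sample, channel)
    m <- colMeans(Xp)
    v <- colMeans(Xp * Xp) - m^2
    inv_sd <- 1 / sqrt(v + l$eps)
    xhat <- (Xp - rep(m, each = H * Wd)) * rep(inv_sd, each = H * Wd)
    gcol <- rep(rep(g, each = B), each = H * Wd)
    bcol <- rep(rep(be, each = B), each = H * Wd)
    out <- xhat * gcol + bcol
    dim(out) <- c(H, Wd, B, C)
    out <- aperm(out, c(3, 1, 2, 4))
    list(out = out,
         cache = list(kind = "per_sample", xhat = xhat, inv_sd = inv_sd,
                      B = B, H = H, W = Wd, C = C))
  } else {
    Xp <- aperm(X, c(2, 3, 1, 4))
    dim(Xp) <- c(H * Wd * B, C)            # one column per channel
    if (train) {
      m <- colMeans(Xp)
      v <- colMeans(Xp * Xp) - m^2
      rm_ <- paste0(id, ".running_mean"); rv_ <- paste0(id, ".running_var")
      buffers[[rm_]] <- (1 - l$momentum) * buffers[[rm_]] + l$momentum * m
      buffers[[rv_]] <- (1 - l$momentum) * buffers[[rv_]] + l$momentum * v
    } else {
      m <- buffers[[paste0(id, ".running_mean")]]
      v <- buffers[[paste0(id, ".running_var")]]
    }
    inv_sd <- 1 / sqrt(v + l$eps)
    n <- H * Wd * B
    xhat <- (Xp - rep(m, each = n)) * rep(inv_sd, each = n)
    out <- xhat * rep(g, each = n) + rep(be, each = n)
    dim(out) <- c(H, Wd, B, C)
    out <- aperm(out, c(3, 1, 2, 4))
    list(out = out,
         cache = list(kind = "batch", xhat = xhat, inv_sd = inv_sd,
                      train = train, B = B, H = H, W = Wd, C = C))
  }
}

gn_forward <- function(l, id, X, params) {
  d <- dim(X); B <- d[1]; H <- d[2]; Wd <- d[3]; C <- d[4]
  if (C != l$channels) stop("group_norm: channel mismatch", call. = FALSE)
  g <- params[[paste0(id, ".gamma")]]; be <- params[[paste0(id, ".beta")]]
  G <- l$groups; cg <- C %/% G
  Xp <- aperm(X, c(2, 3, 4, 1))            # (H, W, C, B)
  dim(Xp) <- c(H * Wd, C, B)
  xhat <- array(0, dim(Xp))
  inv_sd <- matrix(0, G, B)
  for (gi in 1:G) {
    idx <- ((gi - 1) * cg + 1):(gi * cg)
    sub <- Xp[, idx, , drop = FALSE]
    dim(sub) <- c(H * Wd * cg, B)
    m <- colMeans(sub)
    v <- colMeans(sub * sub) - m^2
    isd <- 1 / sqrt(v + l$eps)
    inv_sd[gi, ] <- isd
    sub <- (sub - rep(m, each = H * Wd * cg)) * rep(isd, each = H * Wd * cg)
    dim(sub) <- c(H * Wd, cg, B)
    xhat[, idx, ] <- sub
  }
  out <- xhat * rep(rep(g, each = H * Wd), times = B) +
    rep(rep(be, each = H * Wd), times = B)
  dim(out) <- c(H, Wd, C, B)
  out <- aperm(out, c(4, 1, 2, 3))
  list(out = out, cache = list(xhat = xhat, inv_sd = inv_sd,
                               B = B, H = H, W = Wd, C = C, G = G, cg = cg))
}

# --- backward -------------------------------------------------------------

#' Batched backward pass
#'
#' Backpropagates `dOut` (the gradient of the per-sample losses with
#' respect to the model output) through the cached forward pass. With
#' `per_sample = TRUE` the result is the `(B, P)` matrix of per-sample
#' parameter gradients — row i is d(loss_i)/d(theta), exact because every
#' compliant layer is per-sample pure. With `per_sample = FALSE` the rows
#' are pre-summed into one length-`P` gradient (ordinary training).
#'
#' @param model a [dp_model()].
#' @param caches the `caches` element returned by [nn_forward()].
#' @param dOut upstream gradient, same shape as the forward output.
#' @param per_sample return one gradient row per sample?
#' @return `(B, P)` matrix (`per_sample = TRUE`) or length-`P` vector.
#' @export
nn_backward <- function(model, caches, dOut, per_sample = TRUE) {
  B <- if (is.matrix(dOut)) nrow(dOut) else dim(dOut)[1]
  grads <- list()
  for (i in rev(seq_along(model$layers))) {
    r <- bwd_layer(model$layers[[i]], layer_id(i), caches[[i]], dOut,
                   model$params, per_sample, B)
    dOut <- r$dX
    if (!is.null(r$pgrads)) grads[[layer_id(i)]] <- r$pgrads
  }
  tpl <- param_template(model)
  if (per_sample) {
    out <- matrix(0, B, tpl$total)
  } else {
    out <- numeric(tpl$total)
  }
  for (j in seq_along(tpl$names)) {
    n <- tpl$names[j]
    id <- sub("\\..*$", "", n)
    part <- sub("^[^.]*\\.", "", n)
    gpart <- grads[[id]][[part]]
    cols <- (tpl$offsets[j] + 1):(tpl$offsets[j] + tpl$lens[j])
    if (per_sample) out[, cols] <- gpart else out[cols] <- gpart
  }
  out
}

bwd_layer <- function(l, id, cache, dOut, params, per_sample, B) {
  switch(l$type,
    dense = {
      W <- params[[paste0(id, ".W")]]
      X <- cache$X
      dX <- dOut %*% t(W)
      if (per_sample) {
        inf <- nrow(W); outf <- ncol(W)
        # per-sample outer products, laid out column-major like W itself
        dW <- X[, rep(seq_len(inf), outf), drop = FALSE] *
          dOut[, rep(seq_len(outf), each = inf), drop = FALSE]
        list(dX = dX, pgrads = list(W = dW, b = dOut))
      } else {
        list(dX = dX, pgrads = list(W = crossprod(X, dOut), b = colSums(dOut)))
      }
    },
    relu = list(dX = dOut * cache$mask, pgrads = NULL),
    sigmoid = list(dX = dOut * cache$s * (1 - cache$s), pgrads = NULL),
    flatten = {
      dX <- dOut
      dim(dX) <- cache$dims
      list(dX = dX, pgrads = NULL)
    },
    conv2d = conv2d_backward(l, id, cache, dOut, params, per_sample, B),
    avgpool2d = avgpool_backward(l, cache, dOut),
    batch_norm2d = bn_backward(l, id, cache, dOut, params, per_sample),
    group_norm = gn_backward(l, id, cache, dOut, params, per_sample),
    stop("unknown layer type: ", l$type, call. = FALSE))
}

conv2d_backward <- function(l, id, cache, dOut, params, per_sample, B) {
  W <- params[[paste0(id, ".W")]]
  k <- l$k; Cin <- l$cin; Cout <- l$cout
  Ho <- cache$Ho; Wo <- cache$Wo
  dOm <- dOut; dim(dOm) <- c(B * Ho * Wo, Cout)
  Wm <- W; dim(Wm) <- c(k * k * Cin, Cout)
  dPm <- dOm %*% t(Wm)
  dim(dPm) <- c(B, Ho, Wo, k, k, Cin)
  pd <- cache$padded_dim
  dXp <- array(0, pd)
  for (di in 1:k) for (dj in 1:k)
    dXp[, di:(di + Ho - 1L), dj:(dj + Wo - 1L), ] <-
      dXp[, di:(di + Ho - 1L), dj:(dj + Wo - 1L), ] + dPm[, , , di, dj, ]
  p <- cache$p
  dX <- if (p > 0) dXp[, (p + 1):(pd[2] - p), (p + 1):(pd[3] - p), , drop = FALSE]
        else dXp
  if (per_sample) {
    P3 <- cache$Pm; dim(P3) <- c(B, Ho * Wo, k * k * Cin)
    dO3 <- dOm; dim(dO3) <- c(B, Ho * Wo, Cout)
    dW <- matrix(0, B, k * k * Cin * Cout)
    for (b in seq_len(B)) {
      dW[b, ] <- crossprod(
        matrix(P3[b, , ], Ho * Wo, k * k * Cin),
        matrix(dO3[b, , ], Ho * Wo, Cout))
    }
    db <- apply(dO3, c(1, 3), sum)
    list(dX = dX, pgrads = list(W = dW, b = db))
  } else {
    list(dX = dX, pgrads = list(W = crossprod(cache$Pm, dOm), b = colSums(dOm)))
  }
}

avgpool_backward <- function(l, cache, dOut) {
  f <- l$f; d <- cache$in_dim; B <- d[1]; C <- d[4]
  Ho <- cache$Ho; Wo <- cache$Wo
  dY <- matrix(as.numeric(dOut) / (f * f), B * Ho * Wo * C, f * f)
  dim(dY) <- c(B, Ho, Wo, C, f, f)
  dX0 <- aperm(dY, c(1, 5, 2, 6, 3, 4))
  dim(dX0) <- c(B, Ho * f, Wo * f, C)
  if (Ho * f == d[2] && Wo * f == d[3]) return(list(dX = dX0, pgrads = NULL))
  dX <- array(0, d)
  dX[, 1:(Ho * f), 1:(Wo * f), ] <- dX0
  list(dX = dX, pgrads = NULL)
}

bn_backward <- function(l, id, cache, dOut, params, per_sample) {
  g <- params[[paste0(id, ".gamma")]]
  B <- cache$B; H <- cache$H; Wd <- cache$W; C <- cache$C
  dOp <- aperm(dOut, c(2, 3, 1, 4))
  if (cache$kind == "per_sample") {
    n <- H * Wd
    dim(dOp) <- c(n, B * C)
    gcol <- rep(rep(g, each = B), each = n)
    dxhat <- dOp * gcol
    mh <- rep(colMeans(dxhat), each = n)
    mxh <- rep(colMeans(dxhat * cache$xhat), each = n)
    dXp <- (dxhat - mh - cache$xhat * mxh) * rep(cache$inv_sd, each = n)
    dim(dXp) <- c(H, Wd, B, C)
    dX <- aperm(dXp, c(3, 1, 2, 4))
    dgamma <- matrix(colSums(dOp * cache$xhat), B, C)
    dbeta <- matrix(colSums(dOp), B, C)
    if (!per_sample) { dgamma <- colSums(dgamma); dbeta <- colSums(dbeta) }
    list(dX = dX, pgrads = list(gamma = dgamma, beta = dbeta))
  } else {
    if (per_sample)
      stop(paste("dp-incompatibility:", id,
                 "batch_norm2d couples samples through batch statistics;",
                 "run fix_model() first"), call. = FALSE)
    n <- H * Wd * B
    dim(dOp) <- c(n, C)
    if (cache$train) {
      dxhat <- dOp * rep(g, each = n)
      mh <- rep(colMeans(dxhat), each = n)
      mxh <- rep(colMeans(dxhat * cache$xhat), each = n)
      dXp <- (dxhat - mh - cache$xhat * mxh) * rep(cache$inv_sd, each = n)
    } else {
      dXp <- dOp * rep(g * cache$inv_sd, each = n)
    }
    dim(dXp) <- c(H, Wd, B, C)
    dX <- aperm(dXp, c(3, 1, 2, 4))
    list(dX = dX, pgrads = list(gamma = colSums(dOp * cache$xhat),
                                beta = colSums(dOp)))
  }
}

gn_backward <- function(l, id, cache, dOut, params, per_sample) {
  g <- params[[paste0(id, ".gamma")]]
  B <- cache$B; H <- cache$H; Wd <- cache$W; C <- cache$C
  G <- cache$G; cg <- cache$cg
  dOp <- aperm(dOut, c(2, 3, 4, 1))
  dim(dOp) <- c(H * Wd, C, B)
  dgamma <- matrix(0, B, C); dbeta <- matrix(0, B, C)
  for (ci in 1:C) {
    dc <- matrix(dOp[, ci, ], H * Wd, B)
    xc <- matrix(cache$xhat[, ci, ], H * Wd, B)
    dgamma[, ci] <- colSums(dc * xc)
    dbeta[, ci] <- colSums(dc)
  }
  dXp <- array(0, dim(dOp))
  ne <- H * Wd * cg
  for (gi in 1:G) {
    idx <- ((gi - 1) * cg + 1):(gi * cg)
    dxh <- dOp[, idx, , drop = FALSE] * rep(g[idx], each = H * Wd)
    xh <- cache$xhat[, idx, , drop = FALSE]
    dim(dxh) <- c(ne, B); dim(xh) <- c(ne, B)
    mh <- rep(colMeans(dxh), each = ne)
    mxh <- rep(colMeans(dxh * xh), each = ne)
    sub <- (dxh - mh - xh * mxh) * rep(cache$inv_sd[gi, ], each = ne)
    dim(sub) <- c(H * Wd, cg, B)
    dXp[, idx, ] <- sub
  }
  dim(dXp) <- c(H, Wd, C, B)
  dX <- aperm(dXp, c(4, 1, 2, 3))
  if (!per_sample) { dgamma <- colSums(dgamma); dbeta <- colSums(dbeta) }
  list(dX = dX, pgrads = list(gamma = dgamma, beta = dbeta))
}
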