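#' Synthetic fixture datasets
#'
#' Seeded generators emulating the statistical shape of two medical-image
#' tasks so every pipeline in the package can be exercised offline:
#'
#' * classification: grayscale "chest-film-like" images where negatives
#'   are smooth noise backgrounds and positives additionally carry 1-3
#'   soft elliptical bright opacities, with a class imbalance defaulting
#'   to the 1339 negative / 3824 positive make-up of the paediatric
#'   pneumonia set-up this fixture emulates;
#' * segmentation: one smooth bright "organ" blob per image over textured
#'   background, the binary mask being exactly the blob's support.
#'
#' A fixed seed yields identical manifests and pixel bytes. The images are
#' deliberately simple phantoms: they provide a learnable, high-contrast
#' signal, not radiological realism.
#'
#' @name synthetic
NULL

#' @describeIn synthetic Generate a classification dataset and manifest.
#' @param out_dir output directory (created if needed).
#' @param n_negative,n_positive class counts.
#' @param size image side length in pixels (square), >= 32.
#' @param seed integer seed; same seed, same bytes.
#' @param train_fraction fraction of records assigned to the train split
#'   (rest is val).
#' @return the manifest (invisibly written to `out_dir/manifest.csv`).
#' @export
generate_classification <- function(out_dir, n_negative = 1339,
                                    n_positive = 3824, size = 224, seed = 1,
                                    train_fraction = 0.85) {
  stopifnot(n_negative >= 1, n_positive >= 1, size >= 32)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- n_negative + n_positive
  labels <- c(rep(0L, n_negative), rep(1L, n_positive))
  paths <- sprintf("img%05d.png", seq_len(n))
  with_local_seed(seed, {
    for (i in seq_len(n)) {
      img <- synth_background(size)
      if (labels[i] == 1L) img <- add_opacities(img, sample(1:3, 1))
      write_gray_png(img, file.path(out_dir, paths[i]))
    }
  })
  split <- assign_split(n, train_fraction, seed = seed + 1L)
  manifest <- data.frame(path = paths, label = labels, split = split)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  invisible(structure(manifest, class = c("dataset_manifest", "data.frame"),
                      root = out_dir))
}

#' @describeIn synthetic Generate a segmentation dataset (image/mask pairs).
#' @param n_images number of image/mask pairs (default scaled down for
#'   desk-scale work; privacy accounting always uses the schedule's own n,
#'   which needs no data).
#' @param fg_range admissible mask foreground fraction range.
#' @export
generate_segmentation <- function(out_dir, n_images = 512, size = 256,
                                  seed = 1, train_fraction = 0.85,
                                  fg_range = c(0.05, 0.30)) {
  stopifnot(n_images >= 1, size >= 32, fg_range[1] > 0, fg_range[2] < 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- sprintf("img%05d.png", seq_len(n_images))
  mpaths <- sprintf("msk%05d.png", seq_len(n_images))
  with_local_seed(seed, {
    for (i in seq_len(n_images)) {
      pair <- synth_blob_pair(size, fg_range)
      write_gray_png(pair$image, file.path(out_dir, paths[i]))
      write_gray_png(pair$mask, file.path(out_dir, mpaths[i]))
    }
  })
  split <- assign_split(n_images, train_fraction, seed = seed + 1L)
  manifest <- data.frame(path = paths, label = 1L, mask_path = mpaths,
                         split = split)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  invisible(structure(manifest, class = c("dataset_manifest", "data.frame"),
                      root = out_dir))
}

# smooth background: bilinearly upsampled coarse noise + fine grain
synth_background <- function(size) {
  coarse <- matrix(stats::runif(64), 8, 8)
  bg <- 0.25 + 0.35 * resize_bilinear(coarse, size, size) +
    0.03 * matrix(stats::rnorm(size^2), size, size)
  clamp01(bg)
}

add_opacities <- function(img, k) {
  size <- nrow(img)
  rr <- matrix(seq_len(size), size, size)
  cc <- matrix(seq_len(size), size, size, byrow = TRUE)
  for (j in seq_len(k)) {
    ctr <- stats::runif(2, 0.25 * size, 0.75 * size)
    ax <- stats::runif(2, size / 10, size / 4)
    th <- stats::runif(1, 0, pi)
    amp <- stats::runif(1, 0.20, 0.35)
    dr <- rr - ctr[1]; dc <- cc - ctr[2]
    u <- cos(th) * dr + sin(th) * dc
    v <- -sin(th) * dr + cos(th) * dc
    img <- img + amp * exp(-0.5 * ((u / ax[1])^2 + (v / ax[2])^2))
  }
  clamp01(img)
}

# star-convex blob: radius r(theta) = r0 (1 + sum_k a_k cos(k theta + phi_k))
synth_blob_pair <- function(size, fg_range) {
  frac <- stats::runif(1, fg_range[1], fg_range[2])
  r0 <- size * sqrt(frac / pi)
  ctr <- stats::runif(2, 0.4 * size, 0.6 * size)
  ak <- stats::runif(4, 0, 0.12) / (1:4)
  ph <- stats::runif(4, 0, 2 * pi)
  rr <- matrix(seq_len(size), size, size)
  cc <- matrix(seq_len(size), size, size, byrow = TRUE)
  dr <- rr - ctr[1]; dc <- cc - ctr[2]
  rho <- sqrt(dr^2 + dc^2)
  theta <- atan2(dc, dr)
  rad <- r0 * (1 + Reduce(`+`, lapply(1:4, function(k)
    ak[k] * cos((k + 1) * theta + ph[k]))))
  mask <- (rho <= rad) * 1
  bg <- 0.15 + 0.15 * resize_bilinear(matrix(stats::runif(64), 8, 8),
                                      size, size)
  img <- clamp01(bg + 0.45 * mask +
                   0.05 * matrix(stats::rnorm(size^2), size, size))
  list(image = img, mask = mask)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Affine image warp (inverse mapping)
#'
#' Warps a matrix image by the affine map `dst = A %*% src_c + t` about
#' the image centre, sampling by inverse mapping with bilinear (images) or
#' nearest-neighbour (masks: no interpolated grey values) filtering.
#' Out-of-frame samples are filled with `fill`. The identity map returns
#' the input bit-for-bit; right-angle rotations permute the pixel grid
#' exactly.
#'
#' @param img numeric matrix.
#' @param A 2x2 linear part (acting on centred (row, col) coordinates).
#' @param t length-2 translation in pixels.
#' @param filter `"bilinear"` or `"nearest"`.
#' @param fill fill value outside the source frame.
#' @return warped matrix, same shape.
#' @export
warp_affine <- function(img, A = diag(2), t = c(0, 0),
                        filter = c("bilinear", "nearest"), fill = 0) {
  filter <- match.arg(filter)
  H <- nrow(img); W <- ncol(img)
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  iA <- solve(A)
  u <- rep(seq_len(H) - cr, times = W) - t[1]
  v <- rep(seq_len(W) - cc, each = H) - t[2]
  su <- iA[1, 1] * u + iA[1, 2] * v + cr
  sv <- iA[2, 1] * u + iA[2, 2] * v + cc
  out <- rep(fill, H * W)
  if (filter == "nearest") {
    ri <- round(su); ci <- round(sv)
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    out[ok] <- img[cbind(ri[ok], ci[ok])]
  } else {
    r0 <- floor(su); c0 <- floor(sv)
    fr <- su - r0; fc <- sv - c0
    acc <- numeric(H * W)
    wsum <- numeric(H * W)
    for (dr in 0:1) for (dc in 0:1) {
      ri <- r0 + dr; ci <- c0 + dc
      w <- (if (dr == 0) 1 - fr else fr) * (if (dc == 0) 1 - fc else fc)
      ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W & w > 0
      acc[ok] <- acc[ok] + w[ok] * img[cbind(ri[ok], ci[ok])]
      wsum[ok] <- wsum[ok] + w[ok]
    }
    inside <- wsum > 0
    out[inside] <- acc[inside] + fill * (1 - wsum[inside])
  }
  matrix(out, H, W)
}

resize_bilinear <- function(img, H, W) {
  h <- nrow(img); w <- ncol(img)
  su <- (seq_len(H) - 0.5) * h / H + 0.5
  sv <- (seq_len(W) - 0.5) * w / W + 0.5
  su <- pmin(pmax(su, 1), h); sv <- pmin(pmax(sv, 1), w)
  r0 <- pmin(floor(su), h - 1); c0 <- pmin(floor(sv), w - 1)
  fr <- su - r0; fc <- sv - c0
  img[r0, c0] * outer(1 - fr, 1 - fc) + img[r0 + 1, c0] * outer(fr, 1 - fc) +
    img[r0, c0 + 1] * outer(1 - fr, fc) + img[r0 + 1, c0 + 1] * outer(fr, fc)
}

#' Random data augmentation
#'
#' Classification augmentation draws one random affine from the four
#' families rotation / scaling / translation / shearing; segmentation
#' augmentation draws rotation / translation / scaling / flipping and adds
#' Gaussian pixel noise to the image only. For image/mask pairs the
#' identical geometric transform is applied to both; masks are resampled
#' nearest-neighbour so they stay binary, images bilinearly.
#'
#' Default parameter ranges (documented package defaults): rotation within
#' +/-15 degrees, scale 0.9-1.1, translation within +/-10% of the frame,
#' shear within +/-10 degrees, noise sd 0.02.
#'
#' @param image matrix image in [0, 1].
#' @param mask optional binary matrix mask (segmentation only).
#' @param kind `"classification"` or `"segmentation"`.
#' @param seed integer seed for the random draw (NULL = current RNG).
#' @param params optional fixed transform parameters, a list with fields
#'   `angle` (deg), `scale`, `translate` (length 2, pixels), `shear`
#'   (deg), `flip` (logical), `noise_sd`. Identity parameters (0 / 1 /
#'   c(0,0) / 0 / FALSE / 0) return the input unchanged.
#' @return list with `image` (and `mask` when given) plus `params` used.
#' @export
augment <- function(image, mask = NULL,
                    kind = c("classification", "segmentation"),
                    seed = NULL, params = NULL) {
  kind <- match.arg(kind)
  if (kind == "classification" && !is.null(mask))
    stop("misuse: classification augmentation takes no mask", call. = FALSE)
  if (is.null(params)) {
    draw <- function() {
      size <- nrow(image)
      list(angle = stats::runif(1, -15, 15),
           scale = stats::runif(1, 0.9, 1.1),
           translate = stats::runif(2, -0.1, 0.1) * size,
           shear = if (kind == "classification") stats::runif(1, -10, 10) else 0,
           flip = if (kind == "segmentation") stats::runif(1) < 0.5 else FALSE,
           noise_sd = if (kind == "segmentation") 0.02 else 0)
    }
    params <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
  }
  identity_tf <- params$angle == 0 && params$scale == 1 &&
    all(params$translate == 0) && params$shear == 0 && !isTRUE(params$flip)
  if (identity_tf) {
    out_img <- image
    out_mask <- mask
  } else {
    th <- params$angle * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    Sh <- matrix(c(1, 0, tan(params$shear * pi / 180), 1), 2, 2)
    Fl <- diag(c(1, if (isTRUE(params$flip)) -1 else 1))
    A <- R %*% Sh %*% Fl * params$scale
    out_img <- warp_affine(image, A, params$translate, filter = "bilinear")
    out_mask <- if (!is.null(mask))
      warp_affine(mask, A, params$translate, filter = "nearest")
  }
  if (params$noise_sd > 0) {
    noise <- matrix(stats::rnorm(length(out_img), sd = params$noise_sd),
                    nrow(out_img))
    out_img <- clamp01(out_img + noise)
  }
  out <- list(image = out_img, params = params)
  if (!is.null(mask)) out$mask <- out_mask
  out
}

# 8-bit quantisation happens here, once, so written bytes are a pure
# function of the generator's seeded draws.
write_gray_png <- function(img, path) {
  q <- round(clamp01(img) * 255) / 255
  png::writePNG(q, path)
  invisible(path)
}
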