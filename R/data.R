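#' Dataset manifests
#'
#' A manifest is a plain data frame tying image files to labels (and,
#' for segmentation, mask files), with optional subject identifiers and a
#' `split` column (`train` / `val` / `test`). On disk it is a CSV with
#' columns `path,label[,mask_path][,subject_id],split` relative to its own
#' directory. The privacy unit is one record (one image) unless subject
#' grouping is requested downstream.
#'
#' @param path manifest CSV path.
#' @param check_paths verify that every referenced file exists.
#' @return a data frame of class `dataset_manifest` with attribute `root`
#'   (the manifest's directory, against which relative paths resolve).
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "split") %in% names(df)))
    stop("manifest needs at least 'path' and 'split' columns", call. = FALSE)
  root <- dirname(path)
  if (check_paths) {
    files <- file.path(root, df$path)
    miss <- !file.exists(files)
    if (any(miss))
      stop("manifest references missing files, e.g. ", files[which(miss)[1]],
           call. = FALSE)
    if ("mask_path" %in% names(df)) {
      mfiles <- file.path(root, df$mask_path)
      if (any(!file.exists(mfiles)))
        stop("manifest references missing mask files", call. = FALSE)
    }
  }
  structure(df, class = c("dataset_manifest", "data.frame"), root = root)
}

#' @rdname read_manifest
#' @param manifest a manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Class counts of a manifest
#' @param manifest a manifest with a `label` column.
#' @return named integer vector of per-label counts.
#' @export
class_counts <- function(manifest) {
  stopifnot("label" %in% names(manifest))
  table_ <- table(manifest$label)
  stats::setNames(as.integer(table_), names(table_))
}

#' Train/validation sizes for a fractional split
#'
#' The training share is rounded half-up, so an 85/15 split of 5163
#' records yields 4389 training and 774 validation records.
#'
#' @param n total record count, >= 1.
#' @param train_fraction fraction assigned to training, in (0, 1).
#' @return named integer vector `c(train = ..., val = ...)`.
#' @export
split_counts <- function(n, train_fraction) {
  stopifnot(n >= 1, train_fraction > 0, train_fraction < 1)
  n_train <- floor(train_fraction * n + 0.5)   # half-up
  n_val <- n - n_train
  if (n_train < 1 || n_val < 1)
    stop("degenerate split: both parts must be non-empty (n = ", n, ")",
         call. = FALSE)
  c(train = as.integer(n_train), val = as.integer(n_val))
}

#' Randomised split assignment
#'
#' Assigns each record to `train` or `val` with the sizes of
#' [split_counts()], randomised by an explicit seed. When subject ids are
#' given the split is subject-disjoint: whole subjects are assigned to one
#' side (shuffled subjects are accumulated into the training side until
#' its quota is reached, so realised sizes then match the quota only up to
#' subject granularity).
#'
#' @param n record count.
#' @param train_fraction training fraction in (0, 1).
#' @param seed integer seed for the shuffle.
#' @param subjects optional length-n subject id vector.
#' @return character vector of length n with values `"train"` / `"val"`.
#' @export
assign_split <- function(n, train_fraction, seed, subjects = NULL) {
  sizes <- split_counts(n, train_fraction)
  out <- rep("val", n)
  with_local_seed(seed, {
    if (is.null(subjects)) {
      out[sample.int(n, sizes["train"])] <- "train"
    } else {
      stopifnot(length(subjects) == n)
      subj <- sample(unique(subjects))
      taken <- 0L
      for (s in subj) {
        idx <- which(subjects == s)
        if (taken >= sizes["train"]) break
        out[idx] <- "train"
        taken <- taken + length(idx)
      }
      if (all(out == "train") || all(out == "val"))
        stop("degenerate split: subject structure leaves one side empty",
             call. = FALSE)
    }
  })
  out
}

#' Class weights for imbalanced losses
#'
#' Weight of class c is one minus its proportion of the dataset,
#' `w_c = 1 - n_c / n`; the minority class thus gets the larger weight.
#' Weights over k classes always sum to k - 1.
#'
#' @param counts named positive counts per class (>= 2 classes).
#' @return named numeric weights.
#' @examples
#' class_weights(c(negative = 1339, positive = 3824))
#' @export
class_weights <- function(counts) {
  if (length(counts) < 2)
    stop("class weighting needs at least two classes", call. = FALSE)
  stopifnot(all(counts > 0))
  1 - counts / sum(counts)
}

#' Minibatch index sequences
#'
#' `uniform_batches()` makes one epoch of shuffled fixed-size batches: a
#' seeded permutation partitioned into `ceiling(n/B)` batches covering
#' every index exactly once (the last batch may be short). This is the
#' sampler the `gdp-uniform` accountant models.
#'
#' `poisson_batches()` draws `steps` Poisson-subsampled batches: every
#' index enters each batch independently with probability q, so batch
#' sizes are Binomial(n, q). Empty batches are kept — they become
#' noise-only gradient steps — and every emitted batch counts as one
#' accounting step, which is exactly the mechanism the `gdp-poisson`
#' accountant analyses.
#'
#' @param n dataset size.
#' @param B batch size (uniform sampler), 1 <= B <= n.
#' @param q sampling rate (Poisson sampler), in (0, 1].
#' @param steps number of batches to draw (Poisson sampler).
#' @param seed integer seed.
#' @return list of integer index vectors.
#' @export
uniform_batches <- function(n, B, seed) {
  if (B > n || B < 1) stop("invalid argument: need 1 <= B <= n", call. = FALSE)
  perm <- with_local_seed(seed, sample.int(n))
  split(perm, ceiling(seq_along(perm) / B))
}

#' @rdname uniform_batches
#' @export
poisson_batches <- function(n, q, steps, seed) {
  stopifnot(q > 0, q <= 1, steps >= 0)
  with_local_seed(seed, {
    lapply(seq_len(steps), function(i) which(stats::runif(n) < q))
  })
}

#' Occurrence counting for the privacy ledger
#'
#' Counts how often each record was presented to the model, from a log of
#' per-step index batches. Augmented presentations count exactly like raw
#' ones — augmentation earns no privacy discount — and the number of steps
#' reported to the accountant is the number of logged steps, including
#' empty (noise-only) ones. Step numbering must be gap-free.
#'
#' @param log list of integer index vectors, element t = batch of step t;
#'   or a data frame with columns `step` and `index`.
#' @param n dataset size (gives counts for never-seen records too).
#' @return list with `counts` (length-n integer) and `steps` (count to
#'   report to the accountant).
#' @export
count_occurrences <- function(log, n) {
  if (is.data.frame(log)) {
    steps_present <- sort(unique(log$step))
    if (length(steps_present) &&
        !identical(as.integer(steps_present),
                   seq_len(max(steps_present))))
      stop("log integrity: gaps in step numbering", call. = FALSE)
    idx <- log$index
    total_steps <- if (length(steps_present)) max(steps_present) else 0L
  } else {
    idx <- as.integer(unlist(log, use.names = FALSE))
    total_steps <- length(log)
  }
  counts <- tabulate(idx, nbins = n)
  list(counts = counts, steps = as.integer(total_steps))
}

# Evaluate an expression under a temporary seed, restoring the caller's
# RNG state — samplers must not perturb surrounding experiment code.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Load a manifest's images into memory
#'
#' Reads the referenced PNGs into a `(N, H, W, 1)` array (grayscale; RGB
#' input is averaged to one channel) plus labels or a mask array.
#'
#' @param manifest a [read_manifest()] result (or data frame with attr
#'   `root`).
#' @param split restrict to one split (`NULL` = all records).
#' @return list with `x` (image array), and `y` (labels) or `masks`.
#' @export
load_images <- function(manifest, split = NULL) {
  df <- as.data.frame(manifest)
  root <- attr(manifest, "root") %||% "."
  if (!is.null(split)) df <- df[df$split %in% split, , drop = FALSE]
  if (nrow(df) == 0) stop("no records selected", call. = FALSE)
  imgs <- lapply(file.path(root, df$path), read_gray_png)
  hw <- dim(imgs[[1]])
  x <- array(0, c(nrow(df), hw[1], hw[2], 1))
  for (i in seq_along(imgs)) x[i, , , 1] <- imgs[[i]]
  out <- list(x = x)
  if ("mask_path" %in% names(df)) {
    masks <- array(0, dim(x))
    mi <- lapply(file.path(root, df$mask_path), read_gray_png)
    for (i in seq_along(mi)) masks[i, , , 1] <- as.numeric(mi[[i]] > 0.5)
    out$masks <- masks
  }
  if ("label" %in% names(df)) out$y <- df$label
  out
}

read_gray_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3])], c(1, 2), mean)
  img
}
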