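#' Gaussian noise for the DP mechanism
#'
#' Draws `length` independent samples from N(0, `std`^2). In secure mode
#' (the default, and the only mode permitted during private training) the
#' uniform variates are read from the operating system's cryptographically
#' secure entropy pool (`/dev/urandom`) and transformed to Gaussians by the
#' Box-Muller method; the draw is non-reproducible by design and a `seed`
#' argument is rejected. In insecure mode the draw comes from R's seeded RNG
#' and is bit-reproducible for a fixed seed; it exists for tests and
#' debugging only and must never back a privacy guarantee.
#'
#' The state of R's global RNG is left untouched by both modes, so noise
#' generation never perturbs seeded experiment code around it.
#'
#' @param length number of scalars to draw (>= 0).
#' @param std standard deviation of the noise; in DP-SGD use this is
#'   `sigma * C` (noise multiplier times clipping norm).
#' @param secure draw from the OS CSPRNG (`TRUE`, default) or from R's
#'   seeded RNG (`FALSE`).
#' @param seed integer seed, honoured only when `secure = FALSE`; supplying
#'   one in secure mode is an error rather than a silent downgrade.
#' @return numeric vector of `length` Gaussian draws.
#' @examples
#' gaussian_noise(5, std = 0)            # exact zeros
#' gaussian_noise(8, std = 1, secure = FALSE, seed = 7)
#' @export
gaussian_noise <- function(length, std, secure = TRUE, seed = NULL) {
  stopifnot(length >= 0, std >= 0)
  if (secure && !is.null(seed)) {
    stop("a seed was supplied with secure = TRUE; secure noise is not seedable",
         call. = FALSE)
  }
  if (length == 0) return(numeric(0))
  if (std == 0) return(numeric(length))
  if (secure) {
    box_muller(secure_uniforms(length), secure_uniforms(length)) * std
  } else {
    local_seed_rnorm(length, seed) * std
  }
}

# Uniform(0,1) variates from the OS entropy pool. 32 random bits per variate
# (assembled from raw bytes: R's integer type cannot hold all 2^32 patterns),
# mapped into the open interval (0,1) so log() in Box-Muller never sees 0.
secure_uniforms <- function(n) {
  con <- file("/dev/urandom", "rb", raw = TRUE)  # a device, not a regular file
  on.exit(close(con))
  raw <- readBin(con, what = "raw", n = 4L * n)
  if (length(raw) != 4L * n) stop("short read from /dev/urandom", call. = FALSE)
  b <- matrix(as.numeric(raw), nrow = 4L)
  u32 <- ((b[1, ] * 256 + b[2, ]) * 256 + b[3, ]) * 256 + b[4, ]
  (u32 + 0.5) / 2^32
}

box_muller <- function(u1, u2) {
  sqrt(-2 * log(u1)) * cos(2 * pi * u2)
}

# rnorm under a temporary, isolated RNG state.
local_seed_rnorm <- function(n, seed) {
  if (is.null(seed)) stop("insecure mode requires an explicit seed", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  stats::rnorm(n)
}

#' Noise source constructors
#'
#' A noise source is a function `f(length, std)` handed to
#' [aggregate_and_noise()] and the training loop; these constructors bind the
#' security mode once so downstream code cannot accidentally switch it.
#'
#' @param seed integer seed for the insecure source.
#' @return a function `(length, std) -> numeric vector`.
#' @export
secure_noise_source <- function() {
  f <- function(length, std) gaussian_noise(length, std, secure = TRUE)
  attr(f, "secure") <- TRUE
  f
}

#' @rdname secure_noise_source
#' @export
insecure_noise_source <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  counter <- 0L
  f <- function(length, std) {
    # distinct per-call seeds, reproducible as a sequence
    counter <<- counter + 1L
    gaussian_noise(length, std, secure = FALSE,
                   seed = (seed * 1009L + counter) %% .Machine$integer.max)
  }
  attr(f, "secure") <- FALSE
  f
}
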