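#' Training schedule for privacy accounting
#'
#' Bundles the privacy-relevant hyperparameters of a DP-SGD run: dataset
#' size `n` (number of privacy units, by default images), minibatch size
#' `B`, the number of epochs `E` or total steps `T`, the noise multiplier
#' `sigma`, the clipping norm `C` and the failure probability `delta`.
#' The subsampling rate is `q = B / n`. When only epochs are given, the
#' step count is derived as `T = E * ceiling(n / B)`, i.e. one full
#' traversal of the data per epoch.
#'
#' @param n dataset size (count of privacy units), >= 1.
#' @param batch_size minibatch size B, 1 <= B <= n.
#' @param epochs number of epochs E (optional if `total_steps` given).
#' @param total_steps total step count T (derived from epochs if missing).
#' @param sigma noise multiplier, > 0.
#' @param clip_norm L2 clipping norm C, > 0.
#' @param delta DP failure probability, in (0, 1).
#' @return an object of class `dp_schedule`.
#' @examples
#' training_schedule(n = 5184, batch_size = 32, epochs = 5,
#'                   sigma = 5.0, clip_norm = 0.5, delta = 1e-5)
#' @export
training_schedule <- function(n, batch_size, epochs = NULL, total_steps = NULL,
                              sigma, clip_norm = 1.0, delta = 1e-5) {
  if (!is.numeric(n) || n < 1) stop("invalid schedule: n must be >= 1", call. = FALSE)
  if (!is.numeric(batch_size) || batch_size < 1 || batch_size > n)
    stop("invalid schedule: need 1 <= batch_size <= n", call. = FALSE)
  if (!is.numeric(sigma) || sigma <= 0)
    stop("invalid schedule: sigma must be > 0", call. = FALSE)
  if (!is.numeric(clip_norm) || clip_norm <= 0)
    stop("invalid schedule: clip_norm must be > 0", call. = FALSE)
  if (!is.numeric(delta) || delta <= 0 || delta >= 1)
    stop("invalid schedule: delta must be in (0, 1)", call. = FALSE)
  if (is.null(total_steps)) {
    if (is.null(epochs)) stop("invalid schedule: give epochs or total_steps", call. = FALSE)
    total_steps <- steps_from_epochs(n, batch_size, epochs)
  }
  if (total_steps < 0) stop("invalid schedule: total_steps must be >= 0", call. = FALSE)
  structure(list(
    n = as.integer(n), batch_size = as.integer(batch_size),
    epochs = if (is.null(epochs)) NULL else as.integer(epochs),
    total_steps = as.integer(total_steps),
    q = batch_size / n, sigma = sigma, clip_norm = clip_norm, delta = delta
  ), class = "dp_schedule")
}

#' @export
print.dp_schedule <- function(x, ...) {
  cat(sprintf(
    "DP-SGD schedule: n = %d, B = %d (q = %.5g), T = %d%s, sigma = %g, C = %g, delta = %g\n",
    x$n, x$batch_size, x$q, x$total_steps,
    if (is.null(x$epochs)) "" else sprintf(" (%d epochs)", x$epochs),
    x$sigma, x$clip_norm, x$delta))
  invisible(x)
}

#' Convert epochs to accounting steps
#'
#' One epoch covers the dataset once, so it contributes `ceiling(n / B)`
#' optimiser steps.
#'
#' @inheritParams training_schedule
#' @param epochs number of epochs, >= 0.
#' @return integer step count `E * ceiling(n / B)`.
#' @export
steps_from_epochs <- function(n, batch_size, epochs) {
  if (!is.numeric(n) || n < 1 || !is.numeric(batch_size) || batch_size < 1)
    stop("invalid schedule: n and batch_size must be positive", call. = FALSE)
  if (batch_size > n) stop("invalid schedule: batch_size exceeds n", call. = FALSE)
  if (epochs < 0) stop("invalid schedule: epochs must be >= 0", call. = FALSE)
  as.integer(epochs) * as.integer(ceiling(n / batch_size))
}

#' Gaussian-DP mu for subsampled Gaussian mechanisms
#'
#' Central-limit composition of `T` applications of the Gaussian mechanism
#' with noise multiplier `sigma` under subsampling at rate `q = B/n`. Under
#' Poisson subsampling (each record enters each batch independently with
#' probability q):
#' \deqn{\mu = q \sqrt{T (e^{1/\sigma^2} - 1)}}
#' Under uniform (shuffled, fixed-size batch) subsampling:
#' \deqn{\mu = q \sqrt{T} \sqrt{e^{1/\sigma^2}\Phi(1.5/\sigma) +
#'   3\Phi(-0.5/\sigma) - 2}}
#' with \eqn{\Phi} the standard normal CDF. Both vanish as `T -> 0` or
#' `sigma -> Inf`. Smaller mu means stronger privacy.
#'
#' @param schedule a [training_schedule()].
#' @param steps step count at which to account; defaults to the schedule's
#'   total steps.
#' @return the GDP parameter mu (>= 0).
#' @export
compute_mu_poisson <- function(schedule, steps = schedule$total_steps) {
  stopifnot(inherits(schedule, "dp_schedule"), steps >= 0)
  schedule$q * sqrt(steps * (exp(1 / schedule$sigma^2) - 1))
}

#' @rdname compute_mu_poisson
#' @export
compute_mu_uniform <- function(schedule, steps = schedule$total_steps) {
  stopifnot(inherits(schedule, "dp_schedule"), steps >= 0)
  s <- schedule$sigma
  inner <- exp(1 / s^2) * stats::pnorm(1.5 / s) + 3 * stats::pnorm(-0.5 / s) - 2
  schedule$q * sqrt(steps) * sqrt(max(inner, 0))
}

#' Gaussian-DP duality between mu, epsilon and delta
#'
#' A mu-GDP mechanism satisfies (epsilon, delta)-DP for every epsilon >= 0
#' with
#' \deqn{\delta(\varepsilon;\mu) = \Phi(-\varepsilon/\mu + \mu/2) -
#'   e^\varepsilon \Phi(-\varepsilon/\mu - \mu/2).}
#' `delta_from_eps_mu` evaluates this curve (the exponential factor is
#' folded into the normal log-CDF to stay finite at large epsilon);
#' `eps_from_delta_mu` inverts it, returning the smallest epsilon whose
#' delta does not exceed the target, by bracketed root-finding on
#' [0, 1e4] (bracket expanded if needed) to absolute tolerance 1e-9.
#'
#' @param eps privacy loss epsilon, >= 0.
#' @param mu GDP parameter, >= 0. `mu = 0` is the degenerate mechanism that
#'   releases nothing: delta is 0 and epsilon 0.
#' @param delta target failure probability in (0, 1).
#' @return `delta_from_eps_mu`: delta in [0, 1); `eps_from_delta_mu`:
#'   epsilon >= 0.
#' @examples
#' delta_from_eps_mu(0, 1)            # 2 * pnorm(0.5) - 1
#' eps_from_delta_mu(1e-5, 0.0355)
#' @export
delta_from_eps_mu <- function(eps, mu) {
  stopifnot(all(eps >= 0), all(mu >= 0))
  out <- numeric(length(eps) * 0 + max(length(eps), length(mu)))
  eps <- rep_len(eps, length(out)); mu <- rep_len(mu, length(out))
  pos <- mu > 0
  out[!pos] <- 0
  if (any(pos)) {
    e <- eps[pos]; m <- mu[pos]
    d <- stats::pnorm(-e / m + m / 2) -
      exp(e + stats::pnorm(-e / m - m / 2, log.p = TRUE))
    out[pos] <- pmin(pmax(d, 0), 1)  # clamp float dust at the extremes
  }
  out
}

#' @rdname delta_from_eps_mu
#' @export
eps_from_delta_mu <- function(delta, mu) {
  stopifnot(delta > 0, delta < 1, mu >= 0)
  if (mu == 0) return(0)
  if (!is.finite(mu)) return(Inf)   # degenerate mechanism: no finite budget
  if (delta_from_eps_mu(0, mu) <= delta) return(0)
  upper <- 1e4
  f <- function(e) delta_from_eps_mu(e, mu) - delta
  while (f(upper) > 0) {
    upper <- upper * 10
    if (upper > 1e8) stop("accounting overflow: no epsilon bracket found", call. = FALSE)
  }
  stats::uniroot(f, c(0, upper), tol = 1e-9)$root
}

#' Per-step Renyi-DP curve of the Poisson-sampled Gaussian mechanism
#'
#' For integer orders alpha >= 2 the Renyi divergence of one Poisson-sampled
#' Gaussian step at rate q and noise multiplier sigma has the exact
#' binomial-sum bound
#' \deqn{\varepsilon(\alpha) = \frac{1}{\alpha-1}\log
#'   \sum_{k=0}^{\alpha}\binom{\alpha}{k}(1-q)^{\alpha-k}q^k
#'   e^{k(k-1)/(2\sigma^2)}.}
#' The sum is evaluated in log space (log-sum-exp over `lchoose` terms) so
#' large alpha/small sigma combinations do not overflow. At q = 1 this
#' collapses to the plain Gaussian-mechanism value alpha / (2 sigma^2).
#'
#' @param q sampling rate in [0, 1].
#' @param sigma noise multiplier, > 0.
#' @param orders integer Renyi orders, each >= 2.
#' @return an object of class `rdp_curve`: list with `orders` and
#'   `eps_per_step` (aligned, all >= 0).
#' @export
rdp_sampled_gaussian <- function(q, sigma, orders = 2:256) {
  stopifnot(q >= 0, q <= 1, sigma > 0)
  orders <- as.integer(orders)
  if (length(orders) == 0) stop("invalid argument: empty order list", call. = FALSE)
  if (any(orders < 2)) stop("invalid argument: orders must be integers >= 2", call. = FALSE)
  eps <- vapply(orders, function(alpha) {
    if (q == 0) return(0)
    if (q == 1) return(alpha / (2 * sigma^2))
    k <- 0:alpha
    lt <- lchoose(alpha, k) + (alpha - k) * log1p(-q) + k * log(q) +
      k * (k - 1) / (2 * sigma^2)
    m <- max(lt)
    if (!is.finite(m)) stop("accounting overflow in RDP log-sum", call. = FALSE)
    val <- (m + log(sum(exp(lt - m)))) / (alpha - 1)
    max(val, 0)  # the bound is nonnegative; guard tiny negative float dust
  }, numeric(1))
  structure(list(orders = orders, eps_per_step = eps), class = "rdp_curve")
}

#' Compose an RDP curve over steps and convert to (epsilon, delta)
#'
#' Per-step Renyi divergences compose additively over `T` steps; the
#' standard conversion to (epsilon, delta)-DP then takes the best order:
#' \deqn{\varepsilon = \min_\alpha \left[ T\,\varepsilon(\alpha) +
#'   \frac{\log(1/\delta)}{\alpha - 1} \right].}
#'
#' @param curve an [rdp_sampled_gaussian()] curve.
#' @param steps number of composed steps T, >= 0.
#' @param delta target delta in (0, 1).
#' @return list with `eps` (the minimum) and `best_order` (the minimising
#'   alpha).
#' @export
eps_from_rdp <- function(curve, steps, delta) {
  stopifnot(inherits(curve, "rdp_curve"), steps >= 0, delta > 0, delta < 1)
  if (length(curve$orders) == 0) stop("invalid argument: empty RDP curve", call. = FALSE)
  total <- steps * curve$eps_per_step + log(1 / delta) / (curve$orders - 1)
  i <- which.min(total)
  list(eps = total[i], best_order = curve$orders[i])
}

#' Account the privacy spent by a schedule
#'
#' Dispatches to the requested accountant and returns the budget consumed
#' after `steps` optimiser steps. `gdp-poisson` (the default used by the
#' training loop) and `gdp-uniform` compute mu by the CLT composition and
#' convert to epsilon at the schedule's delta through the GDP dual;
#' `rdp` composes the integer-order Renyi curve (orders 2..256) and
#' converts. Epsilon is non-decreasing in `steps` and in `q`, and
#' non-increasing in `sigma`, for fixed delta.
#'
#' @param schedule a [training_schedule()].
#' @param mode one of `"gdp-poisson"`, `"gdp-uniform"`, `"rdp"`.
#' @param steps step count to account (defaults to the schedule total).
#' @param orders integer RDP orders (rdp mode only).
#' @return an object of class `privacy_spent`: list with `mu` (NA for rdp
#'   mode), `epsilon`, `delta`, `steps_accounted`, `mode`, and for rdp mode
#'   `best_order`.
#' @examples
#' seg <- training_schedule(5184, 32, epochs = 5, sigma = 5, clip_norm = 0.5)
#' audit(seg, "gdp-poisson")
#' @export
audit <- function(schedule, mode = c("gdp-poisson", "gdp-uniform", "rdp"),
                  steps = schedule$total_steps, orders = 2:256) {
  stopifnot(inherits(schedule, "dp_schedule"))
  mode <- match.arg(mode)
  stopifnot(steps >= 0)
  if (mode %in% c("gdp-poisson", "gdp-uniform")) {
    mu <- if (mode == "gdp-poisson") compute_mu_poisson(schedule, steps)
          else compute_mu_uniform(schedule, steps)
    eps <- eps_from_delta_mu(schedule$delta, mu)
    best <- NULL
  } else {
    curve <- rdp_sampled_gaussian(schedule$q, schedule$sigma, orders)
    conv <- eps_from_rdp(curve, steps, schedule$delta)
    mu <- NA_real_; eps <- conv$eps; best <- conv$best_order
  }
  structure(list(mu = mu, epsilon = eps, delta = schedule$delta,
                 steps_accounted = as.integer(steps), mode = mode,
                 best_order = best),
            class = "privacy_spent")
}

#' @export
print.privacy_spent <- function(x, ...) {
  cat(sprintf("privacy spent after %d steps [%s]:\n", x$steps_accounted, x$mode))
  if (!is.na(x$mu)) cat(sprintf("  mu      = %.6g\n", x$mu))
  cat(sprintf("  epsilon = %.6g\n  delta   = %g\n", x$epsilon, x$delta))
  if (!is.null(x$best_order)) cat(sprintf("  best RDP order = %d\n", x$best_order))
  invisible(x)
}
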