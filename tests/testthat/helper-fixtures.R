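# Fixture builders shared across test files. Everything is generated in
# code; tests that need files write them to tempdirs.

# a random image batch (B, s, s, 1) with binary labels
random_batch <- function(B, s = 8, seed = 1) {
  set.seed(seed)
  list(x = array(rnorm(B * s * s), c(B, s, s, 1)),
       y = rbinom(B, 1, 0.5))
}

# small random architectures covering every layer kind the engine supports
random_model <- function(kind = c("dense", "conv", "bn", "gn"), s = 8) {
  kind <- match.arg(kind)
  switch(kind,
    dense = dp_model(layer_flatten(), layer_dense(s * s, 6), layer_relu(),
                     layer_dense(6, 1)),
    conv = dp_model(layer_conv2d(1, 3, 3), layer_relu(), layer_avgpool2d(2),
                    layer_flatten(), layer_dense(((s - 2) %/% 2)^2 * 3, 1)),
    bn = fix_model(dp_model(layer_conv2d(1, 4, 3, padding = "same"),
                            layer_batch_norm2d(4), layer_relu(),
                            layer_flatten(), layer_dense(s * s * 4, 1)))$model,
    gn = dp_model(layer_conv2d(1, 4, 3, padding = "same"),
                  layer_group_norm(4, 2), layer_relu(), layer_flatten(),
                  layer_dense(s * s * 4, 1)))
}

# in-memory classification set: mean-intensity signal, linearly separable
toy_classification_data <- function(n, s = 8, seed = 1) {
  set.seed(seed)
  y <- rbinom(n, 1, 0.5)
  x <- array(rnorm(n * s * s, sd = 0.3), c(n, s, s, 1))
  x[y == 1, , , ] <- x[y == 1, , , ] + 0.8
  list(x = x, y = y)
}

# independent brute-force RDP oracle: plain-arithmetic binomial sum,
# no log-space tricks shared with the implementation
rdp_bruteforce <- function(q, sigma, alpha) {
  k <- 0:alpha
  s <- sum(choose(alpha, k) * (1 - q)^(alpha - k) * q^k *
             exp(k * (k - 1) / (2 * sigma^2)))
  log(s) / (alpha - 1)
}

paper_classification_schedule <- function() {
  training_schedule(n = 4389, batch_size = 32, epochs = 20, sigma = 3.0,
                    clip_norm = 1.0, delta = 1e-5)
}

paper_segmentation_schedule <- function() {
  training_schedule(n = 5184, batch_size = 32, epochs = 5, sigma = 5.0,
                    clip_norm = 0.5, delta = 1e-5)
}
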