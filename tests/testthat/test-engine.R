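test_that("replicas are views over one shared parameter store", {
  set.seed(1)
  m <- random_model("dense")
  w <- wrap_model(m, 4)
  expect_length(w$replicas, 4)
  # same environment object, not copies
  for (r in w$replicas) expect_identical(r$params, m$params)
  # a write through the base store is visible through every replica
  nm <- ls(m$params)[1]
  m$params[[nm]][1] <- 123.456
  for (r in w$replicas) expect_equal(r$params[[nm]][1], 123.456)
})

test_that("wrapping at B = 1 reproduces the plain model exactly", {
  set.seed(2)
  m <- random_model("conv")
  b <- random_batch(1, seed = 3)
  plain <- nn_forward(m, b$x)$out
  wrapped <- parallel_forward(wrap_model(m, 1), b$x)$out
  expect_identical(plain, wrapped)
})

test_that("parallel forward equals per-sample evaluation", {
  set.seed(3)
  m <- random_model("conv")
  b <- random_batch(6, seed = 4)
  w <- wrap_model(m, 6)
  out <- parallel_forward(w, b$x)$out
  for (i in 1:6) {
    single <- nn_forward(m, b$x[i, , , , drop = FALSE])$out
    expect_equal(out[i, ], single[1, ], tolerance = 1e-12)
  }
  # identical samples give identical outputs
  xb <- b$x; for (i in 2:6) xb[i, , , ] <- xb[1, , , ]
  outs <- parallel_forward(w, xb)$out
  expect_true(all(apply(outs, 2, function(col) max(abs(col - col[1]))) < 1e-12))
  expect_error(parallel_forward(w, b$x[1:3, , , , drop = FALSE]), "shape")
})

test_that("a linear model matches the closed-form gradient", {
  # half squared error on w.x with w = (1, 1), x = (1, 2), y = 0:
  # prediction 3, gradient (w.x - y) * x = (3, 6), plus bias gradient 3
  m <- dp_model(layer_dense(2, 1))
  params_set_flat(m, c(1, 1, 0))
  w <- wrap_model(m, 1)
  out <- parallel_forward(w, matrix(c(1, 2), 1))$out
  expect_equal(as.numeric(out), 3)
  ps <- per_sample_grads(w, matrix(c(1, 2), 1), 0, loss_mse())
  expect_equal(as.numeric(ps$values), c(3, 6, 3))
})

test_that("parallel engine equals the serial oracle on random nets", {
  cases <- expand.grid(kind = c("dense", "conv", "bn", "gn"),
                       B = c(1, 5, 16), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    set.seed(100 + i)
    m <- random_model(cases$kind[i])
    b <- random_batch(cases$B[i], seed = 200 + i)
    ps <- per_sample_grads(wrap_model(m, cases$B[i]), b$x, b$y, loss_bce_logits())
    so <- serial_oracle(m, b$x, b$y, loss_bce_logits())
    expect_lt(max(abs(ps$values - so$values)), 1e-5)
    expect_equal(ps$losses, so$losses, tolerance = 1e-10)
  }
})

test_that("per-sample rows are independent across samples", {
  set.seed(7)
  m <- random_model("conv")
  b <- random_batch(5, seed = 8)
  ps1 <- per_sample_grads(wrap_model(m, 5), b$x, b$y, loss_bce_logits())
  # perturb sample 3 only: rows 1, 2, 4, 5 must not move
  x2 <- b$x; x2[3, , , ] <- x2[3, , , ] + 1
  ps2 <- per_sample_grads(wrap_model(m, 5), x2, b$y, loss_bce_logits())
  expect_equal(ps1$values[-3, ], ps2$values[-3, ], tolerance = 1e-12)
  expect_gt(max(abs(ps1$values[3, ] - ps2$values[3, ])), 0)
})

test_that("pre-reduced losses are refused", {
  set.seed(9)
  m <- random_model("dense")
  b <- random_batch(4, seed = 9)
  reduced <- structure(list(
    per_sample = function(pred, y) mean((as.numeric(pred) - y)^2),  # scalar!
    grad = function(pred, y) pred), class = "dp_loss")
  expect_error(per_sample_grads(wrap_model(m, 4), b$x, b$y, reduced), "misuse")
})

test_that("clipping bounds norms, preserves direction, is idempotent", {
  g <- structure(list(values = rbind(c(3, 4), c(0.1, 0), c(0, 0)),
                      per_sample_norms = c(5, 0.1, 0)),
                 class = "per_sample_grads")
  cl <- clip_grads(g, 1)
  expect_equal(cl$grads$values[1, ], c(0.6, 0.8))
  expect_equal(cl$grads$values[2, ], c(0.1, 0))      # within norm: untouched
  expect_equal(cl$grads$values[3, ], c(0, 0))        # zero row: no div failure
  expect_true(all(cl$report$clip_factors > 0 & cl$report$clip_factors <= 1))
  expect_true(all(cl$grads$per_sample_norms <= 1 + 1e-6))
  # idempotence
  cl2 <- clip_grads(cl$grads, 1)
  expect_equal(cl2$grads$values, cl$grads$values, tolerance = 1e-12)
  # random per-sample gradients always land within the ball
  set.seed(10)
  m <- random_model("conv")
  b <- random_batch(8, seed = 11)
  ps <- per_sample_grads(wrap_model(m, 8), b$x, b$y, loss_bce_logits())
  for (C in c(0.01, 0.5, 100)) {
    cc <- clip_grads(ps, C)
    expect_true(all(sqrt(rowSums(cc$grads$values^2)) <= C + 1e-6))
  }
})

test_that("aggregation: noiseless mean, sum/B consistency, noise wiring", {
  g <- structure(list(values = rbind(c(1, 0), c(0, 1)),
                      per_sample_norms = c(1, 1)), class = "per_sample_grads")
  expect_equal(aggregate_and_noise(g, C = 1, sigma = 0), c(0.5, 0.5))
  expect_equal(aggregate_and_noise(g, C = 1, sigma = 0, reduction = "sum") / 2,
               aggregate_and_noise(g, C = 1, sigma = 0))
  # injected noise is scaled by sigma * C and divided by B under mean
  probe <- function(length, std) rep(std, length)
  got <- aggregate_and_noise(g, C = 3, sigma = 2, noise_source = probe)
  expect_equal(got, (c(1, 1) + 6) / 2)
  bad <- function(length, std) numeric(length + 1)
  expect_error(aggregate_and_noise(g, C = 1, sigma = 1, noise_source = bad),
               "shape")
})

test_that("sigma = 0, C = Inf DP step equals an ordinary minibatch step", {
  set.seed(12)
  m1 <- random_model("conv")
  m2 <- random_model("conv")
  params_set_flat(m2, params_get_flat(m1))           # same start
  b <- random_batch(8, seed = 13)
  loss <- loss_bce_logits()
  # DP path, degenerate privacy parameters
  dp_step(wrap_model(m1, 8), b$x, b$y, loss, C = 1e12, sigma = 0,
          optimiser = opt_sgd(0.1))
  # plain minibatch-mean gradient step
  fw <- nn_forward(m2, b$x)
  g <- nn_backward(m2, fw$caches, loss$grad(fw$out, b$y) / 8, per_sample = FALSE)
  opt_sgd(0.1)$step(m2, g)
  expect_lt(max(abs(params_get_flat(m1) - params_get_flat(m2))), 1e-6)
})

test_that("serial oracle basics: single sample and constant loss", {
  set.seed(14)
  m <- random_model("dense")
  b <- random_batch(1, seed = 15)
  so <- serial_oracle(m, b$x, b$y, loss_bce_logits())
  fw <- nn_forward(m, b$x)
  g <- nn_backward(m, fw$caches, loss_bce_logits()$grad(fw$out, b$y),
                   per_sample = FALSE)
  expect_equal(as.numeric(so$values), g, tolerance = 1e-12)
  constant <- structure(list(
    per_sample = function(pred, y) rep(1, length(as.numeric(pred))),
    grad = function(pred, y) pred * 0), class = "dp_loss")
  b4 <- random_batch(4, seed = 16)
  so0 <- serial_oracle(m, b4$x, b4$y, constant)
  expect_true(all(so0$values == 0))
})
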