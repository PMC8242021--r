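test_that("ROC-AUC is the Mann-Whitney probability with half-credit ties", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1.0)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1)), 0.0)
  # symmetry: reversing scores flips the AUC
  set.seed(50)
  sc <- rnorm(100); lb <- rbinom(100, 1, 0.4)
  expect_equal(roc_auc(-sc, lb), 1 - roc_auc(sc, lb), tolerance = 1e-12)
  # independence: AUC near 1/2
  set.seed(51)
  expect_equal(roc_auc(rnorm(1e4), rbinom(1e4, 1, 0.5)), 0.5, tolerance = 0.02)
  # ties get half credit: all-equal scores give exactly 1/2
  expect_equal(roc_auc(rep(1, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(1:5, rep(1, 5)), "undefined")
  # agreement with an independent implementation
  skip_if_not_installed("pROC")
  expect_equal(roc_auc(sc, lb),
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-10)
})

test_that("Dice overlap handles identity, disjointness and empty masks", {
  a <- matrix(0, 4, 4); a[1:2, ] <- 1
  expect_equal(dice(a, a), 1.0)
  b <- matrix(0, 4, 4); b[3:4, ] <- 1
  expect_equal(dice(a, b), 0.0)
  # left half vs full frame on 4x4: 2*8 / (8 + 16)
  full <- matrix(1, 4, 4)
  expect_equal(dice(a, full), 2 / 3)
  expect_equal(dice(matrix(0, 2, 2), matrix(0, 2, 2)), 1.0)
  expect_error(dice(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("private config invariants are enforced", {
  set.seed(60)
  m <- random_model("dense")
  sch <- training_schedule(50, 10, epochs = 2, sigma = 1, clip_norm = 1)
  expect_error(run_config("classification", m, sch, seed = 1,
                          secure_rng = TRUE), "secure_rng")
  expect_error(run_config("classification", m, sch, secure_rng = FALSE),
               "insecure")
  expect_error(run_config("classification", m, sch, eps_budget = 0), "eps_budget")
  expect_s3_class(run_config("classification", m, sch, secure_rng = FALSE,
                             insecure_ok = TRUE, seed = 1), "run_config")
})

test_that("the watchdog halts exactly at the analytically inverted step", {
  set.seed(61)
  schedules <- list(
    training_schedule(60, 10, epochs = 4, sigma = 1.2, clip_norm = 1),
    training_schedule(60, 6, epochs = 3, sigma = 2.0, clip_norm = 0.5),
    training_schedule(60, 20, epochs = 5, sigma = 0.9, clip_norm = 1))
  targets <- c(13, 20, 7)
  data <- toy_classification_data(60, s = 6, seed = 62)
  for (i in seq_along(schedules)) {
    sch <- schedules[[i]]
    budget <- audit(sch, "gdp-poisson", steps = targets[i])$epsilon
    expect_equal(steps_within_budget(sch, budget), targets[i])
    model <- dp_model(layer_flatten(), layer_dense(36, 1))
    cfg <- run_config("classification", model, sch, lr = 0.05,
                      eps_budget = budget, secure_rng = FALSE,
                      insecure_ok = TRUE, seed = 63)
    tr <- train_private(cfg, data)
    expect_equal(tr$n_steps, targets[i])
    expect_equal(tr$halt_reason, "budget_exhausted")
    expect_lte(tr$final_privacy$epsilon, budget + 1e-12)
    # epsilon of the hypothetical next step would exceed the budget
    expect_gt(audit(sch, "gdp-poisson", steps = targets[i] + 1)$epsilon, budget)
  }
})

test_that("epsilon in a trace is non-decreasing and within budget", {
  set.seed(64)
  sch <- training_schedule(40, 8, epochs = 2, sigma = 1.5, clip_norm = 1)
  data <- toy_classification_data(40, s = 6, seed = 65)
  model <- dp_model(layer_flatten(), layer_dense(36, 1))
  cfg <- run_config("classification", model, sch, lr = 0.05,
                    secure_rng = FALSE, insecure_ok = TRUE, seed = 66)
  tr <- train_private(cfg, data)
  expect_equal(tr$halt_reason, "completed")
  expect_true(all(diff(tr$steps$eps) >= 0))
  expect_equal(tr$n_steps, sch$total_steps)
  # occurrence ledger: uniform sampler, 2 epochs -> every record seen twice
  expect_true(all(tr$occurrences$counts == 2))
  expect_equal(tr$occurrences$steps, tr$n_steps)
})

test_that("an immediately exhausted budget performs zero steps", {
  set.seed(67)
  sch <- training_schedule(40, 8, epochs = 2, sigma = 1, clip_norm = 1)
  data <- toy_classification_data(40, s = 6, seed = 68)
  model <- dp_model(layer_flatten(), layer_dense(36, 1))
  eps1 <- audit(sch, "gdp-poisson", steps = 1)$epsilon
  cfg <- run_config("classification", model, sch, eps_budget = eps1 / 2,
                    secure_rng = FALSE, insecure_ok = TRUE, seed = 69)
  before <- params_get_flat(model)
  tr <- train_private(cfg, data)
  expect_equal(tr$n_steps, 0L)
  expect_equal(params_get_flat(model), before)
})

test_that("private loop with degenerate parameters equals non-private loop", {
  set.seed(70)
  data <- toy_classification_data(32, s = 6, seed = 71)
  sch <- training_schedule(32, 8, epochs = 1, sigma = 1e-20, clip_norm = 1e12)
  m1 <- dp_model(layer_flatten(), layer_dense(36, 1))
  m2 <- dp_model(layer_flatten(), layer_dense(36, 1))
  params_set_flat(m2, params_get_flat(m1))
  cfg1 <- run_config("classification", m1, sch, optimiser = "sgd", lr = 0.1,
                     secure_rng = FALSE, insecure_ok = TRUE, seed = 72,
                     class_weighting = FALSE)
  cfg2 <- run_config("classification", m2, sch, optimiser = "sgd", lr = 0.1,
                     secure_rng = FALSE, insecure_ok = TRUE, seed = 72,
                     class_weighting = FALSE)
  tr1 <- train_private(cfg1, data)
  tr2 <- train_nonprivate(cfg2, data)
  expect_lt(max(abs(params_get_flat(m1) - params_get_flat(m2))), 1e-6)
  expect_equal(tr2$final_privacy$epsilon, Inf)
})

test_that("nonprivate training reduces the loss on separable data", {
  set.seed(73)
  data <- toy_classification_data(60, s = 6, seed = 74)
  sch <- training_schedule(60, 10, epochs = 5, sigma = 1, clip_norm = 1)
  model <- dp_model(layer_flatten(), layer_dense(36, 1))
  cfg <- run_config("classification", model, sch, optimiser = "adam", lr = 0.02,
                    secure_rng = FALSE, insecure_ok = TRUE, seed = 75,
                    class_weighting = FALSE)
  tr <- train_nonprivate(cfg, data)
  first <- mean(head(tr$steps$loss, 3))
  last <- mean(tail(tr$steps$loss, 3))
  expect_lt(last, first)
})

test_that("benchmark harness reports repetitions, median and memory", {
  set.seed(76)
  model <- dp_model(layer_flatten(), layer_dense(64, 1))
  b <- benchmark_dp(model, c(8, 8, 1), B = 8, steps = 3, reps = 5)
  expect_length(b$times, 5)
  expect_equal(b$median_time, median(b$times))
  expect_gt(b$peak_memory_mb, 0)
})

test_that("trace serialises to JSON lines", {
  set.seed(77)
  data <- toy_classification_data(20, s = 6, seed = 78)
  sch <- training_schedule(20, 5, epochs = 1, sigma = 1, clip_norm = 1)
  model <- dp_model(layer_flatten(), layer_dense(36, 1))
  cfg <- run_config("classification", model, sch, secure_rng = FALSE,
                    insecure_ok = TRUE, seed = 79)
  tr <- train_private(cfg, data)
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_trace_jsonl(tr, f)
  lines <- readLines(f)
  expect_length(lines, tr$n_steps)
  rec <- jsonlite::fromJSON(lines[1])
  expect_named(rec, c("step", "loss", "eps", "lr"))
})

test_that("checkpoints round-trip the model with privacy metadata", {
  set.seed(80)
  m <- random_model("conv")
  sch <- training_schedule(40, 8, epochs = 1, sigma = 1, clip_norm = 1)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, f, privacy = audit(sch, "gdp-poisson"))
  ck <- load_checkpoint(f)
  expect_equal(params_get_flat(ck$model), params_get_flat(m))
  expect_true(ck$surgery$compliant)
  expect_s3_class(ck$privacy, "privacy_spent")
  b <- random_batch(2, seed = 81)
  expect_equal(nn_forward(ck$model, b$x)$out, nn_forward(m, b$x)$out)
})

test_that("yaml-config front end trains end to end", {
  d <- withr::local_tempdir()
  mf <- generate_classification(d, n_negative = 16, n_positive = 24,
                                size = 32, seed = 90)
  cfg_file <- file.path(d, "run.yaml")
  yaml::write_yaml(list(
    task = "classification",
    data = list(manifest = file.path(d, "manifest.csv")),
    model = list(kind = "tiny_cnn", channels = 2),
    schedule = list(batch_size = 8, epochs = 1, sigma = 1, clip_norm = 1),
    training = list(optimiser = "sgd", lr = 0.05, seed = 91, private = TRUE),
    privacy = list(secure_rng = FALSE, insecure_ok = TRUE)), cfg_file)
  tr <- run_from_config(cfg_file)
  expect_s3_class(tr, "run_trace")
  expect_gt(tr$n_steps, 0)
  expect_true(is.finite(tr$final_privacy$epsilon))
})
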