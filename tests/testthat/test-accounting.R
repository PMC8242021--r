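test_that("epoch-to-step conversion covers the data once per epoch", {
  expect_identical(steps_from_epochs(5184, 32, 5), 810L)
  expect_identical(steps_from_epochs(4389, 32, 20), 2760L)   # 20 * ceil(137.16)
  expect_identical(steps_from_epochs(10, 10, 0), 0L)
  expect_error(steps_from_epochs(0, 10, 1), "positive")
  expect_error(steps_from_epochs(10, 0, 1), "positive")
  expect_error(training_schedule(n = 10, batch_size = 20, epochs = 1, sigma = 1),
               "batch_size")
})

test_that("Poisson-subsampling mu matches direct formula evaluation", {
  s1 <- training_schedule(n = 1, batch_size = 1, total_steps = 1, sigma = 1)
  expect_equal(compute_mu_poisson(s1), sqrt(exp(1) - 1), tolerance = 1e-12)
  expect_equal(compute_mu_poisson(s1, steps = 0), 0)
  seg <- paper_segmentation_schedule()
  expect_equal(compute_mu_poisson(seg), 0.0354907, tolerance = 1e-5)
})

test_that("uniform-subsampling mu matches formula and vanishes as sigma grows", {
  s1 <- training_schedule(n = 1, batch_size = 1, total_steps = 1, sigma = 3)
  expect_equal(compute_mu_uniform(s1),
               sqrt(exp(1 / 9) * pnorm(0.5) + 3 * pnorm(-1 / 6) - 2),
               tolerance = 1e-12)
  expect_equal(compute_mu_uniform(s1, steps = 0), 0)
  shuge <- training_schedule(n = 1, batch_size = 1, total_steps = 1, sigma = 1e8)
  expect_lt(compute_mu_uniform(shuge), 1e-6)
})

test_that("GDP dual: closed form at eps = 0 and limiting behaviour", {
  expect_equal(delta_from_eps_mu(0, 1), 2 * pnorm(0.5) - 1, tolerance = 1e-12)
  expect_equal(delta_from_eps_mu(0, 0), 0)
  expect_equal(delta_from_eps_mu(500, 2), 0, tolerance = 1e-12)
  expect_equal(eps_from_delta_mu(0.5, 0), 0)
})

test_that("GDP dual is monotone: decreasing in eps, increasing in mu", {
  eps_grid <- seq(0, 4, by = 0.25)
  for (mu in c(0.05, 0.5, 1, 3)) {
    d <- delta_from_eps_mu(eps_grid, mu)
    expect_true(all(diff(d) < 0 | d[-1] == 0))  # strict until underflow
  }
  mu_grid <- seq(0.1, 5, by = 0.2)
  for (eps in c(0, 0.5, 2)) {
    d <- vapply(mu_grid, function(m) delta_from_eps_mu(eps, m), numeric(1))
    expect_true(all(diff(d) > 0))
  }
})

test_that("mu <-> (eps, delta) round-trips to 1e-5 over the working range", {
  for (mu in c(0.03, 0.2, 1, 2.5, 5)) {
    for (eps in c(0, 0.1, 1, 3, 5)) {
      d <- delta_from_eps_mu(eps, mu)
      if (d > 1e-300 && d < 1) {
        expect_equal(eps_from_delta_mu(d, mu), eps, tolerance = 1e-5)
      }
    }
  }
})

test_that("epsilon inversion honours the documented bound and round-trip", {
  eps <- eps_from_delta_mu(1e-5, 0.0355)
  expect_equal(eps, 0.11, tolerance = 0.01)
  d <- delta_from_eps_mu(eps, 0.0355)
  expect_lte(d, 1e-5 * (1 + 1e-9))
  expect_gte(d, 1e-5 * (1 - 1e-3))
})

test_that("sampled-Gaussian RDP: no-subsampling limit and brute-force oracle", {
  for (alpha in c(2L, 3L, 8L, 16L)) {
    for (sigma in c(0.8, 1, 5)) {
      curve <- rdp_sampled_gaussian(1, sigma, alpha)
      expect_equal(curve$eps_per_step, alpha / (2 * sigma^2), tolerance = 1e-12)
    }
  }
  expect_equal(rdp_sampled_gaussian(0, 2, 2:8)$eps_per_step, rep(0, 7))
  # brute-force binomial sum, plain arithmetic, small orders
  for (alpha in c(2L, 5L, 8L, 16L)) {
    for (q in c(0.01, 0.1, 0.5)) {
      got <- rdp_sampled_gaussian(q, 2, alpha)$eps_per_step
      expect_equal(got, rdp_bruteforce(q, 2, alpha), tolerance = 1e-10)
    }
  }
})

test_that("RDP-to-DP conversion picks the minimising order", {
  curve <- rdp_sampled_gaussian(0.01, 2, 2:64)
  # T = 0: only the conversion cost log(1/delta)/(alpha-1) remains
  conv0 <- eps_from_rdp(curve, 0, 1e-5)
  expect_equal(conv0$eps, log(1e5) / (64 - 1))
  expect_equal(conv0$best_order, 64L)
  # single order, hand-computable
  one <- structure(list(orders = 2L, eps_per_step = 1), class = "rdp_curve")
  expect_equal(eps_from_rdp(one, 1, exp(-1))$eps, 2)
  expect_error(eps_from_rdp(structure(list(orders = integer(0),
                                           eps_per_step = numeric(0)),
                                      class = "rdp_curve"), 1, 1e-5),
               "empty")
})

test_that("audit dispatches modes and obeys monotonicity in steps, q, sigma", {
  seg <- paper_segmentation_schedule()
  a <- audit(seg, "gdp-poisson")
  expect_s3_class(a, "privacy_spent")
  expect_equal(a$steps_accounted, 810L)
  expect_equal(audit(seg, "gdp-poisson", steps = 0)$epsilon, 0)
  # more steps, more epsilon
  eps_steps <- vapply(c(100, 400, 810), function(s)
    audit(seg, "gdp-poisson", steps = s)$epsilon, numeric(1))
  expect_true(all(diff(eps_steps) > 0))
  # larger sigma, strictly less epsilon
  seg2 <- training_schedule(5184, 32, epochs = 5, sigma = 10, clip_norm = 0.5)
  expect_lt(audit(seg2, "gdp-poisson")$epsilon, a$epsilon)
  # larger q (bigger batches), more epsilon
  seg3 <- training_schedule(5184, 64, total_steps = 810, sigma = 5, clip_norm = 0.5)
  expect_gt(audit(seg3, "gdp-poisson")$epsilon, a$epsilon)
  expect_error(audit(seg, "bogus"), "arg")
})

test_that("GDP accounting is tighter than RDP on both reproduction schedules", {
  for (sch in list(paper_classification_schedule(),
                   paper_segmentation_schedule())) {
    gdp <- audit(sch, "gdp-poisson")$epsilon
    rdp <- audit(sch, "rdp")$epsilon
    expect_lt(gdp, rdp)
  }
})
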