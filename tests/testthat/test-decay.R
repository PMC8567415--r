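# Decay engine: Q10, rate rescaling, fraction remaining, fitting,
# model selection, simulation, serialization.

test_that("q10 matches hand-evaluated values, decreases, and approaches 1.1", {
  expect_equal(q10(0), 13.1)
  expect_equal(q10(10), 2.8948234307, tolerance = 1e-9) # 1.1 + 12 e^-1.9
  expect_equal(q10(1e6), 1.1)

  temps <- seq(-10, 60, by = 0.5)
  vals <- q10(temps)
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > 1.1))
})

test_that("rate rescaling is the continuous Q10 integral", {
  expect_identical(rescale_rate(0.042, 15, 15), 0.042)

  # independent oracle: adaptive quadrature of ln Q10(T)/10
  oracle <- function(k, t1, t2) {
    k * exp(stats::integrate(function(x) log(q10(x)) / 10, t1, t2,
                             rel.tol = 1e-12)$value)
  }
  cases <- list(c(0.01, 14.9, 10.0), c(0.5, 5, 25), c(0.003, 20, 7.3))
  for (cs in cases) {
    expect_equal(rescale_rate(cs[1], cs[2], cs[3]),
                 oracle(cs[1], cs[2], cs[3]), tolerance = 1e-7)
  }
  # monotone increasing in target temperature
  targets <- seq(0, 30, by = 1)
  ks <- vapply(targets, function(Tt) rescale_rate(0.01, 14.9, Tt), 1)
  expect_true(all(diff(ks) > 0))
})

test_that("fraction remaining matches closed forms and is bounded and monotone", {
  single <- pool_set(c(1, 0), c(0.01, 0), reference_temp = 12)
  expect_equal(fraction_remaining(single, 0, 12), 1)
  expect_equal(fraction_remaining(single, 100, 12), exp(-1))

  two <- pool_set(c(0.1, 0.9), c(0.5, 0.001), reference_temp = 14.9)
  expect_equal(fraction_remaining(two, 100, 14.9), 0.814353676232,
               tolerance = 1e-10) # hand-evaluated closed form
  expect_equal(fraction_remaining(two, 0, 25), 1)

  tgrid <- seq(0, 500, by = 5)
  vals <- fraction_remaining(two, tgrid, 20)
  expect_true(all(vals >= 0 & vals <= 1))
  expect_true(all(diff(vals) <= 0))
  temps <- seq(0, 30, by = 1)
  byT <- vapply(temps, function(Tt) fraction_remaining(two, 100, Tt), 1)
  expect_true(all(diff(byT) <= 0))
  expect_error(fraction_remaining(two, -1), "non-negative")
})

test_that("pool_set enforces its invariants and canonical ordering", {
  expect_error(pool_set(c(0.5, 0.4), c(0.1, 0.01)), "sum to 1")
  expect_error(pool_set(c(1.2, -0.2), c(0.1, 0.01)), "non-negative")
  expect_error(pool_set(c(0.5, 0.5), c(-0.1, 0.01)), "non-negative")
  p <- pool_set(c(0.8, 0.2), c(0.001, 0.5)) # slow listed first on input
  expect_equal(p$rates, c(0.5, 0.001))      # reordered fast -> slow
  expect_equal(p$fractions, c(0.2, 0.8))
})

test_that("noiseless fits recover the generating pools to 1e-6 relative", {
  truth <- truth_pools_2()
  s <- simulate_series(truth, dense_times(25, 5), 20)
  fit <- fit_pools(s, 2)
  expect_equal(fit$pools$fractions, truth$fractions, tolerance = 1e-6)
  expect_equal(fit$pools$rates, truth$rates, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
})

test_that("fitting 2 pools to 1-pool data matches the truth at prediction level", {
  one <- pool_set(c(1, 0), c(0.3, 0), reference_temp = 20)
  s <- simulate_series(one, dense_times(25, 5), 20)
  fit <- fit_pools(s, 2)
  horizon <- seq(0, 20, by = 0.5)
  expect_equal(fraction_remaining(fit$pools, horizon, 20),
               fraction_remaining(one, horizon, 20), tolerance = 1e-6)
})

test_that("noisy fits recover fractions within 3 bootstrap standard deviations", {
  # 50 points over 8 years: a design on which the two-pool parameters are
  # well identified, so the residual bootstrap sd tracks the sampling sd
  # (on sparser designs it underestimates it and the check is uninformative)
  truth <- truth_pools_2()
  times <- dense_times(50, 8)
  s <- simulate_series(truth, times, 20, noise_sd = 0.01, seed = 7)
  fit <- fit_pools(s, 2)
  pred <- fraction_remaining(fit$pools, times, 20)
  resid <- s$values - pred
  set.seed(41)
  boot_f1 <- replicate(24, {
    ystar <- pmin(pmax(pred + sample(resid, replace = TRUE), 0), 1.05)
    bs <- suppressWarnings(decay_series(times, ystar, 20))
    fit_pools(bs, 2, n_starts = 2)$pools$fractions[1]
  })
  expect_lt(abs(fit$pools$fractions[1] - truth$fractions[1]),
            3 * stats::sd(boot_f1) + 1e-12)
})

test_that("model selection distinguishes clean 2- and 3-pool data", {
  s2 <- simulate_series(truth_pools_2(), dense_times(40, 8), 20)
  expect_equal(select_model(s2), 2L)
  s3 <- simulate_series(truth_pools_3(), dense_times(60, 10), 20)
  expect_equal(select_model(s3), 3L)
})

test_that("the 1-year inclusion filter and observation minimum are enforced", {
  short <- suppressWarnings(
    decay_series(seq(0, 0.5, length.out = 10),
                 exp(-0.5 * seq(0, 0.5, length.out = 10)), 20)
  )
  expect_error(fit_pools(short, 2), "1 year")
  few <- decay_series(c(0, 1, 2), c(1, 0.8, 0.7), 20)
  expect_error(fit_pools(few, 2), "observations")
})

test_that("simulation is exact when noiseless, deterministic under a seed, and calibrated in noise", {
  truth <- truth_pools_2()
  times <- dense_times(50, 5)
  clean <- simulate_series(truth, times, 20)
  expect_identical(clean$values, fraction_remaining(truth, times, 20))

  a <- simulate_series(truth, times, 20, noise_sd = 0.01, seed = 99)
  b <- simulate_series(truth, times, 20, noise_sd = 0.01, seed = 99)
  expect_identical(a$values, b$values)

  resid_sd <- stats::sd(a$values - clean$values)
  expect_gt(resid_sd, 0.006)
  expect_lt(resid_sd, 0.014)
})

test_that("series and pool sets round-trip through their file formats", {
  s <- simulate_series(truth_pools_2(), dense_times(12, 3), 22,
                       noise_sd = 0.005, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_decay_series(s, f)
  s2 <- read_decay_series(f)
  expect_equal(s2$times, s$times)
  expect_equal(s2$values, s$values)
  expect_equal(s2$incubation_temp, 22)

  p <- truth_pools_2()
  g <- tempfile(fileext = ".json")
  write_pool_set(p, g)
  p2 <- read_pool_set(g)
  expect_equal(p2$fractions, p$fractions)
  expect_equal(p2$rates, p$rates)
  expect_equal(p2$reference_temp, p$reference_temp)
})

test_that("decay_series validates and flags overshoot", {
  expect_error(decay_series(c(0, 1, 1), c(1, 0.9, 0.8), 20), "increasing")
  expect_error(decay_series(c(0, 1, 2), c(1, 1.2, 0.8), 20), "1.05")
  expect_warning(decay_series(c(0, 1, 2), c(1, 1.02, 0.8), 20), "overshoot")
})

test_that("class-surface calibration reproduces printed cells within tolerance", {
  med <- calibrate_class_pools("medium")
  expect_equal(fraction_remaining(med, 100, 10.0), 0.79,
               tolerance = max(0.03, 0.026) / 0.79)
  low <- calibrate_class_pools("low")
  expect_equal(fraction_remaining(low, 1000, 14.9), 0.084,
               tolerance = max(0.03, 0.048) / 0.084)
  for (cls in c("low", "medium", "high")) {
    p <- calibrate_class_pools(cls)
    expect_equal(fraction_remaining(p, 0, 14.9), 1)
    expect_lte(attr(p, "calibration")$max_tol_ratio, 1)
  }
  expect_error(calibrate_class_pools("medium", grid = permanence_table()[1:5, ]),
               "21")
})
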