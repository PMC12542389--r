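test_that("weibull_spec and censoring_scheme validate their parameters", {
  expect_error(weibull_spec(alpha = 0), "positive")
  expect_error(weibull_spec(predictors = c("normal", "gamma"),
                            beta = c(1, 1)), "normal")
  expect_error(censoring_scheme("zero", 1), "\\[0, 1\\)")
  expect_error(censoring_scheme("memoryless", -1), "positive")
  expect_equal(censoring_scheme("none")$kind, "none")
})

test_that("draw_predictors has the stated marginals and is reproducible", {
  Z <- draw_predictors(5, seed = 1)
  expect_equal(dim(Z), c(5L, 4L))
  expect_true(all(Z[, 3:4] %in% c(0, 1)))
  expect_identical(Z, draw_predictors(5, seed = 1))

  Zb <- draw_predictors(100000, seed = 2)
  expect_lt(max(abs(colMeans(Zb) - c(0, 0, 0.5, 0.5))), 0.02)
})

test_that("draw_event_times follows the Weibull model via inverse transform", {
  # alpha = 1, beta = 0: X ~ Exp(1)
  spec <- weibull_spec(alpha = 1, beta = 0, predictors = "normal")
  Z <- draw_predictors(200000, spec, seed = 3)
  X <- draw_event_times(spec, Z, seed = 4)
  expect_lt(abs(mean(X) - 1), 0.02)

  # constant sigma = 2: median is 2 log 2
  spec2 <- weibull_spec(alpha = 1, beta = log(2), predictors = "bernoulli")
  X2 <- draw_event_times(spec2, matrix(1, 200000, 1), seed = 5)
  expect_lt(abs(stats::median(X2) - 2 * log(2)), 0.03)

  # conditional PIT: S(X | z) uniform for a fixed predictor value
  tr <- weibull_spec()
  z <- c(0.7, -0.3, 1, 0)
  Zf <- matrix(rep(z, each = 5000), nrow = 5000)
  Xf <- draw_event_times(tr, Zf, seed = 6)
  u <- exp(-(Xf / exp(sum(tr$beta * z)))^tr$alpha)
  expect_gt(stats::ks.test(u, "punif")$p.value, 0.01)
})

test_that("calibrate_censoring hits the target and matches the closed-form rate", {
  # zero scheme: the parameter is the target itself
  z <- calibrate_censoring("zero", q = 0.2)
  expect_equal(z$param, 0.2)
  # q = 0 degenerates to no censoring
  expect_equal(calibrate_censoring("memoryless", q = 0)$kind, "none")
  expect_error(calibrate_censoring("memoryless", q = 1), "\\[0, 1\\)")

  # X ~ Exp(1): P(C < X) = c / (c + 1), so q = 0.2 gives c = 0.25
  spec <- weibull_spec(alpha = 1, beta = 0, predictors = "normal")
  sc <- calibrate_censoring("memoryless", spec, q = 0.2)
  expect_lt(abs(sc$param - 0.25), 0.01)
  expect_lte(abs(sc$param / (sc$param + 1) - 0.2), 0.002)
  expect_lte(abs(attr(sc, "achieved_q") - 0.2), 0.002)
})

test_that("apply_censoring realizes the scheme definitions", {
  set.seed(8)
  spec <- weibull_spec(alpha = 1, beta = 0, predictors = "normal")
  X <- draw_event_times(spec, draw_predictors(100000, spec))

  # zero censoring: T = 0, delta = 0 with the stated probability
  z <- apply_censoring(X, censoring_scheme("zero", 0.3))
  expect_lt(abs(mean(z$event == 0) - 0.3), 0.005)
  expect_true(all(z$time[z$event == 0] == 0))

  # no censoring: everything observed
  nc <- apply_censoring(X, censoring_scheme("none"))
  expect_true(all(nc$event == 1))
  expect_identical(nc$time, X)

  # memoryless at the closed-form rate for q = 0.2
  ml <- apply_censoring(X, censoring_scheme("memoryless", 0.25))
  expect_lt(abs(mean(ml$event == 0) - 0.2), 0.005)
  expect_true(all(ml$time <= X))
})

test_that("misspecify perturbs shape, scale, or removes a predictor", {
  tr <- weibull_spec()
  expect_equal(misspecify(tr, "shape", 1), tr)
  expect_equal(misspecify(tr, "shape", 0.85)$alpha, 0.85)
  expect_equal(misspecify(tr, "scale", 0.5)$beta, 0.5 * tr$beta)
  expect_equal(misspecify(tr, "missing", 1)$beta,
               c(0, log(0.5), log(2), log(1.5)))
  expect_error(misspecify(tr, "missing", 7), "index")
  expect_error(misspecify(tr, "shape", -1), "positive")
})

test_that("simulate_dataset is reproducible and attaches model predictions", {
  sc <- cached_scheme("memoryless", 0.2)
  d1 <- simulate_dataset(50, scheme = sc, seed = 11)
  d2 <- simulate_dataset(50, scheme = sc, seed = 11)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 50)
  expect_true(all(c("id", "time", "event", "z1", "z4", "shat") %in% names(d1)))

  # shat is the model survival curve at the observed time
  tr <- attr(d1, "truth")
  sigma <- exp(as.matrix(d1[, paste0("z", 1:4)]) %*% tr$beta)
  expect_equal(d1$shat, drop(exp(-(d1$time / sigma)^tr$alpha)))

  # censoring fraction near the calibrated target over a large draw
  db <- simulate_dataset(100000, scheme = sc, seed = 12)
  expect_lt(abs(attr(db, "cens_fraction") - 0.2), 0.01)
})
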