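test_that("empirical_support is the largest clamped residual", {
  s <- make_pit_sample(data.frame(time = 1:3, event = c(1, 0, 1),
                                  shat = c(0.8, 0.3, 0.6)))
  expect_equal(empirical_support(s), 0.7)
  s1 <- make_pit_sample(data.frame(time = 1, event = 0, shat = 0))
  expect_equal(empirical_support(s1), 1 - 1e-12)
  s0 <- make_pit_sample(data.frame(time = 1:2, event = c(0, 0), shat = c(1, 1)))
  expect_error(empirical_support(s0), "degenerate support")
})

test_that("the pooled ECDF is right-continuous with the '<=' convention", {
  s <- make_pit_sample(data.frame(time = 1:2, event = c(1, 0),
                                  shat = c(0.75, 0.5)))   # residuals 0.25, 0.5
  H <- ecdf_h(s)
  expect_equal(H(0.1), 0)
  expect_equal(H(0.3), 0.5)
  expect_equal(H(0.5), 1)
  expect_equal(H(0.25 - 1e-9), 0)
  expect_equal(H(0.25), 0.5)
})

test_that("gof_partition validates edges and applies the half-open convention downstream", {
  p <- gof_partition(K = 10, a = 0.95)
  expect_equal(p$edges[1], 0)
  expect_equal(p$edges[11], 0.95)
  expect_equal(p$K, 10L)
  expect_error(gof_partition(edges = c(0.1, 0.5, 1)), "start at 0")
  expect_error(gof_partition(edges = c(0, 0.5, 0.5, 1)), "strictly increasing")
  expect_error(gof_partition(K = 0), "positive integer")
})

test_that("expected counts match the closed form and the quadrature oracle on worked examples", {
  # single uncensored residual at 0.5, one interval [0, 0.5]:
  # integral of 1/(1-t) from 0 to 0.5 is log 2
  s1 <- make_pit_sample(data.frame(time = 1, event = 1, shat = 0.5))
  p1 <- gof_partition(K = 1, a = 0.5)
  expect_equal(expected_counts(s1, p1), log(2), tolerance = 1e-12)
  expect_equal(expected_counts(s1, p1),
               quad_expected_counts(s1$residuals, p1$edges), tolerance = 1e-8)

  # two subjects, residuals 0.25 (event) and 0.5 (censored):
  # 2 * (int_0^.25 1/(1-t) + int_.25^.5 (1/2)/(1-t)) = 2 (log(4/3) + log(1.5)/2)
  s2 <- make_pit_sample(data.frame(time = 1:2, event = c(1, 0),
                                   shat = c(0.75, 0.5)))
  expect_equal(expected_counts(s2, gof_partition(K = 1, a = 0.5)),
               2 * (log(4 / 3) + 0.5 * log(1.5)), tolerance = 1e-12)

  # no mass above the largest residual: E_k = 0 there
  E <- expected_counts(s2, gof_partition(edges = c(0, 0.5, 0.8)))
  expect_equal(E[2], 0)
  expect_error(expected_counts(s2, gof_partition(K = 2, a = 0.3)),
               "partition/support mismatch")
})

test_that("closed-form expected counts agree with quadrature and are ECDF-convention insensitive", {
  set.seed(11)
  for (b in 1:30) {
    s <- random_pit_sample()
    K <- sample(1:8, 1)
    p <- gof_partition(K = K, a = empirical_support(s))
    E <- expected_counts(s, p)
    expect_true(all(E >= 0))
    Q <- quad_expected_counts(s$residuals, p$edges)
    expect_equal(E, Q, tolerance = 1e-8)
    # "<" vs "<=" ECDF conventions differ on a null set only
    expect_equal(Q, quad_expected_counts(s$residuals, p$edges, strict = TRUE),
                 tolerance = 1e-8)
  }
})

test_that("observed counts follow the half-open binning of event residuals", {
  s <- make_pit_sample(data.frame(time = 1:4, event = c(1, 1, 1, 0),
                                  shat = 1 - c(0.05, 0.15, 0.95, 0.5)))
  p <- gof_partition(K = 10, a = 0.95)
  N <- observed_counts(s, p)
  expect_equal(sum(N), 3)
  expect_true(all(N %in% c(0L, 1L)))
  # residual exactly on an interior edge belongs to the interval to its right
  s2 <- make_pit_sample(data.frame(time = 1, event = 1, shat = 0.5))
  expect_equal(observed_counts(s2, gof_partition(K = 10, a = 1)),
               c(rep(0, 5), 1, rep(0, 4)))
  # no events -> all zeros
  sc <- make_pit_sample(data.frame(time = 1, event = 0, shat = 0.5))
  expect_equal(observed_counts(sc, gof_partition(K = 4, a = 0.5)), rep(0L, 4))
})

test_that("a_calibration_test reproduces the frozen single-subject case and the identity case", {
  # n = 1, uncensored residual 0.5, K = 1: N = 1, E = log 2
  s <- make_pit_sample(data.frame(time = 1, event = 1, shat = 0.5))
  r <- a_calibration_test(s, K = 1)
  stat <- (1 - log(2))^2 / log(2)
  expect_equal(unname(r$statistic), stat, tolerance = 1e-12)
  expect_equal(unname(r$parameter), 1)
  expect_equal(r$p.value, stats::pchisq(stat, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(r$p.value, 0.7124499, tolerance = 1e-6)

  # residual 1 - e^{-1} makes E_1 = -log(1 - r) = 1 = N_1 exactly
  si <- make_pit_sample(data.frame(time = 1, event = 1, shat = exp(-1)))
  ri <- a_calibration_test(si, K = 1)
  expect_equal(unname(ri$statistic), 0, tolerance = 1e-12)
  expect_equal(ri$p.value, 1)
})

test_that("a_calibration_test statistic is recomputable from its stored vectors", {
  set.seed(3)
  s <- random_pit_sample(40)
  r <- a_calibration_test(s, K = 5)
  keep <- r$expected > 1e-10
  expect_equal(unname(r$statistic),
               sum((r$observed[keep] - r$expected[keep])^2 / r$expected[keep]))
  expect_equal(r$p.value,
               stats::pchisq(unname(r$statistic), unname(r$parameter),
                             lower.tail = FALSE))
  expect_equal(sum(r$observed), sum(s$events))
})

test_that("intervals outside the effective support are dropped with reduced df", {
  set.seed(5)
  # all residuals below 0.5 but support overridden to 1: upper intervals empty
  shat <- 1 - stats::runif(30, 0.05, 0.45)
  s <- make_pit_sample(data.frame(time = 1:30, event = 1, shat = shat))
  expect_warning(r <- a_calibration_test(s, K = 10, support = 1), "dropped")
  expect_lt(unname(r$parameter), 10)
  expect_equal(unname(r$parameter), sum(r$expected > 1e-10))
})

test_that("a_calibration_test rejects undersized samples and bad support", {
  s <- make_pit_sample(data.frame(time = 1:3, event = 1, shat = c(0.2, 0.5, 0.8)))
  expect_error(a_calibration_test(s, K = 10), "too few observations")
  expect_error(a_calibration_test(s, K = 2, support = 1.5), "support")
})
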