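# Shared simulation scaffolding for the tests.

# Calibrating a censoring scheme runs a 1e6-draw Monte-Carlo root-finder;
# memoize per (kind, q) so test files can share calibrated schemes.
.scheme_cache <- new.env(parent = emptyenv())
cached_scheme <- function(kind, q, truth = weibull_spec()) {
  key <- sprintf("%s|%g", kind, q)
  if (is.null(.scheme_cache[[key]])) {
    .scheme_cache[[key]] <- calibrate_censoring(kind, truth, q)
  }
  .scheme_cache[[key]]
}

# Covariate-dependent censoring: both the event time and the censoring time
# depend on Z (conditionally independent given Z).  Used to exercise the
# independence of the transformed times S(X|Z) and S(C|Z); deliberately not
# part of the public simulator.
sim_dependent_censoring <- function(n, gamma = c(0.5, -0.5, 0.3, 0.2)) {
  tr <- weibull_spec()
  Z <- draw_predictors(n, tr)
  sigma <- exp(drop(Z %*% tr$beta))
  X <- draw_event_times(tr, Z)
  C <- stats::rexp(n, rate = exp(drop(Z %*% gamma)))
  list(U = exp(-(X / sigma)^tr$alpha),   # S(X | Z)
       V = exp(-(C / sigma)^tr$alpha))   # S(C | Z)
}

# Random censored PIT sample (direct residual construction, no model in the
# loop) for conservation/oracle sweeps.
random_pit_sample <- function(n = NULL) {
  if (is.null(n)) n <- sample(5:50, 1)
  shat <- pmin(pmax(stats::runif(n)^stats::runif(1, 0.5, 2), 1e-6), 1)
  events <- stats::rbinom(n, 1, 0.7)
  make_pit_sample(data.frame(time = seq_len(n), event = events, shat = shat))
}
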