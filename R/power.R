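# Monte-Carlo engine estimating rejection rates of A- and D-calibration over
# the (scheme x q x lambda x n x mode) grid of the power study.
#
# Per-repetition seeds are derived deterministically from a master seed, a
# cell key and the repetition index, so every cell is independently
# reproducible and results do not depend on the order cells are run in.

# 32-bit-safe multiplicative string hash; all arithmetic kept below 2^31.
.hash_key <- function(key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  h
}

.derive_seed <- function(master, cell_hash, i) {
  as.integer((cell_hash + (master %% 2147483647) * 10007 + i * 97) %% 2147483647)
}

.cell_key <- function(scheme, q, mode, lambda, n) {
  sprintf("%s|%g|%s|%g|%d", scheme, q, mode, lambda, as.integer(n))
}

#' Estimate rejection rates for one simulation cell
#'
#' Repeats \code{m} times: simulate a validation dataset of size \code{n}
#' from the true model under the censoring scheme, evaluate the (possibly
#' misspecified) predictive model at the observed times, and run both
#' calibration tests, recording rejections at the given significance levels.
#' At \eqn{\lambda = 1} (shape or scale mode) the null hypothesis holds and
#' the rejection rate estimates the actual type-I error; otherwise it
#' estimates power.
#'
#' @param truth the true \code{\link{weibull_spec}}.
#' @param scheme scheme kind (\code{"memoryless"}, \code{"uniform"},
#'   \code{"zero"} or \code{"none"}).
#' @param q target censoring fraction (ignored for \code{"none"}).
#' @param mode misspecification mode (\code{"shape"}, \code{"scale"},
#'   \code{"missing"}).
#' @param lambda misspecification parameter (or coefficient index for
#'   \code{"missing"}); 1 recovers the truth in shape/scale modes.
#' @param n validation dataset size per repetition.
#' @param m number of Monte-Carlo repetitions.
#' @param level nominal significance level for both tests.
#' @param level_A,level_D per-test overrides of \code{level} (used by
#'   \code{\link{adjusted_level_comparison}}).
#' @param K number of partitioning intervals.
#' @param seed master seed.
#' @param scheme_obj optional pre-calibrated \code{\link{censoring_scheme}},
#'   bypassing \code{\link{calibrate_censoring}} (useful when many cells
#'   share a scheme).
#' @return a one-row data frame (a "power cell") with columns \code{scheme},
#'   \code{q}, \code{mode}, \code{lambda}, \code{n}, \code{m}, \code{level_A},
#'   \code{level_D}, \code{power_A}, \code{se_A}, \code{power_D}, \code{se_D},
#'   where \code{se = sqrt(p (1 - p) / m)} is the binomial standard error.
#' @examples
#' run_cell(n = 100, m = 20, q = 0, scheme = "none", seed = 1)
#' @export
run_cell <- function(truth = weibull_spec(), scheme = "memoryless", q = 0.2,
                     mode = "shape", lambda = 1, n = 1000, m = 2000,
                     level = 0.05, level_A = level, level_D = level,
                     K = 10, seed = 1, scheme_obj = NULL) {
  stopifnot(m >= 1, level_A >= 0, level_A < 1, level_D >= 0, level_D < 1)
  if (is.null(scheme_obj)) {
    scheme_obj <- if (scheme == "none" || q == 0) {
      censoring_scheme("none")
    } else {
      calibrate_censoring(scheme, truth, q)
    }
  }
  if (scheme_obj$kind == "none") q <- 0
  model <- if (mode %in% c("shape", "scale") && lambda == 1) truth
           else misspecify(truth, mode, lambda)
  cell_hash <- .hash_key(.cell_key(scheme, q, mode, lambda, n))
  rej_A <- 0L
  rej_D <- 0L
  for (i in seq_len(m)) {
    set.seed(.derive_seed(seed, cell_hash, i))
    Z <- draw_predictors(n, truth)
    X <- draw_event_times(truth, Z)
    cns <- apply_censoring(X, scheme_obj)
    sigma <- exp(drop(Z %*% model$beta))
    shat <- exp(-(cns$time / sigma)^model$alpha)
    r <- pmin(1 - shat, 1 - .resid_eps)
    core_a <- .acal_core(r, cns$event, K = K)
    keep <- core_a$expected > 1e-10
    stat_a <- sum((core_a$observed[keep] - core_a$expected[keep])^2 /
                    core_a$expected[keep])
    p_A <- stats::pchisq(stat_a, df = sum(keep), lower.tail = FALSE)
    core_d <- .dcal_core(shat, cns$event, K = K)
    stat_d <- sum((core_d$observed - core_d$expected)^2 / core_d$expected)
    p_D <- stats::pchisq(stat_d, df = K - 1, lower.tail = FALSE)
    rej_A <- rej_A + (p_A < level_A)
    rej_D <- rej_D + (p_D < level_D)
  }
  pA <- rej_A / m
  pD <- rej_D / m
  data.frame(scheme = scheme, q = q, mode = mode, lambda = lambda,
             n = n, m = m, level_A = level_A, level_D = level_D,
             power_A = pA, se_A = sqrt(pA * (1 - pA) / m),
             power_D = pD, se_D = sqrt(pD * (1 - pD) / m))
}

#' Run a grid of simulation cells
#'
#' Expands the supplied factor levels into the full grid and runs
#' \code{\link{run_cell}} on each combination.  Censoring schemes are
#' calibrated once per (scheme, q) pair and shared across cells.
#'
#' @param truth the true \code{\link{weibull_spec}}.
#' @param schemes,qs,modes,lambdas,ns vectors of factor levels.
#' @param m repetitions per cell.
#' @param level nominal significance level.
#' @param K number of partitioning intervals.
#' @param seed master seed (each cell derives its own repetition seeds, so
#'   the result is independent of cell execution order).
#' @return a long-format data frame, one row per cell, with the columns of
#'   \code{\link{run_cell}}.
#' @examples
#' run_grid(ns = 100, m = 10, lambdas = c(0.8, 1), qs = 0.2, seed = 1)
#' @export
run_grid <- function(truth = weibull_spec(), schemes = "memoryless",
                     qs = 0.2, modes = "shape", lambdas = 1, ns = 1000,
                     m = 2000, level = 0.05, K = 10, seed = 1) {
  grid <- expand.grid(scheme = schemes, q = qs, mode = modes,
                      lambda = lambdas, n = ns,
                      stringsAsFactors = FALSE)
  if (nrow(grid) == 0) stop("empty grid")
  cache <- new.env(parent = emptyenv())
  get_scheme <- function(kind, q) {
    key <- sprintf("%s|%g", kind, q)
    if (is.null(cache[[key]])) {
      cache[[key]] <- if (kind == "none" || q == 0) censoring_scheme("none")
                      else calibrate_censoring(kind, truth, q)
    }
    cache[[key]]
  }
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    run_cell(truth, scheme = g$scheme, q = g$q, mode = g$mode,
             lambda = g$lambda, n = g$n, m = m, level = level, K = K,
             seed = seed, scheme_obj = get_scheme(g$scheme, g$q))
  })
  do.call(rbind, rows)
}

#' Adjusted-level fairness comparison
#'
#' Runs the A-calibration test at a reduced significance level -- typically
#' the measured actual type-I error of D-calibration in the same cell -- and
#' D-calibration at the nominal level, so the two tests are compared at a
#' matched actual level.
#'
#' @inheritParams run_cell
#' @param reference_level significance level applied to A-calibration.
#' @return a power-cell data frame as in \code{\link{run_cell}}.
#' @export
adjusted_level_comparison <- function(truth = weibull_spec(),
                                      scheme = "memoryless", q = 0.2,
                                      mode = "shape", lambda = 1, n = 1000,
                                      m = 2000, level = 0.05,
                                      reference_level = level, K = 10,
                                      seed = 1, scheme_obj = NULL) {
  stopifnot(reference_level >= 0, reference_level < 1)
  run_cell(truth, scheme = scheme, q = q, mode = mode, lambda = lambda,
           n = n, m = m, level = level, level_A = reference_level,
           level_D = level, K = K, seed = seed, scheme_obj = scheme_obj)
}
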