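# A-calibration: Akritas-type Pearson goodness-of-fit test for right-censored
# PIT residuals.
#
# With U_i = S(X_i | Z_i) and V_i = S(C_i | Z_i) independent (conditional
# independence of X and C given Z is enough), the residuals r_i = 1 - Shat,
# delta_i form a right-censored i.i.d. sample.  Observed counts N_k are the
# uncensored residuals falling in each interval; expected counts under the
# null are
#   E_k = n * int_{I_k} (1 - Hhat(t)) / (1 - t) dt,
# where Hhat is the ECDF of all residuals and 1/(1 - t) is the null density
# adjustment coming from the estimator 1 - Ghat = (1 - Hhat) / (1 - F0) of the
# censoring survival function.  The statistic sum (N_k - E_k)^2 / E_k is
# compared to a chi-square distribution with as many degrees of freedom as
# intervals entering the sum.

#' Empirical support of the transformed sample
#'
#' Upper end \eqn{a} of the support of the distribution of the censored
#' residuals \eqn{\min(U_i, V_i)}.  When the censoring times are bounded the
#' support of \eqn{H} is \eqn{[0, a]} with \eqn{a < 1}; the pragmatic choice
#' implemented here is the empirical one,
#' \eqn{a = \sup\{t \in [0,1] : 1 - \hat H(t) > 0\}}, i.e. the largest
#' (clamped) residual.  When censoring is known to be unbounded, callers may
#' override with \eqn{a = 1} in \code{\link{a_calibration_test}}.
#'
#' @param sample a \code{\link{make_pit_sample}} object.
#' @return the support bound \eqn{a \in (0, 1]}.
#' @export
empirical_support <- function(sample) {
  stopifnot(inherits(sample, "pit_sample"))
  a <- max(sample$residuals)
  if (a <= 0) stop("degenerate support: all residuals are zero")
  a
}

#' Empirical distribution function of the PIT residuals
#'
#' Right-continuous ECDF \eqn{\hat H(t) = n^{-1}\#\{i : r_i \le t\}} of the
#' pooled (event and censored) residuals.
#'
#' @param sample a \code{\link{make_pit_sample}} object.
#' @return a step function as returned by \code{\link[stats]{ecdf}}.
#' @export
ecdf_h <- function(sample) {
  stopifnot(inherits(sample, "pit_sample"))
  stats::ecdf(sample$residuals)
}

#' Partition of the residual scale
#'
#' Builds the interval partition \eqn{\{I_k\}_{k=1,\dots,K}} of \eqn{[0, a]}
#' used by both tests: half-open intervals
#' \eqn{I_k = [e_{k-1}, e_k)} for \eqn{k < K} and a closed last interval.
#' Equal-width intervals by default; arbitrary edge vectors are accepted.
#'
#' @param K number of intervals (ignored when \code{edges} is supplied).
#' @param a upper end of the partitioned range, in \eqn{(0, 1]}.
#' @param edges optional vector of \eqn{K + 1} strictly increasing edges
#'   starting at 0.
#' @return an object of class \code{"gof_partition"} with elements
#'   \code{edges}, \code{K} and \code{a}.
#' @export
gof_partition <- function(K = 10, a = 1, edges = NULL) {
  if (is.null(edges)) {
    if (!(is.numeric(K) && length(K) == 1 && K >= 1 && K == floor(K))) {
      stop("'K' must be a positive integer")
    }
    if (!(is.numeric(a) && length(a) == 1 && a > 0 && a <= 1)) {
      stop("'a' must lie in (0, 1]")
    }
    edges <- seq(0, a, length.out = K + 1)
  } else {
    if (edges[1] != 0) stop("partition must start at 0")
    if (any(diff(edges) <= 0)) stop("partition edges must be strictly increasing")
    if (edges[length(edges)] > 1) stop("partition must end at a <= 1")
    K <- length(edges) - 1L
    a <- edges[length(edges)]
  }
  structure(list(edges = edges, K = as.integer(K), a = a),
            class = "gof_partition")
}

# Cumulative integral int_0^x (1 - Hhat(t)) / (1 - t) dt in closed form.
# 1 - Hhat is piecewise constant with value (n - j)/n on (s_(j), s_(j+1));
# each constant piece c on (u, v] contributes c * (log(1 - u) - log(1 - v)).
# Returns a function evaluating the integral at a vector of points in
# [0, max(r)].
.cum_null_integral <- function(r) {
  n <- length(r)
  s <- sort(r)
  lo <- c(0, s[-n])
  seg <- ((n - seq_len(n) + 1) / n) * (log1p(-lo) - log1p(-s))
  cum <- c(0, cumsum(seg))
  knots <- c(0, s)
  function(x) {
    j <- findInterval(x, s)            # number of residuals <= x
    cum[j + 1] + ((n - j) / n) * (log1p(-knots[j + 1]) - log1p(-x))
  }
}

#' Expected uncensored counts under the null
#'
#' Closed-form evaluation of
#' \eqn{E_k = n \int_{I_k} (1 - \hat H(t))/(1 - t)\, dt}: on every maximal
#' subinterval \eqn{(u, v]} of \eqn{I_k} where \eqn{1 - \hat H} equals a
#' constant \eqn{c}, the contribution is
#' \eqn{n\,c\,[\log(1 - u) - \log(1 - v)]}.
#'
#' @param sample a \code{\link{make_pit_sample}} object.
#' @param partition a \code{\link{gof_partition}} covering \eqn{[0, a]} with
#'   \eqn{a} at most the empirical support (or 1 under the unbounded-censoring
#'   override).
#' @return numeric vector \eqn{(E_1, \dots, E_K)}, all nonnegative.
#' @export
expected_counts <- function(sample, partition) {
  stopifnot(inherits(sample, "pit_sample"), inherits(partition, "gof_partition"))
  r <- sample$residuals
  a_emp <- max(r)
  if (partition$a < a_emp - 1e-9 && partition$a < 1) {
    stop("partition/support mismatch: partition ends below the empirical support")
  }
  cumint <- .cum_null_integral(r)
  # beyond the largest residual 1 - Hhat is identically zero
  edges <- pmin(partition$edges, a_emp)
  sample$n * diff(cumint(edges))
}

#' Observed uncensored counts
#'
#' \eqn{N_k}: number of uncensored subjects whose residual
#' \eqn{1 - \hat S(t_i \mid z_i)} falls in \eqn{I_k}.  Interior edges follow
#' the half-open convention (a residual on an edge belongs to the interval to
#' its right); the last interval is closed.
#'
#' @inheritParams expected_counts
#' @return integer vector \eqn{(N_1, \dots, N_K)}.
#' @export
observed_counts <- function(sample, partition) {
  stopifnot(inherits(sample, "pit_sample"), inherits(partition, "gof_partition"))
  r <- sample$residuals[sample$events == 1L]
  idx <- findInterval(r, partition$edges, rightmost.closed = TRUE)
  tabulate(idx[idx >= 1L & idx <= partition$K], nbins = partition$K)
}

# Shared chi-square assembly for both tests.  Intervals with expected count
# below drop_tol are removed from the sum (with a warning) and the degrees of
# freedom reduced accordingly: empty tail intervals outside the effective
# support would otherwise contribute 0/0.
.gof_chisq <- function(observed, expected, df, method, K, a, edges,
                       drop_tol = 1e-10, data.name = "PIT sample") {
  keep <- expected > drop_tol
  if (!all(keep)) {
    warning(sprintf("%d interval(s) with expected count < %g dropped; df reduced",
                    sum(!keep), drop_tol))
    df <- df - sum(!keep)
  }
  stat <- sum((observed[keep] - expected[keep])^2 / expected[keep])
  structure(
    list(statistic = c(`X-squared` = stat),
         parameter = c(df = df),
         p.value = stats::pchisq(stat, df = df, lower.tail = FALSE),
         observed = observed,
         expected = expected,
         K = K, a = a, edges = edges,
         method = method,
         data.name = data.name),
    class = c("gof_test", "htest")
  )
}

# Fast path used by the Monte-Carlo engine: residuals/events straight in,
# no object construction.
.acal_core <- function(r, events, K = 10, a = NULL, edges = NULL,
                       drop_tol = 1e-10) {
  n <- length(r)
  if (is.null(a)) {
    a <- max(r)
    if (a <= 0) stop("degenerate support: all residuals are zero")
  }
  if (is.null(edges)) edges <- seq(0, a, length.out = K + 1)
  cumint <- .cum_null_integral(r)
  a_emp <- max(r)
  expected <- n * diff(cumint(pmin(edges, a_emp)))
  re <- r[events == 1L]
  idx <- findInterval(re, edges, rightmost.closed = TRUE)
  observed <- tabulate(idx[idx >= 1L & idx <= K], nbins = K)
  list(observed = observed, expected = expected, edges = edges, a = a)
}

#' A-calibration test
#'
#' Akritas-type Pearson goodness-of-fit test for calibration of a survival
#' prediction model under random right-censoring.  The residuals
#' \eqn{1 - \hat S(t_i \mid z_i)} form a right-censored sample that is
#' standard uniform under the null hypothesis that the predictive model is
#' the true model.  The statistic
#' \eqn{\sum_k (N_k - E_k)^2 / E_k} contrasts observed uncensored counts with
#' expected counts computed from a nonparametric estimate of the censoring
#' distribution, and follows a chi-square distribution with \eqn{K} degrees
#' of freedom under the null (one df per interval entering the sum).
#'
#' @param sample a \code{\link{make_pit_sample}} object.
#' @param K number of partitioning intervals (default 10, equal-width).
#' @param support optional override of the support bound \eqn{a}; use 1 when
#'   the censoring times are known to be unbounded.  Defaults to the
#'   empirical support (\code{\link{empirical_support}}).
#' @param edges optional custom partition edges (overrides \code{K} and
#'   \code{support}).
#' @param drop_tol intervals with expected count below this are dropped from
#'   the sum and the degrees of freedom reduced, with a warning.
#' @return an object of classes \code{"gof_test"} and \code{"htest"} with the
#'   statistic, degrees of freedom, p-value and the per-interval
#'   observed/expected vectors.
#' @examples
#' set.seed(1)
#' ds <- simulate_dataset(200, scheme = censoring_scheme("none"))
#' a_calibration_test(make_pit_sample(ds))
#' @seealso \code{\link{d_calibration_test}} for the imputation-based
#'   comparator.
#' @export
a_calibration_test <- function(sample, K = 10, support = NULL, edges = NULL,
                               drop_tol = 1e-10) {
  stopifnot(inherits(sample, "pit_sample"))
  if (is.null(edges)) {
    if (!(is.numeric(K) && length(K) == 1 && K >= 1 && K == floor(K))) {
      stop("'K' must be a positive integer")
    }
    if (sample$n < K) stop("too few observations for K intervals")
    a <- if (is.null(support)) empirical_support(sample) else support
    if (!(a > 0 && a <= 1)) stop("'support' must lie in (0, 1]")
  } else {
    part <- gof_partition(edges = edges)
    K <- part$K
    a <- part$a
    if (sample$n < K) stop("too few observations for K intervals")
  }
  core <- .acal_core(sample$residuals, sample$events, K = K, a = a,
                     edges = edges, drop_tol = drop_tol)
  .gof_chisq(core$observed, core$expected, df = K,
             method = "A-calibration (Akritas-type GOF test for right-censored PIT residuals)",
             K = K, a = core$a, edges = core$edges, drop_tol = drop_tol,
             data.name = deparse(substitute(sample)))
}

#' @export
print.gof_test <- function(x, ...) {
  cat("\n\t", x$method, "\n\n", sep = "")
  cat(sprintf("X-squared = %.6g, df = %d, p-value = %.6g\n",
              x$statistic, x$parameter, x$p.value))
  cat(sprintf("K = %d intervals on [0, %.6g]\n", x$K, x$a))
  tab <- rbind(observed = x$observed, expected = x$expected)
  colnames(tab) <- sprintf("I%d", seq_len(x$K))
  print(round(tab, 3))
  invisible(x)
}
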