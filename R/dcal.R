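# D-calibration: Pearson goodness-of-fit test on the PIT values
# Shat(t_i | z_i), with censored subjects allocated fractionally across
# intervals under the null hypothesis.
#
# The test bins the Shat-values themselves (a left-censored uniform sample
# under the null).  An uncensored subject contributes 1 to the interval
# containing Shat(t_i | z_i).  A subject censored at t_i has its unobserved
# Shat(X_i | z_i) uniform on (0, Shat(t_i | z_i)) under the null, so its unit
# mass is spread over [0, Shat(t_i | z_i)) proportionally to interval
# lengths.  Because the allocation leans on the null hypothesis being tested,
# the test is conservative under censoring.

#' Fractional interval allocation of a censored subject
#'
#' Three-case allocation of one censored subject's unit mass across the
#' partition, given the predicted survival probability \eqn{s = \hat S(t_i
#' \mid z_i)} at the censoring time: interval \eqn{I_k} receives 0 if
#' \eqn{s \le \inf(I_k)}, \eqn{(s - \inf(I_k))/s} if \eqn{s \in I_k}, and
#' \eqn{|I_k|/s} if \eqn{s \ge \sup(I_k)}.  The weights always sum to 1.
#'
#' @param shat predicted survival probability at the censoring time, in
#'   \eqn{(0, 1]}.  Zero is rejected: the allocation is undefined when the
#'   model leaves no survival mass at the censoring time.
#' @param partition a \code{\link{gof_partition}} covering \eqn{[0, 1]}.
#' @return numeric vector of \eqn{K} nonnegative weights summing to 1.
#' @examples
#' censored_contribution(0.5, gof_partition(K = 10))
#' @export
censored_contribution <- function(shat, partition) {
  stopifnot(inherits(partition, "gof_partition"))
  if (abs(partition$a - 1) > 1e-12) {
    stop("D-calibration partitions cover [0, 1]")
  }
  if (!(is.numeric(shat) && length(shat) == 1)) stop("'shat' must be a scalar")
  if (shat == 0) stop("censored at zero predicted survival: allocation undefined")
  if (shat < 0 || shat > 1) stop("'shat' must lie in (0, 1]")
  edges <- partition$edges
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  w <- numeric(partition$K)
  inside <- shat > lo & shat < hi           # half-open [lo, hi): shat == lo
  w[shat >= hi] <- ((hi - lo) / shat)[shat >= hi]   # belongs to the case below
  w[inside] <- (shat - lo[inside]) / shat
  w
}

# Vectorized censored allocation: the three cases collapse to
#   w_k(s) = (min(s, hi_k) - min(s, lo_k)) / s,
# the mass of unif(0, s) in [lo_k, hi_k).  Rows = censored subjects.
.censored_weights <- function(shat, lo, hi) {
  vapply(seq_along(lo),
         function(k) (pmin(shat, hi[k]) - pmin(shat, lo[k])) / shat,
         numeric(length(shat)))
}

# Fast path shared with the Monte-Carlo engine.
.dcal_core <- function(shat, events, K = 10, edges = NULL) {
  n <- length(shat)
  if (is.null(edges)) edges <- seq(0, 1, length.out = K + 1)
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  su <- shat[events == 1L]
  idx <- findInterval(su, edges, rightmost.closed = TRUE)
  observed <- tabulate(idx[idx >= 1L & idx <= K], nbins = K)
  sc <- shat[events == 0L]
  if (length(sc)) {
    if (any(sc == 0)) {
      stop("censored at zero predicted survival: allocation undefined")
    }
    w <- .censored_weights(sc, lo, hi)
    observed <- observed + colSums(matrix(w, ncol = K))
  }
  expected <- n * (hi - lo)
  list(observed = observed, expected = expected, edges = edges)
}

#' D-calibration test
#'
#' Pearson goodness-of-fit test for calibration of a survival prediction
#' model, handling right-censoring by fractional allocation of each censored
#' subject's mass under the null hypothesis
#' (\code{\link{censored_contribution}}).  The binned counts
#' \eqn{\tilde N_k} (uncensored counts plus censored allocations, summing to
#' \eqn{n} exactly) are contrasted with \eqn{E_k = n |I_k|} through
#' \eqn{\sum_k (\tilde N_k - E_k)^2 / E_k}.  With no censoring this
#' coincides exactly with the classical Pearson uniformity test on the
#' \eqn{\hat S}-values.  Because censored mass is imputed from the very null
#' hypothesis being tested, the test is conservative (actual type-I error
#' below nominal) under censoring.
#'
#' @param sample a \code{\link{make_pit_sample}} object (carries the
#'   \eqn{\hat S}-values binned by this test).
#' @param K number of partitioning intervals over \eqn{[0, 1]} (default 10,
#'   equal-width).
#' @param edges optional custom partition edges covering \eqn{[0, 1]}.
#' @param df degrees of freedom for the reference chi-square distribution.
#'   Defaults to \eqn{K - 1}, the classical Pearson convention of the
#'   original D-calibration proposal.
#' @return an object of classes \code{"gof_test"} and \code{"htest"}.
#' @examples
#' set.seed(1)
#' ds <- simulate_dataset(200, scheme = censoring_scheme("none"))
#' d_calibration_test(make_pit_sample(ds))
#' @seealso \code{\link{a_calibration_test}}
#' @export
d_calibration_test <- function(sample, K = 10, edges = NULL, df = NULL) {
  stopifnot(inherits(sample, "pit_sample"))
  if (is.null(edges)) {
    if (!(is.numeric(K) && length(K) == 1 && K >= 1 && K == floor(K))) {
      stop("'K' must be a positive integer")
    }
  } else {
    part <- gof_partition(edges = edges)
    if (abs(part$a - 1) > 1e-12) stop("D-calibration partitions cover [0, 1]")
    K <- part$K
  }
  if (sample$n < K) stop("too few observations for K intervals")
  if (is.null(df)) df <- K - 1L
  core <- .dcal_core(sample$shat, sample$events, K = K, edges = edges)
  .gof_chisq(core$observed, core$expected, df = df,
             method = "D-calibration (Pearson GOF test with null-imputed censored mass)",
             K = as.integer(K), a = 1, edges = core$edges,
             data.name = deparse(substitute(sample)))
}
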