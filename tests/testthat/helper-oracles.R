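# Independent oracles the implementation is checked against.

# Numerical quadrature of n * (1 - H(t)) / (1 - t) over each partition
# interval.  The integrand is integrated piecewise between the ECDF knots so
# every stats::integrate call sees a smooth function; this shares no code
# with the closed-form evaluation in the package.  `strict = TRUE` uses the
# left-continuous "<" ECDF convention, which must give the same integrals
# (the conventions differ on a Lebesgue-null set).
quad_expected_counts <- function(residuals, edges, strict = FALSE) {
  n <- length(residuals)
  H <- if (strict) function(t) mean(residuals < t)
       else function(t) mean(residuals <= t)
  f <- function(t) (1 - vapply(t, H, numeric(1))) / (1 - t)
  knots <- sort(unique(residuals))
  E <- numeric(length(edges) - 1)
  for (k in seq_along(E)) {
    lo <- edges[k]
    hi <- edges[k + 1]
    cuts <- sort(unique(c(lo, hi, knots[knots > lo & knots < hi])))
    tot <- 0
    for (j in seq_len(length(cuts) - 1)) {
      tot <- tot + stats::integrate(f, cuts[j], cuts[j + 1],
                                    rel.tol = 1e-10, abs.tol = 0,
                                    stop.on.error = FALSE)$value
    }
    E[k] <- n * tot
  }
  E
}

# Classical Pearson uniformity test on values in [0, 1], binned with cut()
# (a different binning path than the implementation's findInterval), with
# half-open intervals and a closed last interval.
pearson_uniform_oracle <- function(u, K) {
  edges <- seq(0, 1, length.out = K + 1)
  O <- as.vector(table(cut(u, edges, right = FALSE, include.lowest = FALSE)))
  O[K] <- O[K] + sum(u == 1)
  E <- length(u) * diff(edges)
  stat <- sum((O - E)^2 / E)
  list(statistic = stat,
       p.value = stats::pchisq(stat, df = K - 1, lower.tail = FALSE))
}

# Literal three-case censored allocation, evaluated case by case (the
# package's vectorized pmin form is checked against this).
three_case_oracle <- function(shat, edges) {
  K <- length(edges) - 1
  w <- numeric(K)
  for (k in seq_len(K)) {
    lo <- edges[k]
    hi <- edges[k + 1]
    w[k] <- if (shat <= lo) 0
            else if (shat < hi) (shat - lo) / shat
            else (hi - lo) / shat
  }
  w
}
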