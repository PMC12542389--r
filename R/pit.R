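# PIT residuals for right-censored survival data.
#
# Predicted survival probabilities Shat(t_i | z_i) evaluated at the observed
# (possibly censored) times are mapped to r_i = 1 - Shat(t_i | z_i).  Under a
# correctly specified model the event residuals form a right-censored
# standard-uniform sample on [0, 1]; both calibration tests operate on this
# transformed sample.

# Residuals are clamped to [0, 1 - .resid_eps] before any ECDF / integral
# computation so the integrand 1/(1 - t) in the expected counts is never
# evaluated at its t = 1 singularity.  Shat = 0 is admissible input; t = 1 is
# a removable boundary under the empirical-support truncation.
.resid_eps <- 1e-12

#' Probability integral transform residual
#'
#' Maps predicted survival probabilities \eqn{\hat S(t_i \mid z_i)} at the
#' observed times to residuals \eqn{r_i = 1 - \hat S(t_i \mid z_i)}.  Under a
#' correctly specified model and with right-censored data, the residuals of
#' the uncensored subjects are a right-censored sample from the standard
#' uniform distribution.
#'
#' @param shat numeric vector of predicted survival probabilities in
#'   \eqn{[0, 1]}.
#' @return numeric vector \code{1 - shat}.
#' @examples
#' pit_residual(c(1, 0.5, 0))
#' @export
pit_residual <- function(shat) {
  if (!is.numeric(shat)) stop("'shat' must be numeric")
  bad <- which(!is.finite(shat) | shat < 0 | shat > 1)
  if (length(bad)) {
    stop(sprintf("survival probability outside [0, 1] at index %d (value %s)",
                 bad[1], format(shat[bad[1]])))
  }
  1 - shat
}

#' Construct a PIT sample from censored survival records
#'
#' Vectorizes \code{\link{pit_residual}} over a set of censored records and
#' carries the event indicators along, yielding the right-censored sample on
#' \eqn{[0, 1]} that the calibration tests consume.
#'
#' @param records a data frame with columns \code{time} (nonnegative),
#'   \code{event} (0 = censored, 1 = event) and \code{shat} (predicted
#'   survival probability at \code{time}, in \eqn{[0, 1]}), e.g. as returned
#'   by \code{\link{simulate_dataset}} or \code{\link{read_survival_csv}}.
#' @return an object of class \code{"pit_sample"}: a list with elements
#'   \code{residuals} (clamped to \eqn{[0, 1 - 10^{-12}]}), \code{shat}
#'   (the original survival probabilities), \code{events} and \code{n}.
#' @examples
#' rec <- data.frame(time = c(1, 2), event = c(1, 0), shat = c(0.6, 0.3))
#' make_pit_sample(rec)
#' @export
make_pit_sample <- function(records) {
  if (is.null(records) || NROW(records) == 0L) stop("empty sample")
  records <- as.data.frame(records)
  for (col in c("time", "event", "shat")) {
    if (!col %in% names(records)) {
      stop(sprintf("records must contain a '%s' column", col))
    }
  }
  time <- records$time
  event <- records$event
  shat <- records$shat
  if (anyNA(time) || anyNA(event) || anyNA(shat)) {
    stop(sprintf("missing value in row %d",
                 which(is.na(time) | is.na(event) | is.na(shat))[1]))
  }
  if (any(time < 0)) {
    stop(sprintf("negative time in row %d", which(time < 0)[1]))
  }
  if (!all(event %in% c(0, 1))) {
    stop(sprintf("event indicator outside {0, 1} in row %d",
                 which(!event %in% c(0, 1))[1]))
  }
  res <- pit_residual(shat)
  structure(
    list(residuals = pmin(res, 1 - .resid_eps),
         shat = shat,
         events = as.integer(event),
         n = length(res)),
    class = "pit_sample"
  )
}

#' @export
print.pit_sample <- function(x, ...) {
  cat(sprintf("PIT sample: n = %d, events = %d (%.1f%% censored)\n",
              x$n, sum(x$events), 100 * mean(x$events == 0)))
  cat(sprintf("residual range: [%.4g, %.4g]\n",
              min(x$residuals), max(x$residuals)))
  invisible(x)
}

#' Evaluate a predictive survival model
#'
#' Evaluates a predictive-model contract -- a function \code{(t, z)} returning
#' the predicted survival probability -- and validates the contract: times
#' must be nonnegative and returned values must be probabilities.  Survival
#' curves are assumed continuous and nonincreasing with value 1 at
#' \eqn{t = 0}; strict monotonicity is not required (flat segments are
#' handled through the generalized inverse when simulating).
#'
#' @param model a function of \code{(t, z)} returning survival probabilities,
#'   e.g. from \code{\link{weibull_model}}.
#' @param t numeric vector of nonnegative times.
#' @param z predictor vector, or matrix with one row per element of \code{t}.
#' @return numeric vector of survival probabilities in \eqn{[0, 1]}.
#' @examples
#' mod <- weibull_model(weibull_spec(alpha = 1, beta = 0, predictors = "normal"))
#' evaluate_survival_curve(mod, t = 1, z = 0)  # exp(-1)
#' @export
evaluate_survival_curve <- function(model, t, z) {
  if (!is.function(model)) stop("'model' must be a function of (t, z)")
  if (any(t < 0)) stop(sprintf("negative time at index %d", which(t < 0)[1]))
  p <- model(t, z)
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("model contract violation: survival probability outside [0, 1]")
  }
  p
}
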