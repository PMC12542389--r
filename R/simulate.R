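# Weibull simulation harness with three censoring schemes.
#
# True survival model: S(t; alpha, sigma) = exp(-(t / sigma)^alpha) with
# subject-specific scale sigma = exp(beta' z).  Default truth: alpha = 1,
# beta = (log 2, log 1/2, log 2, log 1.5), predictors z1, z2 ~ N(0, 1) and
# z3, z4 ~ Bernoulli(0.5), independent.  Censoring is memoryless
# (exponential), uniform on (0, b), or "zero" (a point mass at 0 with
# probability q, else never censored); the scheme parameter is calibrated to
# hit a target censoring fraction q.

#' Weibull survival model specification
#'
#' Shape \eqn{\alpha > 0} and log-scale coefficient vector \eqn{\beta}
#' defining \eqn{S(t; \alpha, \sigma) = \exp(-(t/\sigma)^\alpha)} with
#' \eqn{\sigma = \exp(\beta^\top z)}.  Serves both as the data-generating
#' truth and (possibly misspecified, see \code{\link{misspecify}}) as the
#' predictive model under evaluation.
#'
#' @param alpha shape parameter, \eqn{> 0}.  The default 1 gives an
#'   exponential model.
#' @param beta coefficient vector on the log-scale of \eqn{\sigma}.
#' @param predictors character vector of marginal distributions, one per
#'   coefficient: \code{"normal"} (standard normal) or \code{"bernoulli"}
#'   (fair coin).
#' @return an object of class \code{"weibull_spec"}.
#' @examples
#' weibull_spec()  # the default truth used throughout the power study
#' @export
weibull_spec <- function(alpha = 1,
                         beta = c(log(2), log(0.5), log(2), log(1.5)),
                         predictors = c("normal", "normal",
                                        "bernoulli", "bernoulli")) {
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha > 0)) {
    stop("'alpha' must be a positive scalar")
  }
  if (length(predictors) != length(beta)) {
    stop("'predictors' must name one distribution per coefficient")
  }
  if (!all(predictors %in% c("normal", "bernoulli"))) {
    stop("predictor distributions must be 'normal' or 'bernoulli'")
  }
  structure(list(alpha = alpha, beta = as.numeric(beta),
                 predictors = predictors),
            class = "weibull_spec")
}

#' @export
print.weibull_spec <- function(x, ...) {
  cat(sprintf("Weibull model: alpha = %g, beta = (%s)\n",
              x$alpha, paste(signif(x$beta, 4), collapse = ", ")))
  cat("predictors:", paste(x$predictors, collapse = ", "), "\n")
  invisible(x)
}

#' Predictive-model contract for a Weibull specification
#'
#' Wraps a \code{\link{weibull_spec}} as a callable \code{(t, z)} returning
#' \eqn{S(t \mid z) = \exp(-(t/\exp(\beta^\top z))^\alpha)}.
#'
#' @param spec a \code{\link{weibull_spec}}.
#' @return a function \code{(t, z)}; \code{z} may be a vector (one subject)
#'   or a matrix with one row per element of \code{t}.
#' @export
weibull_model <- function(spec) {
  stopifnot(inherits(spec, "weibull_spec"))
  force(spec)
  function(t, z) {
    z <- if (is.matrix(z)) z else matrix(z, nrow = 1)
    sigma <- exp(drop(z %*% spec$beta))
    exp(-(t / sigma)^spec$alpha)
  }
}

#' Censoring scheme
#'
#' One of three right-censoring mechanisms with a single rate-controlling
#' parameter: \code{"memoryless"} draws censoring times from an exponential
#' distribution (\code{param} = rate), \code{"uniform"} from
#' \eqn{U(0, \code{param})}, and \code{"zero"} censors a subject at time 0
#' with probability \code{param} (and never otherwise).  \code{"none"}
#' disables censoring.
#'
#' @param kind scheme kind.
#' @param param rate (memoryless), upper bound (uniform) or zero-censoring
#'   probability (zero); ignored for \code{"none"}.
#' @return an object of class \code{"censoring_scheme"}.
#' @seealso \code{\link{calibrate_censoring}} to choose \code{param} for a
#'   target censoring fraction.
#' @export
censoring_scheme <- function(kind = c("memoryless", "uniform", "zero", "none"),
                             param = NULL) {
  kind <- match.arg(kind)
  if (kind == "none") {
    param <- NA_real_
  } else {
    if (!(is.numeric(param) && length(param) == 1)) {
      stop("'param' must be a numeric scalar")
    }
    if (kind == "zero") {
      if (param < 0 || param >= 1) stop("zero-censoring probability must lie in [0, 1)")
    } else if (param <= 0) {
      stop("'param' must be positive")
    }
  }
  structure(list(kind = kind, param = param), class = "censoring_scheme")
}

#' Draw subject predictors
#'
#' Independent columns with the marginals named in the specification
#' (default: \eqn{z_1, z_2 \sim N(0,1)}, \eqn{z_3, z_4 \sim} Bernoulli(0.5)).
#'
#' @param n number of subjects.
#' @param spec a \code{\link{weibull_spec}} naming the marginals.
#' @param seed optional integer seed; when \code{NULL} the current RNG
#'   stream is used.
#' @return an \code{n x length(beta)} matrix with columns \code{z1, z2, ...}.
#' @export
draw_predictors <- function(n, spec = weibull_spec(), seed = NULL) {
  stopifnot(inherits(spec, "weibull_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- length(spec$predictors)
  Z <- matrix(0, nrow = n, ncol = p,
              dimnames = list(NULL, paste0("z", seq_len(p))))
  for (j in seq_len(p)) {
    Z[, j] <- if (spec$predictors[j] == "normal") stats::rnorm(n)
              else stats::rbinom(n, 1, 0.5)
  }
  Z
}

#' Draw event times from the true model
#'
#' Inverse-transform sampling: \eqn{X_i = \sigma(z_i) (-\log U_i)^{1/\alpha}}
#' with \eqn{U_i \sim U(0, 1)}, so that \eqn{X_i \mid z_i} has survival
#' function \eqn{S(t; \alpha, \sigma(z_i))}.
#'
#' @param spec a \code{\link{weibull_spec}}.
#' @param Z predictor matrix from \code{\link{draw_predictors}}.
#' @param seed optional integer seed.
#' @return vector of event times.
#' @export
draw_event_times <- function(spec, Z, seed = NULL) {
  stopifnot(inherits(spec, "weibull_spec"))
  if (!is.null(seed)) set.seed(seed)
  sigma <- exp(drop(Z %*% spec$beta))
  sigma * (-log(stats::runif(nrow(Z))))^(1 / spec$alpha)
}

# Evaluate an expression with a fixed seed without disturbing the caller's
# RNG stream.
.with_fixed_seed <- function(seed, expr) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  expr
}

#' Calibrate a censoring scheme to a target censoring fraction
#'
#' Chooses the scheme parameter (rate, upper bound, or zero-probability) so
#' that the censoring fraction \eqn{q = P(C < X)} under the given true model
#' matches the target.  For the zero scheme the parameter equals \eqn{q}
#' exactly.  For the memoryless and uniform schemes \eqn{q(\mathrm{param})}
#' is estimated by Monte Carlo with a fixed internal seed and \eqn{10^6}
#' simulated event times, integrating the closed-form conditional probability
#' \eqn{P(C < X \mid X)} over the draws, and the parameter is solved by
#' bracketed root-finding.
#'
#' @param kind scheme kind (\code{"memoryless"}, \code{"uniform"} or
#'   \code{"zero"}).
#' @param spec the true \code{\link{weibull_spec}}.
#' @param q target censoring fraction in \eqn{[0, 1)}; \code{q = 0} returns
#'   the no-censoring scheme.
#' @param n_mc number of Monte-Carlo draws for the root-finder.
#' @return a calibrated \code{\link{censoring_scheme}} with attribute
#'   \code{achieved_q} (the Monte-Carlo estimate at the solved parameter,
#'   within 0.002 of the target).
#' @examples
#' sc <- calibrate_censoring("memoryless", weibull_spec(), q = 0.2)
#' sc$param
#' @export
calibrate_censoring <- function(kind = c("memoryless", "uniform", "zero"),
                                spec = weibull_spec(), q, n_mc = 1e6) {
  kind <- match.arg(kind)
  stopifnot(inherits(spec, "weibull_spec"))
  if (!(is.numeric(q) && length(q) == 1 && q >= 0 && q < 1)) {
    stop("target censoring fraction 'q' must lie in [0, 1)")
  }
  if (q == 0) return(censoring_scheme("none"))
  if (kind == "zero") {
    sch <- censoring_scheme("zero", q)
    attr(sch, "achieved_q") <- q
    return(sch)
  }
  X <- .with_fixed_seed(181112, {
    Z <- draw_predictors(n_mc, spec)
    draw_event_times(spec, Z)
  })
  # P(C < X | X): 1 - exp(-rate X) for exponential C, min(X/b, 1) for
  # uniform(0, b) C; both monotone in the parameter.
  qfun <- switch(kind,
    memoryless = function(rate) mean(-expm1(-rate * X)),
    uniform = function(b) mean(pmin(X / b, 1))
  )
  f <- function(par) qfun(par) - q
  lower <- 1e-8
  upper <- 1
  expand <- function(par, grow) {
    for (i in 1:60) {
      if (is.finite(f(par)) && sign(f(par)) != sign(f(lower))) break
      par <- par * grow
    }
    par
  }
  # memoryless: q increasing in rate; uniform: q decreasing in the bound.
  if (kind == "memoryless") {
    if (f(lower) > 0) stop("root not bracketed: target below attainable range")
    upper <- expand(1, 10)
  } else {
    # reverse roles: f(lower) > 0 (tiny bound censors everyone)
    if (f(lower) < 0) stop("root not bracketed: target above attainable range")
    upper <- expand(1, 10)
  }
  if (sign(f(lower)) == sign(f(upper))) {
    stop(sprintf("root not bracketed on [%g, %g]: q(lower) = %.4f, q(upper) = %.4f, target %.4f",
                 lower, upper, qfun(lower), qfun(upper), q))
  }
  root <- stats::uniroot(f, c(lower, upper), tol = 1e-10)$root
  achieved <- qfun(root)
  if (abs(achieved - q) > 0.002) {
    stop(sprintf("calibration failed: achieved q = %.4f, target %.4f", achieved, q))
  }
  sch <- censoring_scheme(kind, root)
  attr(sch, "achieved_q") <- achieved
  sch
}

#' Apply right-censoring to event times
#'
#' Draws censoring times from the scheme and returns the censored
#' observations \eqn{T_i = \min(X_i, C_i)} with event indicators
#' \eqn{\Delta_i = 1[X_i < C_i]} (ties at machine precision, a measure-zero
#' event for the continuous schemes, are assigned \eqn{\Delta = 1}).
#' Zero-censored subjects get \eqn{T = 0, \Delta = 0}.
#'
#' @param X vector of event times.
#' @param scheme a \code{\link{censoring_scheme}}.
#' @param seed optional integer seed.
#' @return a list with elements \code{time}, \code{event} and \code{cens}
#'   (the raw censoring times, \code{Inf} where never censored).
#' @export
apply_censoring <- function(X, scheme, seed = NULL) {
  stopifnot(inherits(scheme, "censoring_scheme"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(X)
  C <- switch(scheme$kind,
    none = rep(Inf, n),
    memoryless = stats::rexp(n, rate = scheme$param),
    uniform = stats::runif(n, 0, scheme$param),
    zero = ifelse(stats::runif(n) < scheme$param, 0, Inf)
  )
  list(time = pmin(X, C), event = as.integer(X <= C), cens = C)
}

#' Misspecify a Weibull model
#'
#' Produces the misspecified predictive models of the power study: the shape
#' mode scales \eqn{\alpha' = \lambda\alpha}, the scale mode scales the
#' coefficient vector \eqn{\beta' = \lambda\beta}, and the missing mode zeroes
#' one coefficient (the model is evaluated with the predictor omitted, not
#' refit).  \eqn{\lambda = 1} recovers the truth in the first two modes.
#'
#' @param spec the true \code{\link{weibull_spec}}.
#' @param mode one of \code{"shape"}, \code{"scale"}, \code{"missing"}.
#' @param lambda positive misspecification factor (shape/scale), or the
#'   coefficient index to zero out (missing).
#' @return a new \code{\link{weibull_spec}}.
#' @examples
#' misspecify(weibull_spec(), "shape", 0.85)
#' @export
misspecify <- function(spec, mode = c("shape", "scale", "missing"), lambda) {
  stopifnot(inherits(spec, "weibull_spec"))
  mode <- match.arg(mode)
  if (mode == "missing") {
    idx <- lambda
    if (!(length(idx) == 1 && idx == floor(idx) && idx >= 1 &&
          idx <= length(spec$beta))) {
      stop("'lambda' must index a coefficient in 'missing' mode")
    }
    beta <- spec$beta
    beta[idx] <- 0
    return(weibull_spec(spec$alpha, beta, spec$predictors))
  }
  if (!(is.numeric(lambda) && length(lambda) == 1 && lambda > 0)) {
    stop("'lambda' must be a positive scalar")
  }
  switch(mode,
    shape = weibull_spec(lambda * spec$alpha, spec$beta, spec$predictors),
    scale = weibull_spec(spec$alpha, lambda * spec$beta, spec$predictors)
  )
}

#' Simulate a censored validation dataset
#'
#' Draws predictors and event times from the true model, applies the
#' censoring scheme, and (optionally) attaches the predicted survival
#' probabilities \eqn{\hat S(t_i \mid z_i)} of a predictive model evaluated
#' at the observed times -- everything the calibration tests need.
#'
#' @param n number of subjects.
#' @param truth the true \code{\link{weibull_spec}}.
#' @param scheme a \code{\link{censoring_scheme}} (already calibrated; see
#'   \code{\link{calibrate_censoring}}).
#' @param model the predictive \code{\link{weibull_spec}} whose calibration
#'   is under study; defaults to the truth (the null hypothesis holds).
#'   \code{NULL} omits the \code{shat} column.
#' @param seed optional integer seed.
#' @return a data frame with columns \code{id}, \code{time}, \code{event},
#'   the predictors \code{z1, ...}, and \code{shat}; attributes \code{truth},
#'   \code{scheme}, \code{model} and \code{cens_fraction}.
#' @examples
#' sc <- calibrate_censoring("memoryless", q = 0.2)
#' ds <- simulate_dataset(100, scheme = sc, seed = 1)
#' attr(ds, "cens_fraction")
#' @export
simulate_dataset <- function(n, truth = weibull_spec(),
                             scheme = censoring_scheme("none"),
                             model = truth, seed = NULL) {
  stopifnot(inherits(truth, "weibull_spec"),
            inherits(scheme, "censoring_scheme"))
  if (!is.null(seed)) set.seed(seed)
  Z <- draw_predictors(n, truth)
  X <- draw_event_times(truth, Z)
  cns <- apply_censoring(X, scheme)
  ds <- data.frame(id = seq_len(n), time = cns$time, event = cns$event)
  ds <- cbind(ds, as.data.frame(Z))
  if (!is.null(model)) {
    stopifnot(inherits(model, "weibull_spec"))
    sigma <- exp(drop(Z %*% model$beta))
    ds$shat <- exp(-(cns$time / sigma)^model$alpha)
  }
  attr(ds, "truth") <- truth
  attr(ds, "scheme") <- scheme
  attr(ds, "model") <- model
  attr(ds, "cens_fraction") <- mean(cns$event == 0)
  ds
}
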