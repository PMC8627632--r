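# "Current practice": standard parametric survival models fitted by
# right-censored maximum likelihood, with AIC/BIC and log-hazard prediction.
# Fitting is delegated to flexsurv; the censored log-likelihood below is an
# independent closed-form implementation used for validation and nesting
# checks.

.parametric_families <- list(
  exponential       = list(dist = "exp",      n_par = 1L),
  weibull           = list(dist = "weibull",  n_par = 2L),
  gompertz          = list(dist = "gompertz", n_par = 2L),
  loglogistic       = list(dist = "llogis",   n_par = 2L),
  lognormal         = list(dist = "lnorm",    n_par = 2L),
  gamma             = list(dist = "gamma",    n_par = 2L),
  generalised_gamma = list(dist = "gengamma", n_par = 3L)
)

#' Names of the supported standard parametric families
#'
#' @return Character vector of family names.
#' @export
parametric_families <- function() names(.parametric_families)

# Per-family density/survival on natural parameters.  `pars` is a named
# numeric vector on the unconstrained scale (positive parameters entered as
# logs; location and Gompertz shape / generalised-gamma Q unconstrained).
.family_dens_surv <- function(family, pars, t) {
  switch(family,
    exponential = {
      r <- exp(pars[["log_rate"]])
      list(d = stats::dexp(t, r), s = stats::pexp(t, r, lower.tail = FALSE))
    },
    weibull = {
      a <- exp(pars[["log_shape"]]); b <- exp(pars[["log_scale"]])
      list(d = stats::dweibull(t, a, b),
           s = stats::pweibull(t, a, b, lower.tail = FALSE))
    },
    gompertz = {
      a <- pars[["shape"]]; r <- exp(pars[["log_rate"]])
      list(d = flexsurv::dgompertz(t, a, r),
           s = flexsurv::pgompertz(t, a, r, lower.tail = FALSE))
    },
    loglogistic = {
      a <- exp(pars[["log_shape"]]); b <- exp(pars[["log_scale"]])
      list(d = flexsurv::dllogis(t, a, b),
           s = flexsurv::pllogis(t, a, b, lower.tail = FALSE))
    },
    lognormal = {
      m <- pars[["meanlog"]]; s <- exp(pars[["log_sdlog"]])
      list(d = stats::dlnorm(t, m, s),
           s = stats::plnorm(t, m, s, lower.tail = FALSE))
    },
    gamma = {
      a <- exp(pars[["log_shape"]]); r <- exp(pars[["log_rate"]])
      list(d = stats::dgamma(t, a, r),
           s = stats::pgamma(t, a, r, lower.tail = FALSE))
    },
    generalised_gamma = {
      mu <- pars[["mu"]]; sg <- exp(pars[["log_sigma"]]); q <- pars[["Q"]]
      list(d = flexsurv::dgengamma(t, mu, sg, q),
           s = flexsurv::pgengamma(t, mu, sg, q, lower.tail = FALSE))
    },
    stop("unknown family: ", family)
  )
}

#' Right-censored log-likelihood of a standard parametric family
#'
#' Computes \eqn{\sum_i d_i \log \lambda(t_i) + \log S(t_i)} for a named
#' family at given parameter values, via the equivalent
#' \eqn{\sum_i d_i \log f(t_i) + (1 - d_i)\log S(t_i)}.  Parameters are
#' supplied on the unconstrained scale used for optimisation: strictly
#' positive parameters as logs (`log_rate`, `log_shape`, `log_scale`,
#' `log_sdlog`, `log_sigma`), location-type and sign-free parameters
#' directly (`meanlog`, `mu`, Gompertz `shape`, generalised-gamma `Q`).
#'
#' @param family One of [parametric_families()].
#' @param parameters Named numeric vector on the unconstrained scale.
#' @param data A [survival_data()] frame.
#' @return The log-likelihood value.
#' @examples
#' d <- survival_data(c(1, 2, 3), c(1, 1, 0))
#' censored_log_likelihood("exponential", c(log_rate = log(1/3)), d)
#' @export
censored_log_likelihood <- function(family, parameters, data) {
  family <- match.arg(family, parametric_families())
  stopifnot(nrow(data) > 0)
  if (any(!is.finite(parameters))) stop("parameters must be finite")
  if (any(data$time <= 0)) stop("all times must be positive")
  ds <- .family_dens_surv(family, parameters, data$time)
  sum(ifelse(data$event == 1, log(ds$d), log(ds$s)))
}

#' Fit a standard parametric survival model
#'
#' Maximum-likelihood fit of one parametric family to right-censored data
#' (via [flexsurv::flexsurvreg()], which optimises log-transformed positive
#' parameters from data-driven starting values).  Optimiser failure is
#' returned as a flagged non-converged fit, not an error.
#'
#' @param data A [survival_data()] frame with at least one event.
#' @param family One of [parametric_families()].
#' @return A `hazard_fit` (subclass `parametric_fit`).
#' @examples
#' d <- simulate_cohort(scenario(200, 3), seed = 1)
#' f <- fit_parametric(d, "weibull")
#' AIC(f)
#' predict(f, c(1, 2, 5))
#' @export
fit_parametric <- function(data, family) {
  family <- match.arg(family, parametric_families())
  stopifnot(sum(data$event) >= 1)
  info <- .parametric_families[[family]]
  fit <- tryCatch(
    flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = data,
                          dist = info$dist),
    error = function(e) e
  )
  if (inherits(fit, "error"))
    return(failed_fit("parametric_fit", family, conditionMessage(fit)))
  if (!is.null(fit$opt$convergence) && fit$opt$convergence != 0)
    return(failed_fit("parametric_fit", family, "optimiser did not converge"))
  est <- stats::setNames(fit$res[, "est"], rownames(fit$res))
  predict_fn <- function(times) {
    h <- summary(fit, t = times, type = "hazard", ci = FALSE,
                 tidy = TRUE)$est
    hazard_curve(times, pmax(log(h), -700))
  }
  new_hazard_fit("parametric_fit", family, est, fit$loglik, info$n_par,
                 nrow(data), predict_fn, extra = list(flexsurv_fit = fit))
}

#' Fit the current-practice model class
#'
#' Fits all standard parametric families and selects among the converged
#' fits by information criterion.  The Gompertz is fitted but excluded from
#' selection by default (it is notoriously unstable under extrapolation);
#' set `include_gompertz = TRUE` to allow it to compete.  The generalised F
#' family is not offered.
#'
#' @param data A [survival_data()] frame.
#' @param include_gompertz Allow the Gompertz family into selection?
#' @param criterion `"aic"` or `"bic"`.
#' @return The selected `hazard_fit`; the full candidate list is attached as
#'   attribute `"candidates"`.
#' @export
fit_current_practice <- function(data, include_gompertz = FALSE,
                                 criterion = "aic") {
  fams <- parametric_families()
  fits <- lapply(fams, function(f) fit_parametric(data, f))
  names(fits) <- fams
  pool <- if (include_gompertz) fits else fits[setdiff(fams, "gompertz")]
  best <- select_best(pool, criterion)
  attr(best, "candidates") <- fits
  best
}
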