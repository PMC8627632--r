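# Royston-Parmar models: restricted cubic splines in log-time on the log
# cumulative-hazard scale (Weibull extension) or log cumulative-odds scale
# (log-logistic extension), fitted by full censored-data maximum
# likelihood via flexsurv.  Internal knots sit at centiles of the
# uncensored log event times, boundary knots at their extremes; beyond the
# boundary knots the spline — hence the extrapolated log-hazard trend — is
# linear in log-time.

#' Fit a Royston-Parmar spline survival model
#'
#' @param data A [survival_data()] frame with events.
#' @param n_internal_knots Number of internal knots, 0 to 5; 0 reduces the
#'   hazard-scale model to a Weibull and the odds-scale model to a
#'   log-logistic.
#' @param scale `"hazard"` (log cumulative hazard; Weibull extension) or
#'   `"odds"` (log cumulative odds; log-logistic extension).
#' @return A `hazard_fit` (subclass `rpm_fit`).  Non-convergence or a
#'   non-monotone fitted cumulative hazard is returned as a flagged
#'   failure.
#' @export
fit_rpm <- function(data, n_internal_knots = 0L,
                    scale = c("hazard", "odds")) {
  scale <- match.arg(scale)
  stopifnot(n_internal_knots >= 0L, n_internal_knots <= 5L,
            sum(data$event) >= 1)
  label <- sprintf("RPM (%d knots, %s scale)", n_internal_knots, scale)
  fit <- tryCatch(
    suppressWarnings(
      flexsurv::flexsurvspline(survival::Surv(time, event) ~ 1, data = data,
                               k = n_internal_knots, scale = scale)),
    error = function(e) e
  )
  if (inherits(fit, "error"))
    return(failed_fit("rpm_fit", label, conditionMessage(fit)))
  if (!is.null(fit$opt$convergence) && fit$opt$convergence != 0)
    return(failed_fit("rpm_fit", label, "optimiser did not converge"))
  # hazard must be non-negative (monotone cumulative hazard) in-sample
  chk <- seq(min(data$time), max(data$time), length.out = 101L)
  hchk <- summary(fit, t = chk, type = "hazard", ci = FALSE, tidy = TRUE)$est
  if (any(!is.finite(hchk)) || any(hchk < 0))
    return(failed_fit("rpm_fit", label,
                      "non-monotone fitted cumulative hazard"))
  est <- fit$res[, "est"]
  predict_fn <- function(times) {
    h <- summary(fit, t = times, type = "hazard", ci = FALSE,
                 tidy = TRUE)$est
    hazard_curve(times, pmin(pmax(log(h), -700), 700))
  }
  new_hazard_fit("rpm_fit", label, est, fit$loglik,
                 n_internal_knots + 2L, nrow(data), predict_fn,
                 extra = list(flexsurv_fit = fit, scale = scale,
                              n_internal_knots = n_internal_knots))
}

#' Fit and select within the Royston-Parmar class
#'
#' Fits both scales with 0 to `max_knots` internal knots and selects the
#' converged fit with the lowest information criterion.
#'
#' @inheritParams fit_rpm
#' @param max_knots Largest number of internal knots considered.
#' @param criterion `"aic"` or `"bic"`.
#' @return The selected `hazard_fit`, with all candidates attached as
#'   attribute `"candidates"`.
#' @export
fit_rpm_best <- function(data, max_knots = 5L, criterion = "aic") {
  grid <- expand.grid(k = 0:max_knots, scale = c("hazard", "odds"),
                      stringsAsFactors = FALSE)
  fits <- lapply(seq_len(nrow(grid)), function(i)
    fit_rpm(data, grid$k[i], grid$scale[i]))
  best <- select_best(fits, criterion)
  attr(best, "candidates") <- fits
  best
}
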