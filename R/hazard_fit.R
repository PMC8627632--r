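#' Log-hazard curve on a time grid
#'
#' The common prediction container of all model classes: a strictly
#' increasing positive time grid with point estimates of log-hazard and
#' optional uncertainty bands.
#'
#' @param time Strictly increasing vector of positive times (years).
#' @param log_hazard Log-hazard values, same length as `time`, all finite.
#' @param lower,upper Optional pointwise band for the log-hazard.
#' @return A data frame of class `hazard_curve`.
#' @export
hazard_curve <- function(time, log_hazard, lower = NULL, upper = NULL) {
  stopifnot(is.numeric(time), is.numeric(log_hazard),
            length(time) == length(log_hazard))
  if (any(time <= 0)) stop("grid times must be strictly positive")
  if (is.unsorted(time, strictly = TRUE)) stop("grid must be strictly increasing")
  if (any(!is.finite(log_hazard))) stop("log-hazard values must be finite")
  out <- data.frame(time = time, log_hazard = log_hazard)
  if (!is.null(lower)) out$lower <- lower
  if (!is.null(upper)) out$upper <- upper
  class(out) <- c("hazard_curve", "data.frame")
  out
}

#' @export
plot.hazard_curve <- function(x, ..., xlab = "Time (years)",
                              ylab = "log hazard", type = "l") {
  graphics::plot(x$time, x$log_hazard, type = type, xlab = xlab,
                 ylab = ylab, ...)
  if (!is.null(x$lower)) {
    graphics::lines(x$time, x$lower, lty = 2)
    graphics::lines(x$time, x$upper, lty = 2)
  }
  invisible(x)
}

# Internal constructor for the shared fitted-model contract.  Every fitter
# supplies a predict_fn mapping a positive time grid to log-hazard values;
# loglik/n_par feed AIC/BIC; converged = FALSE marks flagged failures that
# selection must skip.
new_hazard_fit <- function(subclass, label, parameters, loglik, n_par,
                           n_obs, predict_fn, converged = TRUE,
                           extra = list()) {
  obj <- c(list(label = label, parameters = parameters,
                log_likelihood = loglik, n_parameters = n_par,
                n_obs = n_obs,
                aic = 2 * n_par - 2 * loglik,
                bic = n_par * log(n_obs) - 2 * loglik,
                converged = converged,
                predict_fn = predict_fn), extra)
  structure(obj, class = c(subclass, "hazard_fit"))
}

# Flagged failure result: carries the reason, excluded from selection.
failed_fit <- function(subclass, label, reason) {
  structure(list(label = label, converged = FALSE, reason = reason),
            class = c(subclass, "hazard_fit_failure", "hazard_fit"))
}

#' Has a fit converged?
#'
#' @param object A `hazard_fit`.
#' @return `TRUE` for a usable fit, `FALSE` for a flagged failure.
#' @export
is_converged <- function(object) {
  isTRUE(object$converged)
}

#' @export
print.hazard_fit <- function(x, ...) {
  if (!is_converged(x)) {
    cat(sprintf("Failed hazard model fit [%s]: %s\n", x$label,
                x$reason %||% "did not converge"))
    return(invisible(x))
  }
  cat(sprintf("Hazard model fit: %s\n", x$label))
  cat(sprintf("  log-likelihood %.4f on %d parameter(s), n = %d\n",
              x$log_likelihood, x$n_parameters, x$n_obs))
  cat(sprintf("  AIC %.4f, BIC %.4f\n", x$aic, x$bic))
  invisible(x)
}

#' @export
summary.hazard_fit <- function(object, ...) {
  out <- list(label = object$label,
              converged = is_converged(object),
              parameters = object$parameters,
              log_likelihood = object$log_likelihood,
              n_parameters = object$n_parameters,
              aic = object$aic, bic = object$bic)
  class(out) <- "summary.hazard_fit"
  out
}

#' @export
print.summary.hazard_fit <- function(x, ...) {
  cat(sprintf("%s (converged: %s)\n", x$label, x$converged))
  if (x$converged) {
    cat(sprintf("  logLik %.4f  k %d  AIC %.4f  BIC %.4f\n",
                x$log_likelihood, x$n_parameters, x$aic, x$bic))
    if (length(x$parameters)) {
      cat("  parameters:\n")
      print(x$parameters)
    }
  }
  invisible(x)
}

#' @export
coef.hazard_fit <- function(object, ...) {
  object$parameters
}

#' @export
logLik.hazard_fit <- function(object, ...) {
  structure(object$log_likelihood, df = object$n_parameters,
            nobs = object$n_obs, class = "logLik")
}

#' Predict log-hazard on a time grid
#'
#' All fitted model classes share this contract: pointwise log-hazard over
#' any strictly positive grid, including extrapolation times beyond the
#' observed data.
#'
#' @param object A converged `hazard_fit`.
#' @param times Strictly positive, strictly increasing time grid (years).
#' @param ... Unused.
#' @return A [hazard_curve].
#' @export
predict.hazard_fit <- function(object, times, ...) {
  if (!is_converged(object))
    stop("cannot predict from a failed fit")
  if (any(times <= 0)) stop("grid times must be strictly positive")
  object$predict_fn(times)
}

#' @export
plot.hazard_fit <- function(x, times = NULL, ...) {
  if (is.null(times)) times <- seq(0.05, 10, by = 0.05)
  plot(predict(x, times), ...)
}

#' Serialise a fitted model summary to JSON
#'
#' @param object A `hazard_fit`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
fit_to_json <- function(object, path = NULL) {
  s <- list(label = object$label, converged = is_converged(object))
  if (is_converged(object)) {
    s$parameters <- as.list(object$parameters)
    s$log_likelihood <- object$log_likelihood
    s$n_parameters <- object$n_parameters
    s$aic <- object$aic
    s$bic <- object$bic
  } else {
    s$reason <- object$reason
  }
  js <- jsonlite::toJSON(s, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Select the best fitted model by information criterion
#'
#' Returns the converged model minimising AIC or BIC.  Ties are broken by
#' fewest parameters, then by position in the supplied list (fitters emit
#' candidates in a fixed family/spec order, so positional tie-break is the
#' fixed-ordering rule).
#'
#' @param models List of `hazard_fit` objects.
#' @param criterion `"aic"` or `"bic"`.
#' @return The selected `hazard_fit`.
#' @export
select_best <- function(models, criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  ok <- Filter(is_converged, models)
  if (length(ok) == 0L) stop("no converged model to select from")
  crit <- vapply(ok, function(m) m[[criterion]], numeric(1))
  npar <- vapply(ok, function(m) m$n_parameters, numeric(1))
  ord <- order(crit, npar, seq_along(ok))
  ok[[ord[1L]]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
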