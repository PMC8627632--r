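#' Fit a hazard model of any class
#'
#' Front door to the five model classes.  Returns an object inheriting
#' from `hazard_fit`, with `print`, `summary`, `coef`, `logLik`,
#' `AIC`/`BIC`, `predict` (log-hazard over any positive grid, including
#' extrapolation times) and `plot` methods.
#'
#' Classes with several specifications (`"current_practice"`, `"rpm"`,
#' `"fp1"`, `"fp2"`) are selected within class by AIC; the selected fit
#' carries all candidates as attribute `"candidates"`.
#'
#' @param data A [survival_data()] frame (or any data frame with `time`
#'   and `event` columns).
#' @param class One of [model_classes()], or a single parametric family
#'   name from [parametric_families()].
#' @param ... Passed to the class fitter ([fit_current_practice()],
#'   [fit_rpm_best()], [fit_fp_best()], [fit_gam()], [fit_dsm()],
#'   [fit_parametric()]).
#' @return A `hazard_fit`.
#' @examples
#' d <- simulate_cohort(scenario(300, 3), seed = 7)
#' f <- fit_hazard(d, "current_practice")
#' f
#' head(predict(f, seq(0.5, 10, by = 0.5)))
#' @export
fit_hazard <- function(data, class = "current_practice", ...) {
  if (!inherits(data, "survival_data"))
    data <- survival_data(data$time, data$event)
  if (class %in% parametric_families())
    return(fit_parametric(data, class, ...))
  switch(match.arg(class, model_classes()),
    current_practice = fit_current_practice(data, ...),
    rpm = fit_rpm_best(data, ...),
    fp1 = fit_fp_best(data, 1L, ...),
    fp2 = fit_fp_best(data, 2L, ...),
    gam = fit_gam(data, ...),
    dsm_damped_local = fit_dsm(data, "damped", "local", ...),
    dsm_damped_global = fit_dsm(data, "damped", "global", ...),
    dsm_local_local = fit_dsm(data, "local", "local", ...),
    dsm_local_global = fit_dsm(data, "local", "global", ...)
  )
}
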