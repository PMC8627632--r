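# Penalised-spline (GAM) hazard model: log-hazard as a cubic regression
# spline in log-time, fitted to piecewise-exponential counts with a
# curvature penalty whose null space is linear in log-time — i.e. the
# Weibull log-hazard form.  Smoothing is estimated by REML with a GCV
# fallback; extrapolation continues linearly in log-time beyond the data.

#' Fit a penalised-spline hazard model
#'
#' Fits \eqn{\log \lambda(t) = s(\log t)} with a cubic regression spline
#' basis (maximum dimension `k`) by penalised Poisson regression of
#' interval event counts with log-exposure offset, via [mgcv::gam()].  The
#' curvature penalty shrinks towards functions linear in log-time, so the
#' infinite-smoothing limit is a Weibull hazard.  Beyond the last observed
#' interval midpoint the prediction continues linearly in log-time.
#'
#' @param data A [survival_data()] frame with events.
#' @param k Basis dimension of the spline (default 10).
#' @param n_intervals Number of equal-width intervals of the split grid.
#' @param sp Optional fixed smoothing parameter; `NULL` estimates it by
#'   REML (falling back to GCV if REML optimisation fails).
#' @return A `hazard_fit` (subclass `gam_fit`) whose `n_parameters` is the
#'   effective degrees of freedom of the penalised fit.
#' @export
fit_gam <- function(data, k = 10L, n_intervals = 100L, sp = NULL) {
  stopifnot(k >= 3, sum(data$event) >= 1)
  pe <- pe_table(data, n_intervals)
  df <- data.frame(events = pe$events, lt = log(pe$tref),
                   log_exposure = log(pe$exposure))
  # spline knots span the event-time range; the cr basis continues
  # linearly outside its knots, which covers the pre-first-event device
  # rows and gives linear-in-log-time extrapolation
  ev_lt <- log(range(data$time[data$event == 1]))
  knots <- list(lt = seq(ev_lt[1], ev_lt[2], length.out = k))
  fit_once <- function(method) {
    mgcv::gam(events ~ s(lt, k = k, bs = "cr") + offset(log_exposure),
              family = stats::poisson(), data = df, method = method,
              knots = knots, sp = if (is.null(sp)) NULL else sp)
  }
  fit <- tryCatch(fit_once("REML"), error = function(e) e)
  if (inherits(fit, "error"))
    fit <- tryCatch(fit_once("GCV.Cp"), error = function(e) e)
  if (inherits(fit, "error"))
    return(failed_fit("gam_fit", "GAM (penalised spline)",
                      conditionMessage(fit)))
  if (!fit$converged)
    return(failed_fit("gam_fit", "GAM (penalised spline)",
                      "smoothing-parameter optimisation failed"))
  lt_max <- max(df$lt)
  eta_at <- function(lt) {
    as.numeric(mgcv::predict.gam(
      fit, newdata = data.frame(lt = lt, log_exposure = 0), type = "link"))
  }
  # boundary value and log-time slope, for linear continuation
  eps <- 1e-3
  eta_b <- eta_at(lt_max)
  slope_b <- (eta_b - eta_at(lt_max - eps)) / eps
  predict_fn <- function(times) {
    lt <- log(times)
    eta <- numeric(length(lt))
    inside <- lt <= lt_max
    if (any(inside)) eta[inside] <- eta_at(lt[inside])
    if (any(!inside)) eta[!inside] <- eta_b + slope_b * (lt[!inside] - lt_max)
    hazard_curve(times, pmin(pmax(eta, -700), 700))
  }
  edf <- sum(fit$edf)
  new_hazard_fit("gam_fit", "GAM (penalised spline)", stats::coef(fit),
                 as.numeric(stats::logLik(fit)), edf, nrow(data),
                 predict_fn,
                 extra = list(gam_fit = fit, edf = edf,
                              smoothing = fit$sp))
}
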