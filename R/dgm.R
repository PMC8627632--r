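#' Two-component mixture-Weibull data-generating mechanism
#'
#' Constructs the parameter set of a two-component mixture-Weibull survival
#' mechanism with survival function
#' \deqn{S(t) = \rho \exp(-\Lambda_1 t^{\gamma_1}) +
#'   (1-\rho) \exp(-\Lambda_2 t^{\gamma_2}).}
#' The mixture can be read as two latent sub-populations, one with a high
#' hazard (short survival) and one with a low hazard (long survival).  The
#' default values give a true hazard with two turning points within four
#' years and a long-term increase driven by the first (ageing-like)
#' component.
#'
#' @param gamma1,gamma2 Weibull shape parameters of the two components
#'   (dimensionless, > 0).
#' @param lambda1,lambda2 Weibull scale (rate-like) parameters of the two
#'   components (> 0), on the \eqn{\exp(-\Lambda t^\gamma)} scale.
#' @param rho Mixing proportion of component 1, in \[0, 1\].
#' @return An object of class `mixture_weibull`.
#' @examples
#' p <- mixture_weibull()
#' mixture_survival(c(2, 3, 4), p)
#' @export
mixture_weibull <- function(gamma1 = 1.8, lambda1 = 0.02,
                            gamma2 = 1.4, lambda2 = 2.3,
                            rho = 0.5) {
  stopifnot(is.numeric(gamma1), is.numeric(lambda1),
            is.numeric(gamma2), is.numeric(lambda2), is.numeric(rho),
            length(gamma1) == 1L, length(lambda1) == 1L,
            length(gamma2) == 1L, length(lambda2) == 1L, length(rho) == 1L)
  if (gamma1 <= 0 || lambda1 <= 0 || gamma2 <= 0 || lambda2 <= 0)
    stop("shape and scale parameters must be strictly positive")
  if (rho < 0 || rho > 1)
    stop("'rho' must lie in [0, 1]")
  structure(list(gamma1 = gamma1, lambda1 = lambda1,
                 gamma2 = gamma2, lambda2 = lambda2, rho = rho),
            class = "mixture_weibull")
}

#' @export
print.mixture_weibull <- function(x, ...) {
  cat("Two-component mixture-Weibull mechanism\n")
  cat(sprintf("  component 1: shape %.4g, scale %.4g (weight %.3g)\n",
              x$gamma1, x$lambda1, x$rho))
  cat(sprintf("  component 2: shape %.4g, scale %.4g (weight %.3g)\n",
              x$gamma2, x$lambda2, 1 - x$rho))
  invisible(x)
}

#' Mixture-Weibull survival function
#'
#' Closed-form survival probability of the mixture mechanism.
#'
#' @param t Vector of times in years, all >= 0.
#' @param params A [mixture_weibull()] parameter object.
#' @return Survival probabilities in \[0, 1\], one per element of `t`.
#' @export
mixture_survival <- function(t, params = mixture_weibull()) {
  stopifnot(inherits(params, "mixture_weibull"), is.numeric(t))
  if (any(t < 0)) stop("'t' must be non-negative")
  params$rho * exp(-params$lambda1 * t^params$gamma1) +
    (1 - params$rho) * exp(-params$lambda2 * t^params$gamma2)
}

#' Mixture-Weibull hazard function
#'
#' Closed-form hazard of the mixture mechanism: the mixture density divided
#' by the mixture survival, equal to \eqn{-\mathrm{d}\log S(t)/\mathrm{d}t}.
#' The hazard is only defined for strictly positive times (the default
#' mechanism's hazard tends to 0 as t tends to 0+ but that limit is not
#' returned).
#'
#' @inheritParams mixture_survival
#' @param t Vector of times in years, all > 0.
#' @return Hazard rates (per year, >= 0), one per element of `t`.
#' @export
mixture_hazard <- function(t, params = mixture_weibull()) {
  stopifnot(inherits(params, "mixture_weibull"), is.numeric(t))
  if (any(t <= 0)) stop("'t' must be strictly positive")
  num <- params$lambda1 * params$gamma1 * t^(params$gamma1 - 1) *
    params$rho * exp(-params$lambda1 * t^params$gamma1) +
    params$lambda2 * params$gamma2 * t^(params$gamma2 - 1) *
    (1 - params$rho) * exp(-params$lambda2 * t^params$gamma2)
  num / mixture_survival(t, params)
}

#' True log-hazard curve of the mechanism
#'
#' Convenience wrapper returning the estimand — the natural log of the
#' time-varying hazard — as a [hazard_curve].
#'
#' @inheritParams mixture_hazard
#' @param grid Strictly positive, strictly increasing time grid.
#' @return A [hazard_curve] with the true log-hazard.
#' @export
true_log_hazard <- function(grid, params = mixture_weibull()) {
  hazard_curve(grid, log(mixture_hazard(grid, params)))
}

#' Stationary points of the mixture hazard
#'
#' Locates all interior stationary points (turning points) of the mixture
#' hazard on an interval by scanning a fine grid for sign changes of the
#' central-difference derivative, then refining each bracketed root with
#' [stats::uniroot()].
#'
#' @inheritParams mixture_hazard
#' @param interval Length-2 numeric, `0 < interval[1] < interval[2]`.
#' @param n_grid Number of grid points for the sign-change scan.
#' @return Ascending numeric vector of turning-point times (possibly empty).
#' @examples
#' hazard_turning_points(mixture_weibull())
#' @export
hazard_turning_points <- function(params = mixture_weibull(),
                                  interval = c(0.01, 4),
                                  n_grid = 4000L) {
  stopifnot(length(interval) == 2L, interval[1] > 0,
            interval[2] > interval[1])
  dh <- function(t) {
    eps <- 1e-6
    (mixture_hazard(t + eps, params) - mixture_hazard(t - eps, params)) /
      (2 * eps)
  }
  grid <- seq(interval[1], interval[2], length.out = n_grid)
  d <- dh(grid)
  flips <- which(d[-length(d)] * d[-1] < 0)
  vapply(flips, function(i) {
    stats::uniroot(dh, c(grid[i], grid[i + 1]), tol = 1e-12)$root
  }, numeric(1))
}

#' Simulation scenario description
#'
#' A scenario is a sample size together with an administrative-censoring
#' (follow-up) time.  The nine study scenarios cross sample sizes
#' 100/300/600 with follow-up 2/3/4 years; arbitrary positive values are
#' accepted for extensions.
#'
#' @param sample_size Number of subjects (positive integer).
#' @param follow_up Administrative censoring time in years (> 0, may be
#'   `Inf` for no censoring).
#' @param label Optional text label.
#' @param id Optional integer id used in the deterministic seed stream of
#'   [run_scenario()].
#' @return An object of class `scenario`.
#' @seealso [scenarios()] for the nine study scenarios.
#' @export
scenario <- function(sample_size, follow_up, label = NULL, id = 0L) {
  stopifnot(length(sample_size) == 1L, sample_size >= 1,
            length(follow_up) == 1L, follow_up > 0)
  if (is.null(label))
    label <- sprintf("n=%d, follow-up %g years", as.integer(sample_size),
                     follow_up)
  structure(list(sample_size = as.integer(sample_size),
                 follow_up = follow_up, label = label, id = as.integer(id)),
            class = "scenario")
}

#' The nine study scenarios
#'
#' Sample sizes 100 (small), 300 (medium) and 600 (large) crossed with
#' follow-up of 2, 3 and 4 years.  Under the default mechanism the true
#' survival at those follow-up times is 46.8%, 43.3% and 39.2%.
#'
#' @return A data frame with columns `id`, `sample_size`, `follow_up`,
#'   `label`.
#' @export
scenarios <- function() {
  fu <- rep(c(2, 3, 4), each = 3)
  n <- rep(c(100L, 300L, 600L), times = 3)
  data.frame(
    id = 1:9,
    sample_size = n,
    follow_up = fu,
    label = sprintf("%s follow-up, %s sample size",
                    rep(c("short", "medium", "long"), each = 3),
                    rep(c("small", "medium", "large"), times = 3)),
    stringsAsFactors = FALSE
  )
}

#' Right-censored survival dataset
#'
#' Thin constructor/validator for individual-level right-censored data:
#' positive observation times and 0/1 event indicators.
#'
#' @param time Positive event or censoring times (years).
#' @param event Event indicators: 1 = event (death), 0 = censored.
#' @param follow_up Optional administrative censoring time carried as an
#'   attribute (used by interval-based fitters as the default upper limit).
#' @return A data frame of class `survival_data` with columns `time` and
#'   `event`.
#' @export
survival_data <- function(time, event, follow_up = NULL) {
  stopifnot(length(time) == length(event))
  if (any(!is.finite(time)) || any(time <= 0))
    stop("all times must be positive and finite")
  if (!all(event %in% c(0, 1)))
    stop("'event' must contain only 0 (censored) and 1 (event)")
  out <- data.frame(time = as.numeric(time), event = as.integer(event))
  class(out) <- c("survival_data", "data.frame")
  attr(out, "follow_up") <- follow_up
  out
}

#' Simulate a right-censored cohort from the mixture mechanism
#'
#' Each subject's latent component is drawn with probability `rho`, the
#' event time is drawn from that component by inverse-transform sampling
#' (\eqn{(-\log U/\Lambda)^{1/\gamma}}), and observation is administratively
#' censored at the scenario's follow-up time.
#'
#' @param scen A [scenario()] object.
#' @param params A [mixture_weibull()] parameter object.
#' @param seed Integer seed; identical seeds reproduce the dataset exactly.
#' @return A [survival_data()] frame of `scen$sample_size` rows.
#' @examples
#' d <- simulate_cohort(scenario(100, 2), seed = 1)
#' mean(d$event == 0)  # censored fraction, about 46.8% on average
#' @export
simulate_cohort <- function(scen, params = mixture_weibull(), seed = NULL) {
  stopifnot(inherits(scen, "scenario"), inherits(params, "mixture_weibull"))
  if (!is.null(seed)) set.seed(seed)
  n <- scen$sample_size
  comp1 <- stats::runif(n) < params$rho
  u <- stats::runif(n)
  gam <- ifelse(comp1, params$gamma1, params$gamma2)
  lam <- ifelse(comp1, params$lambda1, params$lambda2)
  tt <- (-log(u) / lam)^(1 / gam)
  event <- as.integer(tt <= scen$follow_up)
  time <- pmin(tt, scen$follow_up)
  survival_data(time, event, follow_up = scen$follow_up)
}
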