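# Dynamic survival models: discrete-time hazard state-space models that
# extend the linear-Weibull log-hazard (intercept + slope on log-time) by
# letting the slope ("trend") — and optionally the intercept ("level") —
# evolve as random walks across time intervals.  The damped variant
# multiplies the trend by a factor phi in (0,1), estimated from the data,
# so extrapolated trends decay geometrically to zero and forecasts level
# off.  Posterior sampling is done with JAGS via rjags.

.dsm_model_string <- function(level, trend, fixed) {
  lines <- c(
    "model {",
    "  for (j in 1:J) {",
    "    events[j] ~ dpois(mu[j])",
    "    mu[j] <- exposure[j] * exp(alpha[parent[j]] + beta[parent[j]] * lt[j])",
    "  }",
    "  alpha[1] ~ dnorm(0, 0.01)",
    "  beta[1] ~ dnorm(0, 0.01)")
  # trend state
  if (isTRUE(fixed$static_trend)) {
    lines <- c(lines,
      "  for (k in 2:K) { beta[k] <- phi * beta[k-1] }")
  } else {
    lines <- c(lines,
      "  for (k in 2:K) { beta[k] ~ dnorm(phi * beta[k-1], tau_trend) }")
    if (is.null(fixed$sd_trend)) {
      lines <- c(lines,
        "  sd_trend ~ dnorm(0, pow(sd_trend_scale, -2)) T(0,)",
        "  tau_trend <- pow(sd_trend, -2)")
    } else {
      lines <- c(lines, "  tau_trend <- pow(sd_trend, -2)")
    }
  }
  # damping factor
  if (trend == "local") {
    lines <- c(lines, "  phi <- 1")
  } else if (!is.null(fixed$phi)) {
    # phi supplied in the data list
  } else {
    lines <- c(lines, "  phi ~ dbeta(phi_a, phi_b)")
  }
  # level state
  if (level == "global" || isTRUE(fixed$static_level)) {
    lines <- c(lines, "  for (k in 2:K) { alpha[k] <- alpha[k-1] }")
  } else {
    lines <- c(lines,
      "  for (k in 2:K) { alpha[k] ~ dnorm(alpha[k-1], tau_level) }")
    if (is.null(fixed$sd_level)) {
      lines <- c(lines,
        "  sd_level ~ dnorm(0, pow(sd_level_scale, -2)) T(0,)",
        "  tau_level <- pow(sd_level, -2)")
    } else {
      lines <- c(lines, "  tau_level <- pow(sd_level, -2)")
    }
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' Fit a dynamic survival model
#'
#' Discretises the data onto an equal-width interval grid
#' (occurrence/exposure form) and fits, by MCMC, the observation model
#' \deqn{y_k \sim \mathrm{Poisson}(E_k \exp(\alpha_k + \beta_k \log t_k))}
#' (with \eqn{t_k} the interval midpoint) under state evolution
#' \eqn{\beta_k = \phi\,\beta_{k-1} + \epsilon_k} and, for a local level,
#' \eqn{\alpha_k = \alpha_{k-1} + \eta_k}.  A local trend fixes
#' \eqn{\phi = 1}; a damped trend estimates \eqn{\phi \in (0,1)}.  With
#' innovation scales at zero, a damping of 1 and a global level the model
#' reduces to a Bayesian linear-Weibull fit.
#'
#' Priors: half-normal scales on the innovation standard deviations, a
#' Beta prior on \eqn{\phi} centred near 0.9, and diffuse normal priors on
#' the initial states; all configurable via `priors`.  Innovation
#' standard deviations fixed below 1e-6 are treated as exactly zero (the
#' corresponding state is held static), which both defines the degenerate
#' limit and avoids sampling a near-degenerate random walk.
#'
#' @param data A [survival_data()] frame.
#' @param trend `"damped"` (phi estimated in (0,1)) or `"local"` (phi = 1).
#' @param level `"global"` (constant intercept) or `"local"` (random-walk
#'   intercept).
#' @param interval_width Discretisation width in years (default 0.1).
#' @param priors List with elements `sd_trend_scale`, `sd_level_scale`
#'   (half-normal scales) and `phi_a`, `phi_b` (Beta parameters).
#' @param fixed Optional list fixing `phi`, `sd_trend` and/or `sd_level`
#'   at given values instead of estimating them.
#' @param n_iter,n_burn,n_adapt,thin MCMC run lengths.
#' @param seed Integer seed for the sampler (full-pipeline reproducibility).
#' @return A `hazard_fit` (subclass `dsm_fit`) carrying posterior draws of
#'   the states, innovation scales and damping factor, plus effective
#'   sample size diagnostics.  Sampler failure yields a flagged failure.
#' @export
fit_dsm <- function(data, trend = c("damped", "local"),
                    level = c("global", "local"),
                    interval_width = 0.1,
                    priors = list(), fixed = list(),
                    n_iter = 2000L, n_burn = 500L, n_adapt = 500L,
                    thin = 2L, seed = 1L) {
  trend <- match.arg(trend)
  level <- match.arg(level)
  pr <- utils::modifyList(list(sd_trend_scale = 0.2, sd_level_scale = 0.2,
                               phi_a = 18, phi_b = 2), priors)
  follow_up <- attr(data, "follow_up") %||% max(data$time)
  if (!is.finite(follow_up)) follow_up <- max(data$time)
  if (interval_width > follow_up)
    stop("'interval_width' exceeds the follow-up limit")
  K <- as.integer(ceiling(follow_up / interval_width - 1e-9))
  if (K < 5L) stop("need at least 5 state intervals")
  label <- sprintf("DSM (%s trend, %s level)", trend, level)

  # Observation layer: a log-uniform sub-grid refined below the first
  # event time, each row tied to the state pair of its parent equal-width
  # interval.  This keeps the state process on the coarse grid while the
  # Poisson device stays accurate near t = 0.
  t_floor <- min(data$time) * 1e-3
  m <- ceiling(log(follow_up / t_floor) / 0.15)
  cuts <- sort(unique(c(exp(seq(log(t_floor), log(follow_up),
                                length.out = m + 1L)),
                        interval_width * seq_len(K))))
  cuts <- cuts[cuts < max(data$time) - 1e-12]
  obs <- aggregate_intervals(split_time(data, cuts), cuts)
  obs$tref <- ifelse(obs$start == 0, obs$stop / exp(1),
                     sqrt(obs$start * obs$stop))
  obs$parent <- pmin(K, floor(obs$start / interval_width + 1e-9) + 1L)
  if (length(unique(obs$parent[obs$exposure > 0])) < 5L)
    stop("need at least 5 intervals with positive exposure")

  fixed$static_trend <- !is.null(fixed$sd_trend) && fixed$sd_trend < 1e-6
  fixed$static_level <- !is.null(fixed$sd_level) && fixed$sd_level < 1e-6
  jdata <- list(J = nrow(obs), K = K, events = obs$events,
                exposure = obs$exposure, lt = log(obs$tref),
                parent = obs$parent)
  if (!fixed$static_trend) {
    if (is.null(fixed$sd_trend)) jdata$sd_trend_scale <- pr$sd_trend_scale
    else jdata$sd_trend <- fixed$sd_trend
  }
  if (level == "local" && !fixed$static_level) {
    if (is.null(fixed$sd_level)) jdata$sd_level_scale <- pr$sd_level_scale
    else jdata$sd_level <- fixed$sd_level
  }
  if (trend == "damped") {
    if (!is.null(fixed$phi)) jdata$phi <- fixed$phi
    else { jdata$phi_a <- pr$phi_a; jdata$phi_b <- pr$phi_b }
  }

  monitors <- c("alpha", "beta")
  if (trend == "damped" && is.null(fixed$phi)) monitors <- c(monitors, "phi")
  if (!fixed$static_trend && is.null(fixed$sd_trend))
    monitors <- c(monitors, "sd_trend")
  if (level == "local" && !fixed$static_level && is.null(fixed$sd_level))
    monitors <- c(monitors, "sd_level")

  inits <- list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = as.integer(seed))
  draws <- tryCatch({
    model <- rjags::jags.model(
      textConnection(.dsm_model_string(level, trend, fixed)),
      data = jdata, inits = inits, n.chains = 1L, n.adapt = n_adapt,
      quiet = TRUE)
    stats::update(model, n_burn, progress.bar = "none")
    rjags::coda.samples(model, monitors, n.iter = n_iter, thin = thin,
                        progress.bar = "none")
  }, error = function(e) e)
  if (inherits(draws, "error"))
    return(failed_fit("dsm_fit", label, conditionMessage(draws)))

  m <- as.matrix(draws[[1]])
  alpha <- m[, paste0("alpha[", seq_len(K), "]"), drop = FALSE]
  beta <- m[, paste0("beta[", seq_len(K), "]"), drop = FALSE]
  phi_draws <- if (trend == "local") rep(1, nrow(m))
    else if (!is.null(fixed$phi)) rep(fixed$phi, nrow(m))
    else m[, "phi"]
  ess <- c(alpha_K = as.numeric(coda::effectiveSize(alpha[, K])),
           beta_K = as.numeric(coda::effectiveSize(beta[, K])))

  fit <- new_hazard_fit(
    "dsm_fit", label,
    parameters = c(alpha = mean(alpha[, K]), beta = mean(beta[, K]),
                   phi = mean(phi_draws)),
    loglik = NA_real_, n_par = NA_real_, n_obs = nrow(data),
    predict_fn = NULL, converged = TRUE,
    extra = list(trend = trend, level = level, alpha_draws = alpha,
                 beta_draws = beta, phi_draws = phi_draws,
                 K = K, interval_width = interval_width,
                 follow_up = K * interval_width, ess = ess))
  fit$predict_fn <- function(times) .dsm_predict(fit, times)
  fit
}

# Posterior log-hazard at arbitrary positive times.  In-sample times use
# the states of the containing interval; forecast times use the final
# level and a trend forecast beta_{K+h} = phi^h * beta_K (phi = 1 for the
# local trend).  The point summary is the posterior mean of log-hazard,
# with a central 90% band.
.dsm_predict <- function(fit, times) {
  K <- fit$K
  w <- fit$interval_width
  last_stop <- K * w
  est <- lo <- hi <- numeric(length(times))
  for (i in seq_along(times)) {
    t <- times[i]
    if (t <= last_stop + 1e-9) {
      k <- max(1L, min(K, as.integer(ceiling(t / w - 1e-9))))
      a <- fit$alpha_draws[, k]
      b <- fit$beta_draws[, k]
    } else {
      h <- ceiling((t - last_stop) / w - 1e-9)
      a <- fit$alpha_draws[, K]
      b <- fit$phi_draws^h * fit$beta_draws[, K]
    }
    lh <- a + b * log(t)
    est[i] <- mean(lh)
    qq <- stats::quantile(lh, c(0.05, 0.95), names = FALSE)
    lo[i] <- qq[1]; hi[i] <- qq[2]
  }
  hazard_curve(times, est, lower = lo, upper = hi)
}

#' Extrapolate a fitted dynamic survival model
#'
#' Forecasts the posterior log-hazard path over a grid extending to the
#' requested horizon: the level is held at its final in-sample value and
#' the trend is forecast as \eqn{\beta_{K+h} = \phi^h \beta_K} per
#' posterior draw (constant for the local trend, geometrically damped
#' otherwise), then summarised by the posterior mean at each grid time.
#'
#' @param fit A converged `dsm_fit`.
#' @param horizon Forecast horizon in years (must exceed the fitted
#'   follow-up).
#' @param grid Time grid in (0, horizon]; defaults to steps of the fitted
#'   interval width.
#' @return A [hazard_curve] with a 90% posterior band.
#' @export
extrapolate_dsm <- function(fit, horizon, grid = NULL) {
  stopifnot(inherits(fit, "dsm_fit"), is_converged(fit))
  if (horizon <= fit$follow_up)
    stop("'horizon' must exceed the fitted follow-up")
  if (is.null(grid))
    grid <- seq(fit$interval_width, horizon, by = fit$interval_width)
  if (any(grid <= 0) || any(grid > horizon + 1e-9))
    stop("grid must lie in (0, horizon]")
  predict(fit, grid)
}

#' Geometric damped-trend forecast
#'
#' The trend forecast after `steps` intervals: `phi^steps * trend`
#' (`phi = 1` reproduces the undamped local trend).
#'
#' @param trend Final in-sample trend value.
#' @param phi Damping factor in (0, 1].
#' @param steps Number of forecast intervals (>= 0).
#' @return The forecast trend value.
#' @export
forecast_trend <- function(trend, phi, steps) {
  stopifnot(phi > 0, phi <= 1, steps >= 0)
  phi^steps * trend
}
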