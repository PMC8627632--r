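# Fractional-polynomial hazard models: global regressions of log-hazard on
# one or two fractional powers of time, fitted through the
# piecewise-exponential Poisson device on a fine equal-width split grid so
# that all specifications share one approximate likelihood and AIC scale.

.fp_powers <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

#' Enumerate fractional-polynomial specifications
#'
#' First-order specifications use one power from
#' \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\} (8 models); second-order
#' specifications use an unordered pair from the same set with repetition
#' allowed (36 models).  Power 0 denotes the log transform; a repeated
#' power p contributes the pair \eqn{t^p} and \eqn{t^p \log t}.
#'
#' @param order 1 or 2.
#' @return A list of numeric power vectors (length 1 or 2).
#' @examples
#' length(enumerate_fp_specs(1))  # 8
#' length(enumerate_fp_specs(2))  # 36
#' @export
enumerate_fp_specs <- function(order) {
  if (!order %in% c(1, 2)) stop("'order' must be 1 or 2")
  if (order == 1) return(lapply(.fp_powers, function(p) p))
  out <- list()
  for (i in seq_along(.fp_powers))
    for (j in i:length(.fp_powers))
      out[[length(out) + 1L]] <- c(.fp_powers[i], .fp_powers[j])
  out
}

# Design matrix of the fractional-polynomial basis at times t.
fp_basis <- function(t, powers) {
  g <- function(p) if (p == 0) log(t) else t^p
  if (length(powers) == 1L) {
    m <- cbind(g(powers))
  } else if (powers[1] == powers[2]) {
    m <- cbind(g(powers[1]), g(powers[1]) * log(t))
  } else {
    m <- cbind(g(powers[1]), g(powers[2]))
  }
  colnames(m) <- paste0("g", seq_len(ncol(m)))
  m
}

#' Fit a fractional-polynomial hazard model
#'
#' Fits \eqn{\log \lambda(t) = \beta_0 + \beta_1 g_1(t) (+ \beta_2 g_2(t))}
#' by Poisson regression of interval event counts on the fractional
#' powers of interval-midpoint time, with log-exposure offset, on an
#' equal-width split grid over the observed range.  Divergent fits
#' (separation, non-convergence, unstable coefficients) are returned as
#' flagged failures.
#'
#' @param data A [survival_data()] frame with events.
#' @param powers Numeric vector of one or two powers from the
#'   fractional-polynomial set (see [enumerate_fp_specs()]).
#' @param n_intervals Number of equal-width intervals of the split grid.
#' @return A `hazard_fit` (subclass `fp_fit`).
#' @export
fit_fp <- function(data, powers, n_intervals = 100L) {
  stopifnot(length(powers) %in% c(1L, 2L), all(powers %in% .fp_powers),
            sum(data$event) >= 1)
  pe <- pe_table(data, n_intervals)
  X <- fp_basis(pe$tref, powers)
  # standardise the basis columns for the optimiser (negative powers give
  # huge covariate ranges); coefficients are mapped back afterwards
  ctr <- colMeans(X)
  scl <- pmax(apply(X, 2, stats::sd), 1e-300)
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  df <- data.frame(events = pe$events, Xs, log_exposure = log(pe$exposure))
  form <- stats::as.formula(paste(
    "events ~", paste(colnames(X), collapse = " + "), "+ offset(log_exposure)"))
  label <- sprintf("FP(%d) powers (%s)", length(powers),
                   paste(powers, collapse = ", "))
  fit <- tryCatch(
    suppressWarnings(stats::glm(form, family = stats::poisson(), data = df)),
    error = function(e) e
  )
  if (inherits(fit, "error"))
    return(failed_fit("fp_fit", label, conditionMessage(fit)))
  cfs <- stats::coef(fit)
  if (!fit$converged || any(!is.finite(cfs)) || any(abs(cfs[-1]) > 1e3))
    return(failed_fit("fp_fit", label, "divergent coefficients"))
  cf <- c(cfs[1] - sum(cfs[-1] * ctr / scl), cfs[-1] / scl)
  names(cf) <- c("(Intercept)", colnames(X))
  predict_fn <- function(times) {
    eta <- cf[1] + drop(fp_basis(times, powers) %*% cf[-1])
    hazard_curve(times, pmin(pmax(eta, -700), 700))
  }
  new_hazard_fit("fp_fit", label, cf, as.numeric(stats::logLik(fit)),
                 length(cf), nrow(data), predict_fn,
                 extra = list(powers = powers, glm_fit = fit))
}

#' Fit and select within a fractional-polynomial class
#'
#' Fits every specification of the given order and selects the converged
#' fit with the lowest information criterion.  FP(1) and FP(2) are kept as
#' separate classes.
#'
#' @inheritParams fit_fp
#' @param order 1 or 2.
#' @param criterion `"aic"` or `"bic"`.
#' @return The selected `hazard_fit`, with all candidates attached as
#'   attribute `"candidates"`.
#' @export
fit_fp_best <- function(data, order, n_intervals = 100L, criterion = "aic") {
  specs <- enumerate_fp_specs(order)
  fits <- lapply(specs, function(p) fit_fp(data, p, n_intervals))
  best <- select_best(fits, criterion)
  attr(best, "candidates") <- fits
  best
}
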