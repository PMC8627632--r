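test_that("censored log-likelihood matches closed forms and nests", {
  d <- survival_data(c(1, 2, 3), c(1, 1, 0))
  # exponential: 2 log(rate) - 6 rate
  for (r in c(0.2, 1 / 3, 0.9)) {
    expect_equal(censored_log_likelihood("exponential", c(log_rate = log(r)), d),
                 2 * log(r) - 6 * r)
  }
  # Weibull with shape 1 reproduces the exponential exactly
  for (r in c(0.2, 0.7)) {
    expect_equal(
      censored_log_likelihood("weibull",
                              c(log_shape = 0, log_scale = log(1 / r)), d),
      censored_log_likelihood("exponential", c(log_rate = log(r)), d))
  }
  expect_error(censored_log_likelihood("exponential", c(log_rate = NaN), d),
               "finite")
})

test_that("censored log-likelihood equals an independent per-term oracle", {
  d <- fix_cohort(80, 2, seed = 11)
  sh <- 1.3; sc <- 2.1
  # oracle: Weibull hazard/survival written out directly, term by term
  terms <- vapply(seq_len(nrow(d)), function(i) {
    t <- d$time[i]
    log_h <- log(sh / sc) + (sh - 1) * log(t / sc)
    log_S <- -(t / sc)^sh
    d$event[i] * log_h + log_S
  }, numeric(1))
  ll <- censored_log_likelihood(
    "weibull", c(log_shape = log(sh), log_scale = log(sc)), d)
  expect_equal(ll, sum(terms), tolerance = 1e-12)
})

test_that("maximum-likelihood fits recover closed-form and true parameters", {
  d <- survival_data(c(1, 2, 3), c(1, 1, 0))
  f <- fit_parametric(d, "exponential")
  expect_equal(unname(coef(f)["rate"]), 1 / 3, tolerance = 1e-5)
  expect_equal(f$log_likelihood,
               censored_log_likelihood("exponential",
                                       c(log_rate = log(1 / 3)), d),
               tolerance = 1e-6)
  # large-sample recovery of the second mixture component's shape
  dw <- fix_weibull_sample(50000)
  fw <- fit_parametric(dw, "weibull")
  expect_equal(unname(coef(fw)["shape"]), 1.4, tolerance = 0.02)
  # bit-reproducible refit
  fw2 <- fit_parametric(dw, "weibull")
  expect_identical(coef(fw), coef(fw2))
})

test_that("generalisations dominate nested families in log-likelihood", {
  d <- fix_cohort(200, 3, seed = 21)
  ll <- function(fam) fit_parametric(d, fam)$log_likelihood
  expect_gte(ll("weibull"), ll("exponential") - 1e-6)
  expect_gte(ll("gamma"), ll("exponential") - 1e-6)
  expect_gte(ll("generalised_gamma"), ll("weibull") - 1e-4)
})

test_that("information criteria are consistent with stored log-likelihoods", {
  d <- fix_cohort(150, 2, seed = 31)
  for (fam in c("exponential", "weibull", "lognormal")) {
    f <- fit_parametric(d, fam)
    expect_equal(f$aic, 2 * f$n_parameters - 2 * f$log_likelihood)
    expect_equal(f$bic,
                 f$n_parameters * log(nrow(d)) - 2 * f$log_likelihood)
    expect_equal(AIC(f), f$aic)
    expect_equal(BIC(f), f$bic)
  }
})

test_that("model selection minimises the criterion with fixed tie-breaks", {
  mk <- function(label, ll, k, n = 100) {
    hazext:::new_hazard_fit("parametric_fit", label, NULL, ll, k, n,
                            function(times) hazard_curve(times, times * 0))
  }
  m1 <- mk("a", -5.2, 1)
  m2 <- mk("b", -6.05, 2)
  expect_identical(select_best(list(m2, m1))$label, "a")
  # equal AIC: 2*1 - 2*ll1 == 2*2 - 2*ll2 when ll2 = ll1 + 1
  t1 <- mk("one_par", -5, 1)
  t2 <- mk("two_par", -4, 2)
  expect_equal(t1$aic, t2$aic)
  expect_identical(select_best(list(t2, t1))$label, "one_par")
  # full tie: first in fixed ordering wins
  t3 <- mk("first", -5, 1)
  t4 <- mk("second", -5, 1)
  expect_identical(select_best(list(t3, t4))$label, "first")
  fail <- hazext:::failed_fit("parametric_fit", "bad", "no")
  expect_identical(select_best(list(fail, m1))$label, "a")
  expect_error(select_best(list(fail)), "no converged")
})

test_that("selection is consistent on data simulated from the smaller family", {
  set.seed(77)
  d <- survival_data(rexp(4000, 0.5), rep(1, 4000))
  fits <- list(fit_parametric(d, "exponential"), fit_parametric(d, "weibull"))
  expect_identical(select_best(fits)$label, "exponential")
})

test_that("predicted log-hazards have the family's shape", {
  d <- fix_cohort(200, 3, seed = 41)
  grid <- exp(seq(log(0.2), log(8), length.out = 50))
  # exponential: constant at log(rate)
  fe <- fit_parametric(d, "exponential")
  pe <- predict(fe, grid)
  expect_equal(pe$log_hazard, rep(log(unname(coef(fe)["rate"])), 50),
               tolerance = 1e-6)
  # Weibull: linear in log-time with slope shape - 1
  fw <- fit_parametric(d, "weibull")
  pw <- predict(fw, grid)
  sl <- coef(lm(pw$log_hazard ~ log(grid)))[2]
  expect_equal(unname(sl), unname(coef(fw)["shape"]) - 1, tolerance = 1e-6)
  # lognormal: non-monotone, rises then falls
  fl <- fit_parametric(d, "lognormal")
  pl <- predict(fl, exp(seq(log(0.01), log(50), length.out = 400)))
  s <- sign(diff(pl$log_hazard))
  expect_equal(s[1], 1)
  expect_equal(s[length(s)], -1)
  expect_error(predict(fw, c(-1, 2)), "positive")
})

test_that("current-practice selection excludes Gompertz unless asked", {
  d <- fix_cohort(150, 3, seed = 51)
  best <- fit_current_practice(d)
  cands <- attr(best, "candidates")
  expect_named(cands, parametric_families())
  expect_false(best$label == "gompertz")
  aics <- vapply(cands[setdiff(names(cands), "gompertz")],
                 function(f) if (is_converged(f)) f$aic else Inf, numeric(1))
  expect_equal(best$aic, min(aics))
})
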