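test_that("mixture survival matches closed-form values and boundary", {
  p <- mixture_weibull()
  expect_equal(mixture_survival(0, p), 1)
  expect_equal(round(mixture_survival(2, p), 3), 0.468)
  expect_equal(round(mixture_survival(3, p), 3), 0.433)
  expect_equal(round(mixture_survival(4, p), 3), 0.392)
  # frozen from direct closed-form evaluation, cross-checked by
  # numerically integrating the hazard and exponentiating
  expect_equal(mixture_survival(1, p), 0.5403, tolerance = 5e-4)
  h_int <- integrate(function(u) mixture_hazard(u, p), 0, 1,
                     rel.tol = 1e-10)$value
  expect_equal(exp(-h_int), mixture_survival(1, p), tolerance = 1e-7)
  expect_error(mixture_survival(-1, p), "non-negative")
})

test_that("survival is non-increasing and hazard is its negative log-derivative", {
  p <- mixture_weibull()
  grid <- exp(seq(log(0.01), log(10), length.out = 200))
  s <- mixture_survival(grid, p)
  expect_true(all(diff(s) < 0))
  eps <- 1e-6
  dlogS <- (log(mixture_survival(grid + eps, p)) -
            log(mixture_survival(grid - eps, p))) / (2 * eps)
  h <- mixture_hazard(grid, p)
  expect_true(all(h >= 0))
  expect_equal(h, -dlogS, tolerance = 1e-6)
  expect_error(mixture_hazard(0, p), "positive")
})

test_that("degenerate mixing weights reduce to single-Weibull closed forms", {
  for (r in c(0, 1)) {
    p <- mixture_weibull(rho = r)
    gam <- if (r == 1) p$gamma1 else p$gamma2
    lam <- if (r == 1) p$lambda1 else p$lambda2
    t <- c(0.3, 1, 2.7)
    expect_equal(mixture_survival(t, p), exp(-lam * t^gam))
    expect_equal(mixture_hazard(t, p), lam * gam * t^(gam - 1))
  }
})

test_that("parameter validation rejects invalid mechanisms", {
  expect_error(mixture_weibull(gamma1 = -1), "positive")
  expect_error(mixture_weibull(rho = 1.5), "rho")
})

test_that("turning-point search finds the hazard's stationary points", {
  tp <- hazard_turning_points(mixture_weibull(), c(0.01, 4))
  expect_length(tp, 2)
  # frozen from an independent uniroot refinement of the central-difference
  # derivative of the closed-form hazard
  expect_equal(tp, c(0.32675, 2.13360), tolerance = 1e-3)
  # derivative vanishes at the refined roots
  eps <- 1e-5
  dh <- (mixture_hazard(tp + eps) - mixture_hazard(tp - eps)) / (2 * eps)
  expect_true(all(abs(dh) < 1e-8))
  # first is a local maximum, second a local minimum
  h <- mixture_hazard(c(tp[1] - 0.05, tp[1], tp[1] + 0.05))
  expect_true(h[2] > h[1] && h[2] > h[3])
  # monotone single-Weibull hazard has no turning points
  expect_length(hazard_turning_points(mixture_weibull(rho = 0), c(0.01, 4)), 0)
})

test_that("cohort simulation is reproducible and censors administratively", {
  sc <- scenario(100, 2, id = 1)
  d1 <- simulate_cohort(sc, seed = 7)
  d2 <- simulate_cohort(sc, seed = 7)
  d3 <- simulate_cohort(sc, seed = 8)
  expect_identical(d1, d2)
  expect_false(identical(d1$time, d3$time))
  expect_equal(nrow(d1), 100)
  expect_true(all(d1$time[d1$event == 0] == 2))
  expect_true(all(d1$time <= 2))
  # no administrative censoring at infinite follow-up
  d_inf <- simulate_cohort(scenario(200, Inf), seed = 1)
  expect_true(all(d_inf$event == 1))
})

test_that("censored fraction matches the true survival at follow-up", {
  sc <- scenario(100, 2, id = 1)
  cens <- vapply(1:30, function(r) {
    mean(simulate_cohort(sc, seed = 100 + r)$event == 0)
  }, numeric(1))
  expect_equal(mean(cens), 0.468, tolerance = 0.03)
})
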