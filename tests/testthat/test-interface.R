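test_that("the IPD adapter validates, filters and groups delimited text", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("time,event", "1,1", "2,1", "3,0"), path)
  d <- read_ipd(path)
  expect_s3_class(d, "survival_data")
  expect_equal(nrow(d), 3)
  expect_equal(sum(d$event), 2)
  # non-positive times are rejected and counted
  writeLines(c("time,event", "0,1", "1.5,1", "-2,0", "2,0"), path)
  expect_message(d2 <- read_ipd(path), "2 row")
  expect_equal(nrow(d2), 2)
  expect_equal(attr(d2, "n_rejected"), 2)
  # grouped files partition into per-arm datasets
  writeLines(c("time,event,arm", "1,1,a", "2,0,a", "0.5,1,b"), path)
  g <- read_ipd(path, group_col = "arm")
  expect_named(g, c("a", "b"))
  expect_equal(nrow(g$a) + nrow(g$b), 3)
  expect_error(read_ipd(path, time_col = "missing"), "missing column")
  # round trip through the writer
  out <- tempfile(fileext = ".csv")
  write_ipd(g$a, out)
  expect_equal(read_ipd(out)$time, g$a$time)
})

test_that("study configuration round-trips through JSON without loss", {
  cfg <- study_config(classes = c("current_practice", "gam"),
                      n_replicates = 7, base_seed = 123, horizon = 8,
                      grid_step = 0.1, include_gompertz = TRUE,
                      scenario_ids = c(1L, 5L))
  path <- tempfile(fileext = ".json")
  write_config(cfg, path)
  expect_equal(read_config(path), cfg)
})

test_that("a run manifest records version, seed and configuration", {
  cfg <- study_config(n_replicates = 2)
  path <- tempfile(fileext = ".json")
  write_manifest(cfg, path)
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(m$package, "hazext")
  expect_equal(m$config$base_seed, 1)
  expect_equal(m$config$n_replicates, 2)
})

test_that("the smoothed nonparametric hazard tracks the truth loosely", {
  d <- fix_cohort(20000, 3, seed = 23)
  sm <- smoothed_hazard(d, bandwidth = 0.15)
  expect_s3_class(sm, "hazard_curve")
  mid <- sm$time > 0.5 & sm$time < 2.5
  truth <- log(mixture_hazard(sm$time[mid]))
  expect_lt(mean(abs(sm$log_hazard[mid] - truth)), 0.25)
})

test_that("the case-study workflow reports per-candidate criteria and curves", {
  d <- fix_cohort(200, 2, seed = 29)
  cfg <- study_config(classes = "current_practice", horizon = 5,
                      grid_step = 0.25)
  cs <- run_case_study(list(arm_a = d), cfg, late_arms = list(arm_a = d))
  a <- cs$arm_a
  expect_named(a$fits, "current_practice")
  expect_equal(sort(unique(a$ic_table$model)), sort(parametric_families()))
  expect_true(all(is.finite(a$ic_table$aic[a$ic_table$converged])))
  expect_s3_class(a$curves$current_practice, "hazard_curve")
  expect_equal(max(a$curves$current_practice$time), 5)
  expect_s3_class(a$late_hazard, "hazard_curve")
})

test_that("spline selection on Weibull data recovers the 0-knot model", {
  d <- fix_weibull_sample(2000, seed = 9, censor_at = 6)
  best <- fit_rpm_best(d)
  expect_equal(best$n_internal_knots, 0)
  expect_equal(best$scale, "hazard")
})
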