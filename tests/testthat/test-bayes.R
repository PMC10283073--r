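# the random-walk sampler needs its full default chain length for a
# comfortable split-R-hat margin; only the seed varies across tests
quick_config <- function(seed) sampler_config(seed = seed)

test_that("bounded MCMC is deterministic and recovers lim on strong data", {
  ds <- simulate_trials(uniform_design(60, n_per_power = 2000),
                        bounded_target_truth(), seed = 42)
  fit <- fit_bounded_mcmc(ds, "target", "bounded",
                          config = quick_config(7))
  expect_lt(abs(fit$medians[["lim"]] - 0.40), 0.05)
  expect_true(all(fit$rhat < 1.01))
  expect_true(all(fit$ess > 200))
  # identical seed, identical draws
  fit2 <- fit_bounded_mcmc(ds, "target", "bounded",
                           config = quick_config(7))
  expect_identical(fit$samples, fit2$samples)
  expect_identical(fit$medians, fit2$medians)
  # medians are the marginal 50th percentiles of the draws
  expect_equal(fit$medians[["a"]], median(fit$samples$a))
})

test_that("with lim = 1 truth the bounded fit approaches the simple MLE curve", {
  truth <- bounded_target_truth(lim = 1, a = 0.8, b = -8)
  ds <- simulate_trials(uniform_design(60, n_per_power = 400), truth,
                        seed = 5)
  fit <- fit_bounded_mcmc(ds, "target", "bounded", config = quick_config(3))
  expect_gt(fit$medians[["lim"]], 0.9)
  mle <- fit_logistic(ds, "target")
  xs <- seq(5.5, 20, by = 0.5)
  gap <- max(abs(predict(fit$curve_at_medians, xs) -
                 predict(mle$curve, xs)))
  expect_lt(gap, 0.05)
})

test_that("posterior medians round-trip through parameters and serialization", {
  samples <- data.frame(lim = c(0.3, 0.4, 0.5), a = c(1, 1, 1),
                        b = c(-9, -10, -11), chain = 1L)
  expect_equal(median(samples$lim), 0.4)
  ds <- simulate_trials(uniform_design(60, n_per_power = 300),
                        bounded_target_truth(), seed = 8)
  fit <- fit_bounded_mcmc(ds, "target", "bounded", config = quick_config(2))
  params <- posterior_median_params(fit)
  expect_s3_class(params, "irdose_params")
  expect_equal(params$lim, median(fit$samples$lim))
  path <- withr::local_tempfile(fileext = ".json")
  curve_to_json(fit$curve_at_medians, path)
  expect_equal(curve_from_json(path)$params, params)
})

test_that("bounded MLE is a consistent oracle for the MCMC medians", {
  ds <- simulate_trials(uniform_design(60, n_per_power = 1000),
                        bounded_target_truth(), seed = 77)
  mle <- fit_bounded_mle(ds, "target", "bounded")
  expect_lt(abs(mle$curve$params$lim - 0.40), 0.05)
  expect_false(mle$boundary_flag)
  mc <- fit_bounded_mcmc(ds, "target", "bounded", config = quick_config(9))
  xs <- seq(5.5, 20, by = 0.5)
  gap <- max(abs(predict(mc$curve_at_medians, xs) - predict(mle$curve, xs)))
  expect_lt(gap, 0.05)
})

test_that("plateau-free data pushes the bounded MLE limit to the boundary", {
  # all design powers sit in the rising phase: inflection at 24 mW, well
  # above the 5.5-20 mW span, so lim is unidentified
  truth <- bounded_target_truth(lim = 0.9, a = 0.5, b = -12)
  ds <- simulate_trials(uniform_design(60, n_per_power = 200), truth,
                        seed = 13)
  mle <- fit_bounded_mle(ds, "target", "bounded")
  expect_true(mle$boundary_flag || mle$curve$params$lim > 0.8)
})

test_that("fixing lim at 1 reduces the bounded MLE to the logistic glm fit", {
  ds <- simulate_trials(uniform_design(60, n_per_power = 150),
                        active_truth_60s(), seed = 31)
  fixed <- fit_bounded_mle(ds, "target", "bounded", fix_lim = 1)
  glm_fit <- fit_logistic(ds, "target")
  expect_equal(fixed$curve$params$a, glm_fit$curve$params$a,
               tolerance = 1e-4)
  expect_equal(fixed$curve$params$b, glm_fit$curve$params$b,
               tolerance = 1e-3)
  expect_equal(fixed$loglik, glm_fit$loglik, tolerance = 1e-6)
})

test_that("manual deviance LRT reports df 3 and agrees with the MLE route", {
  # size-dependent truth (valid at any normalized size) so the full
  # model is preferred
  truth <- truth_spec(
    target = response_curve("size", size_params(1.2, -0.8, 0, -10),
                            endpoint = "target", duration = 60),
    neighboring = response_curve("simple", simple_params(0, -35),
                                 endpoint = "neighboring", duration = 60),
    death = response_curve("simple", simple_params(0, -35),
                           endpoint = "death", duration = 60))
  ds <- normalize_cell_size(
    simulate_trials(uniform_design(60, n_per_power = 150), truth, seed = 55))
  full_mle <- fit_bounded_mle(ds, "target", "bounded_size")
  red_mle <- fit_bounded_mle(ds, "target", "bounded")
  res_mle <- lrt_nested(full_mle, red_mle)
  expect_equal(res_mle$df, 3L)

  # oracle identity: identical curves give identical statistics
  res_manual <- manual_lrt(full_mle, red_mle, ds)
  expect_equal(res_manual$statistic, res_mle$statistic, tolerance = 1e-9)
  expect_equal(res_manual$df, res_mle$df)

  # identical full and reduced curves: statistic 0, p = 1
  same <- full_mle$curve
  reduced_same <- response_curve(
    "bounded", bounded_params(same$params$lim, same$params$a1,
                              same$params$b),
    endpoint = "target", duration = 60, size_stats = same$size_stats)
  full_same <- response_curve(
    "bounded_size",
    bounded_size_params(same$params$lim, same$params$a1, 0, 0, 0,
                        same$params$b),
    endpoint = "target", duration = 60, size_stats = same$size_stats)
  res0 <- manual_lrt(full_same, reduced_same, ds)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  expect_error(manual_lrt(red_mle, full_mle, ds), "not nested")
})

test_that("non-convergent chains raise an error carrying diagnostics", {
  ds <- simulate_trials(uniform_design(60, n_per_power = 400),
                        bounded_target_truth(), seed = 2)
  tight <- suppressWarnings(sampler_config(chains = 4L, iterations = 100L,
                                           warmup = 100L, seed = 1,
                                           rhat_threshold = 1.0001,
                                           ess_threshold = 1e5))
  err <- tryCatch(
    fit_bounded_mcmc(ds, "target", "bounded", config = tight),
    irdose_nonconvergence = function(e) e)
  expect_s3_class(err, "irdose_nonconvergence")
  expect_true(all(c("rhat", "ess") %in% names(err)))
})
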