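test_that("curve inversion matches the closed form at anchor responses", {
  fit <- exact_emax_fit(0, 100, 10)
  expect_equal(invert_emax(fit, 50), 10, tolerance = 1e-8) # ED50 definition
  expect_equal(invert_emax(fit, 0), 0, tolerance = 1e-8)
  expect_equal(invert_emax(fit, 20), 2.5, tolerance = 1e-8) # 10 * 20 / 80
})

test_that("inversion round-trips predict for decreasing and increasing curves", {
  set.seed(111)
  for (i in 1:30) {
    b <- runif(1, -5, 5)
    t <- b + sample(c(-1, 1), 1) * runif(1, 1, 100)
    e <- exp(runif(1, log(0.5), log(20)))
    fit <- exact_emax_fit(b, t, e)
    d <- exp(runif(1, log(0.01), log(max(fit$doses))))
    expect_rel_equal(invert_emax(fit, predict(fit, d)), d, 1e-9)
  }
})

test_that("inversion is monotone and fails loudly outside the dynamic range", {
  fit <- exact_emax_fit(0, -8, 5)
  obs <- seq(-0.5, -7, by = -0.5)
  pred <- vapply(obs, function(o) invert_emax(fit, o), numeric(1))
  expect_true(all(diff(pred) > 0)) # deeper hypothermia, larger dose
  expect_error(invert_emax(fit, 0.5), "dynamic range") # beyond Bottom
  expect_error(invert_emax(fit, -9), "dynamic range")  # beyond Top
  expect_error(invert_emax(fit, -8), "dynamic range|infinite")
  # beyond the tested doses: refused by default, allowed up to 2x max dose
  far <- predict(fit, 150)
  expect_error(invert_emax(fit, far), "largest tested dose")
  expect_rel_equal(invert_emax(fit, far, allow_extrapolation = TRUE), 150, 1e-9)
  too_far <- predict(fit, 2.5 * max(fit$doses))
  expect_error(invert_emax(fit, too_far, allow_extrapolation = TRUE), "2x")
  bad <- fit_emax(c(0, 1, 3, 10, 30), rep(1, 5))
  expect_error(invert_emax(bad, 0.5), "non-converged")
})

test_that("aggregation reproduces the across-behavior mean and SEM", {
  agg <- aggregate_predicted(c(10.3, 11.6, 4.5))
  expect_equal(round(agg$mean, 1), 8.8)
  expect_equal(round(agg$sem, 1), 2.2)
  expect_equal(aggregate_predicted(c(7, 7, 7)), list(mean = 7, sem = 0, k = 3))
  expect_equal(aggregate_predicted(c(0, 2))$sem, 1)
  expect_true(is.na(aggregate_predicted(5)$sem))
  expect_error(aggregate_predicted(numeric(0)), "at least one")
  set.seed(121)
  for (i in 1:10) {
    x <- rnorm(sample(2:6, 1), 8, 3)
    agg <- aggregate_predicted(x)
    expect_equal(agg$mean, mean(x), tolerance = 1e-12)
    expect_equal(agg$sem, sd(x) / sqrt(length(x)), tolerance = 1e-12)
  }
})

test_that("fold ratios and report rounding follow the stated conventions", {
  expect_equal(round(fold_ratio(8.8, 3.7), 1), 2.4)
  expect_equal(fold_ratio(5, 5), 1)
  expect_equal(fold_ratio(0, 5), 0)
  expect_error(fold_ratio(1, 0), "> 0")
})

test_that("startle prediction evaluates the polynomial and floors at zero", {
  zero <- fit_startle_polynomial(c(0, 1, 2), c(0, 0, 0))
  expect_equal(predict_startle(zero, 4), 0)
  fit <- fit_startle_polynomial(c(0, 5, 10), c(100, 400, 100))
  expect_equal(predict_startle(fit, 5), 400, tolerance = 1e-9)
  steep <- fit_startle_polynomial(c(0, 5, 10), c(100, 50, 0))
  expect_warning(v <- predict_startle(steep, 15), "floored")
  expect_gte(v, 0)
  expect_error(predict_startle(fit, -1), ">= 0")
})

test_that("within-SEM validation is a symmetric band including the boundary", {
  expect_equal(validate_within_sem(558, 600, 100), "within_sem")
  expect_equal(validate_within_sem(310, 100, 50), "outside_sem")
  expect_equal(validate_within_sem(42, 42, 0), "within_sem")
  expect_error(validate_within_sem(1, 1, -1), ">= 0")
})

test_that("noiseless cohorts round-trip through the whole prediction chain", {
  cfg <- noiseless_config(n = 5L)
  rep <- suppressWarnings(run_pipeline(run_config(simulation = cfg, seed = 12)))
  # ED50s recovered exactly
  truth <- c(locomotion = 1.3, tail_flick = 3.9, temperature = 14.4)
  expect_rel_equal(rep$triad$ed50[names(truth)], truth, 1e-6)
  # oral condition: top E-gel 29.2 mg/kg at oral potency 3.7/29.2 -> 3.7
  expect_rel_equal(rep$equivalence$aggregate_mean, 3.7, 1e-6)
  expect_equal(rep$equivalence$aggregate_sem, 0, tolerance = 1e-6)
  # predicted startle equals the generator quadratic at the true dose
  sp <- triadose:::default_startle_params()
  for (sx in c("male", "female")) {
    truth_v <- sp[[sx]]$a0 + sp[[sx]]$a1 * 3.7 + sp[[sx]]$a2 * 3.7^2
    got <- rep$equivalence$startle[[sx]]$predicted_vmax
    expect_rel_equal(got, truth_v, 1e-6)
  }
})

test_that("equivalence report drops failing behaviors but keeps the rest", {
  fits <- list(
    locomotion = exact_emax_fit(0, -3500, 1.3, doses = c(0, 1, 3, 10, 30)),
    temperature = exact_emax_fit(0, -8.64, 14.4, doses = c(0, 1, 3, 10, 30))
  )
  oral <- c(locomotion = -5000, temperature = -4) # locomotion beyond Top
  expect_warning(repy <- equivalence_report(fits, oral), "locomotion")
  expect_true(is.na(repy$per_behavior_dose[["locomotion"]]))
  expect_equal(repy$k_behaviors, 1)
  expect_rel_equal(repy$aggregate_mean,
                   invert_emax(fits$temperature, -4), 1e-9)
  oral_bad <- c(locomotion = -5000, temperature = -20)
  expect_error(suppressWarnings(equivalence_report(fits, oral_bad)),
               "every behavior")
})

test_that("bootstrap CI for a single behavior brackets the point estimate", {
  set.seed(131)
  doses <- rep(c(0, 1, 3, 10, 30), each = 8)
  y <- emax_predict_curve(doses, 0, -8, 4) + rnorm(length(doses), 0, 0.8)
  oral <- rnorm(8, emax_predict_curve(6, 0, -8, 4), 0.8)
  bt <- bootstrap_predicted_dose(doses, y, oral, reps = 60, seed = 5)
  expect_true(bt$lower <= bt$estimate && bt$estimate <= bt$upper)
  expect_gt(bt$reps_used, 40)
})
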