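test_that("grams_consumed subtracts, clamps, and rejects mass gain", {
  expect_equal(grams_consumed(10.00, 8.10), 1.90)
  expect_equal(grams_consumed(5.00, 5.00), 0.00)
  expect_equal(grams_consumed(5.00, 5.03), 0.00) # within drying tolerance
  expect_error(grams_consumed(4.00, 4.50, tolerance = 0.05), "gained mass")
  expect_error(grams_consumed(0, 1), "positive")
})

test_that("dose conversion follows the concentration/body-mass formula", {
  spec10 <- gelatin_spec("E", "THC", 10)
  expect_equal(dose_mg_per_kg(1.0, spec10, 25), 1.0 * (10 / 15) / 0.025,
               tolerance = 1e-12) # 26.67 mg/kg
  expect_equal(dose_mg_per_kg(1.5, gelatin_spec("CTR", "THC", 2), 25), 8.0)
  expect_equal(dose_mg_per_kg(0, spec10, 25), 0)
  # linear in grams and concentration; inverse in body mass
  d0 <- dose_mg_per_kg(1.2, 5, 25)
  expect_equal(dose_mg_per_kg(2.4, 5, 25), 2 * d0)
  expect_equal(dose_mg_per_kg(1.2, 10, 25), 2 * d0)
  expect_equal(dose_mg_per_kg(1.2, 5, 12.5), 2 * d0)
  expect_error(dose_mg_per_kg(-1, spec10, 25), ">= 0")
  expect_error(gelatin_spec("E", "VEH", 10), "concentration 0")
})

test_that("piecewise rates reproduce the printed intake profiles", {
  s <- piecewise_series(13.0, 4.2)
  r <- piecewise_rates(s$minutes, s$cum)
  expect_equal(r$r1, 13.0, tolerance = 1e-12)
  expect_equal(r$r2, 4.2, tolerance = 1e-12)
  expect_equal(round(r$percent_reduction, 1), 67.7)

  s2 <- piecewise_series(16.3, 9.9)
  r2 <- piecewise_rates(s2$minutes, s2$cum)
  expect_equal(round(r2$percent_reduction, 1), 39.3)

  # constant rate: no reduction
  r3 <- piecewise_rates(seq(0, 120, 10), 5 * seq(0, 120, 10))
  expect_equal(r3$percent_reduction, 0, tolerance = 1e-12)

  expect_error(piecewise_rates(seq(0, 120, 10), rev(seq(0, 120, 10))),
               "nondecreasing")
  expect_error(piecewise_rates(seq(0, 120, 10), seq(0, 120, 10),
                               changepoint = 120), "inside")
})

test_that("rate decomposition conserves total intake on arbitrary series", {
  set.seed(71)
  for (i in 1:25) {
    m <- seq(0, 120, by = 10)
    cum <- cumsum(c(0, runif(12, 0, 50)))
    cp <- sample(seq(10, 110, 10), 1)
    r <- piecewise_rates(m, cum, changepoint = cp)
    expect_equal(r$r1 * cp + r$r2 * (120 - cp), cum[length(cum)],
                 tolerance = 1e-9)
    if (r$r2 <= r$r1 && r$r2 >= 0 && r$r1 > 0) {
      expect_true(r$percent_reduction >= 0 && r$percent_reduction <= 100)
    }
  }
})

test_that("least-squares changepoint search recovers a clean breakpoint", {
  s <- piecewise_series(13.0, 4.2, cp = 40)
  est <- estimate_changepoint(s$minutes, s$cum)
  expect_equal(est$changepoint, 40)
  expect_equal(est$rss, 0, tolerance = 1e-16)
  expect_equal(est$r1, 13.0, tolerance = 1e-9)
})

test_that("non-consumer fraction counts animals at or below threshold", {
  grams <- c(rep(0, 7), runif(10, 0.5, 2))
  expect_equal(nonconsumer_fraction(grams), 7 / 17)
  expect_equal(round(100 * nonconsumer_fraction(grams)), 41)
  expect_equal(nonconsumer_fraction(rep(0, 5)), 1)
  expect_equal(nonconsumer_fraction(c(1, 2, 3)), 0)
  expect_error(nonconsumer_fraction(numeric(0)), "empty")
})
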