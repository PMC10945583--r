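test_that("cohort generation is deterministic given config and seed", {
  cfg <- small_config(n = 4L)
  a <- generate_cohort(cfg, seed = 3)
  b <- generate_cohort(cfg, seed = 3)
  expect_identical(a, b)
  c_ <- generate_cohort(cfg, seed = 4)
  expect_false(identical(a$triad$post, c_$triad$post))
})

test_that("noiseless difference scores sit exactly on the Emax curves", {
  cfg <- noiseless_config(n = 3L)
  co <- generate_cohort(cfg, seed = 9)
  tri <- co$triad
  tri$diff <- tri$post - tri$pre
  ip <- tri[tri$route == "ip", ]
  for (a in names(cfg$assay_params)) {
    p <- cfg$assay_params[[a]]
    sub <- ip[ip$assay == a, ]
    expect_equal(sub$diff,
                 emax_predict_curve(sub$nominal_dose_or_conc,
                                    p$bottom, p$top, p$ed50),
                 tolerance = 1e-12)
  }
  # oral rows respond at oral_potency * consumed dose
  eg <- tri[tri$route == "e_gel" & tri$nominal_dose_or_conc == 10 &
              tri$assay == "temperature", ]
  p <- cfg$assay_params$temperature
  expect_equal(eg$diff,
               emax_predict_curve(eg$consumed_mg_per_kg * cfg$oral_potency,
                                  p$bottom, p$top, p$ed50),
               tolerance = 1e-12)
})

test_that("simulated dosimetry matches the anchored group-mean consumed dose", {
  cfg <- small_config(n = 100L, ip_doses = c(0, 3),
                      gel_concentrations = 10,
                      oral_dose_means = c("10" = 29.2))
  co <- generate_cohort(cfg, seed = 17)
  cons <- co$consumption
  thc <- cons[cons$treatment == "THC" & cons$conc_mg_per_15ml == 10, ]
  dose <- dose_mg_per_kg(grams_consumed(thc$pre_mass_g, thc$post_mass_g),
                         thc$conc_mg_per_15ml, thc$body_mass_g)
  expect_equal(length(dose), 200)
  expect_lt(abs(mean(dose) - 29.2), 2 * sem(dose))
})

test_that("consumption simulation follows the two-segment profile", {
  prof <- consumption_profile(13.0, 4.2, 40, 120, animal_rate_cv = 0)
  s <- simulate_consumption(prof, bin = 10, n = 1, seed = 1)
  expect_equal(unname(s[1, "40"]), 520)   # 13.0 * 40
  expect_equal(unname(s[1, "120"]), 856)  # 520 + 4.2 * 80
  r <- piecewise_rates(as.numeric(colnames(s)), s[1, ])
  expect_rel_equal(c(r$r1, r$r2), c(13.0, 4.2), 1e-9)

  zero <- simulate_consumption(consumption_profile(0, 0, 40, 120), bin = 10)
  expect_true(all(zero == 0))
  expect_error(simulate_consumption(prof, bin = -1), "> 0")
  expect_error(simulate_consumption(prof, bin = 7), "divide")

  # with rate noise, every series is still nondecreasing and starts at 0
  noisy <- simulate_consumption(consumption_profile(13, 4.2, 40, 120,
                                                    animal_rate_cv = 0.5),
                                bin = 10, n = 20, seed = 2)
  expect_true(all(noisy[, 1] == 0))
  expect_true(all(apply(noisy, 1, function(x) all(diff(x) >= 0))))
})

test_that("startle simulation follows the sex-specific quadratic", {
  flat <- list(male = list(a0 = 900, a1 = 0, a2 = 0),
               tone_scale = c("null" = 0.02, "120" = 1), noise_sd = 0)
  for (d in c(0, 1, 10)) {
    s <- simulate_startle(d, "male", flat, n = 4, seed = 1)
    expect_equal(s$vmax_cm_per_min[s$tone_db == "120"], rep(900, 4))
  }
  expect_error(simulate_startle(1, "unknown", flat), "unknown sex")
  expect_error(simulate_startle(-1, "male", flat), ">= 0")

  # inverted U: interior maximum across doses when a2 < 0
  sp <- triadose:::default_startle_params()
  sp$noise_sd <- 0
  doses <- c(0.1, 1, 5, 10)
  means <- vapply(doses, function(d) {
    s <- simulate_startle(d, "male", sp, n = 2, seed = 1)
    mean(s$vmax_cm_per_min[s$tone_db == "120"])
  }, numeric(1))
  peak <- which.max(means)
  expect_true(peak > 1 && peak < length(doses))

  # noiseless round trip through the polynomial fit
  fit_doses <- c(0, 1, 3, 5, 8)
  for (sx in c("male", "female")) {
    m <- vapply(fit_doses, function(d) {
      s <- simulate_startle(d, sx, sp, n = 2, seed = 1)
      mean(s$vmax_cm_per_min[s$tone_db == "120"])
    }, numeric(1))
    fit <- fit_startle_polynomial(fit_doses, m, sex = sx)
    expect_rel_equal(c(fit$a0, fit$a1, fit$a2),
                     unlist(sp[[sx]])[c("a0", "a1", "a2")], 1e-6)
  }
})

test_that("PK curves respect the anchored concentration windows", {
  pk2 <- simulate_pk(29.2, c(0, 2, 26))
  brain_thc <- pk2[pk2$tissue == "brain" & pk2$analyte == "THC", ]
  expect_equal(brain_thc$conc_pmol_per_g[brain_thc$time_hr == 0], 0,
               tolerance = 1e-9)
  c2 <- brain_thc$conc_pmol_per_g[brain_thc$time_hr == 2]
  expect_true(c2 >= 500 && c2 <= 600)
  expect_lt(brain_thc$conc_pmol_per_g[brain_thc$time_hr == 26], 50)

  expect_true(all(simulate_pk(0, c(0, 1, 2))$conc_pmol_per_g == 0))
  expect_error(simulate_pk(-1, 1), ">= 0")
  expect_error(simulate_pk(1, -1), ">= 0")

  # single interior maximum per analyte; metabolites peak at/after parent
  tgrid <- seq(0, 30, by = 0.05)
  fine <- simulate_pk(29.2, tgrid)
  tmax <- sapply(split(fine[fine$tissue == "brain", ],
                       fine$analyte[fine$tissue == "brain"]), function(sub) {
    conc <- sub$conc_pmol_per_g
    expect_true(all(conc >= 0))
    s <- sign(diff(conc))
    expect_lte(sum(diff(s[s != 0]) != 0), 1) # one rise-fall transition
    sub$time_hr[which.max(conc)]
  })
  expect_lte(tmax[["THC"]], tmax[["11-OH-THC"]])
  expect_lte(tmax[["11-OH-THC"]], tmax[["11-COOH-THC"]])
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(sexes = character(0)), "sexes")
  expect_error(cohort_config(n_per_group = 0), "n_per_group")
  expect_error(cohort_config(noise_sd = c(locomotion = -1, tail_flick = 0,
                                          temperature = 0)), ">= 0")
  expect_error(cohort_config(assay_params = list(
    locomotion = emax_params(0, -1, 1))), "assay_params")
  expect_error(emax_params(0, 0, 1), "differ")
  expect_error(emax_params(0, 1, 0), "> 0")
  expect_error(consumption_profile(changepoint = 130, duration = 120),
               "changepoint")
})
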