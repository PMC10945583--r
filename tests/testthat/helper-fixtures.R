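# Shared fixtures built in code.

# A small cohort configuration with every noise source switched off, so
# analyses must recover generator parameters exactly.
noiseless_config <- function(n = 6L, ...) {
  cohort_config(
    n_per_group = n,
    noise_sd = c(locomotion = 0, tail_flick = 0, temperature = 0),
    oral_dose_cv = 0,
    pk_cv = 0,
    ctr_nonconsumer_p = 0,
    consumption_profile_thc = consumption_profile(13.0, 4.2, 40, 120,
                                                  animal_rate_cv = 0),
    consumption_profile_veh = consumption_profile(16.3, 9.9, 40, 120,
                                                  animal_rate_cv = 0),
    startle_params = local({
      p <- triadose:::default_startle_params()
      p$noise_sd <- 0
      p
    }),
    ...
  )
}

# A small noisy configuration for fast stochastic tests.
small_config <- function(n = 6L, ...) {
  cohort_config(n_per_group = n, ...)
}

# Noiseless two-segment cumulative series at 10-min bins.
piecewise_series <- function(r1, r2, cp = 40, end = 120, bin = 10) {
  m <- seq(0, end, by = bin)
  list(minutes = m,
       cum = ifelse(m <= cp, r1 * m, r1 * cp + r2 * (m - cp)))
}

# Emax fit from noiseless data at standard i.p. dose levels.
exact_emax_fit <- function(bottom, top, ed50,
                           doses = c(0, 0.3, 1, 3, 10, 30, 100)) {
  fit_emax(doses, emax_predict_curve(doses, bottom, top, ed50))
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  # absolute comparison at the same tolerance when the target is ~0
  expect_true(all(abs(actual - expected) <= rel_tol * pmax(abs(expected), 1)),
              label = sprintf("relative error of %s vs %s within %g",
                              paste(signif(actual, 8), collapse = ","),
                              paste(signif(expected, 8), collapse = ","),
                              rel_tol))
}
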