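#' Emax generator parameters for one assay
#'
#' @param bottom Baseline response (assay units) at dose 0.
#' @param top Asymptotic response; may be below `bottom` for decreasing
#'   responses (hypolocomotion, hypothermia).
#' @param ed50 Dose (mg/kg) at half-maximal effect; > 0.
#' @return An `emax_params` list.
#' @export
emax_params <- function(bottom, top, ed50) {
  if (ed50 <= 0) stop("emax_params(): ed50 must be > 0", call. = FALSE)
  if (bottom == top) stop("emax_params(): bottom and top must differ", call. = FALSE)
  structure(list(bottom = bottom, top = top, ed50 = ed50),
            class = "emax_params")
}

#' Two-segment consumption profile
#'
#' Mean cumulative-intake profile: a constant early rate up to the
#' changepoint, then a constant late rate to the end of access, with an
#' optional onset delay and per-animal lognormal rate heterogeneity.
#'
#' @param early_rate,late_rate Intake rates in mg gelatin per minute (>= 0).
#' @param changepoint Changepoint in minutes, strictly inside `(0, duration)`.
#' @param duration Access duration in minutes.
#' @param onset_delay Minutes before intake begins (default 0).
#' @param animal_rate_cv Coefficient of variation of the per-animal
#'   lognormal rate multiplier (mean 1); 0 for a noiseless profile.
#' @return A `consumption_profile` list.
#' @export
consumption_profile <- function(early_rate = 13.0, late_rate = 4.2,
                                changepoint = 40, duration = 120,
                                onset_delay = 0, animal_rate_cv = 0) {
  if (early_rate < 0 || late_rate < 0) {
    stop("consumption_profile(): rates must be >= 0", call. = FALSE)
  }
  if (!(changepoint > 0 && changepoint < duration)) {
    stop("consumption_profile(): need 0 < changepoint < duration", call. = FALSE)
  }
  if (onset_delay < 0 || onset_delay >= duration) {
    stop("consumption_profile(): onset_delay must lie in [0, duration)", call. = FALSE)
  }
  if (animal_rate_cv < 0) {
    stop("consumption_profile(): animal_rate_cv must be >= 0", call. = FALSE)
  }
  structure(
    list(early_rate = early_rate, late_rate = late_rate,
         changepoint = changepoint, duration = duration,
         onset_delay = onset_delay, animal_rate_cv = animal_rate_cv),
    class = "consumption_profile"
  )
}

#' Pharmacokinetic generator parameters
#'
#' One-compartment first-order absorption with a sequential metabolite
#' chain (THC -> 11-OH-THC -> 11-COOH-THC), calibrated -- not fitted -- to
#' reproduce the concentration ranges observed after a 2 hr access to
#' 10 mg/15 ml THC gelatin: brain THC peaking between 500 and 600 pmol/g
#' around the end of access and falling below 50 pmol/g by 24 h after
#' access.
#'
#' @param ka Absorption rate, 1/hr.
#' @param ke Parent (THC) elimination rate, 1/hr.
#' @param k_oh,k_cooh Elimination rates of 11-OH-THC and 11-COOH-THC, 1/hr.
#' @param scale Dose-to-brain-concentration scale for THC, pmol/g per mg/kg.
#' @param frac_oh,frac_cooh Peak brain concentrations of the metabolites
#'   relative to `scale * dose` (unitless).
#' @param brain_plasma Brain:plasma partition ratio (> 0).
#' @return A `pk_params` list.
#' @export
pk_params <- function(ka = 1.2, ke = 0.18, k_oh = 0.9, k_cooh = 0.75,
                      scale = 26.4, frac_oh = 0.58, frac_cooh = 0.35,
                      brain_plasma = 1.4) {
  vals <- c(ka = ka, ke = ke, k_oh = k_oh, k_cooh = k_cooh,
            scale = scale, brain_plasma = brain_plasma)
  if (any(vals <= 0)) stop("pk_params(): all rates and scales must be > 0", call. = FALSE)
  if (frac_oh < 0 || frac_cooh < 0) {
    stop("pk_params(): metabolite fractions must be >= 0", call. = FALSE)
  }
  if (length(unique(c(ka, ke, k_oh, k_cooh))) != 4L) {
    stop("pk_params(): rate constants must be pairwise distinct", call. = FALSE)
  }
  structure(
    list(ka = ka, ke = ke, k_oh = k_oh, k_cooh = k_cooh,
         scale = scale, frac_oh = frac_oh, frac_cooh = frac_cooh,
         brain_plasma = brain_plasma),
    class = "pk_params"
  )
}

#' Quadratic through three (dose, response) anchor points
#'
#' Solves the exact second-order polynomial passing through three points,
#' used to define the sex-specific startle generator coefficients from the
#' baseline and two anchored (dose, V_max) pairs.
#'
#' @param doses,vmax Numeric vectors of length 3 (distinct doses).
#' @return Named numeric vector `c(a0, a1, a2)`.
#' @export
startle_quad_through <- function(doses, vmax) {
  stopifnot(length(doses) == 3L, length(vmax) == 3L)
  if (length(unique(doses)) != 3L) {
    stop("startle_quad_through(): doses must be distinct", call. = FALSE)
  }
  cf <- solve(cbind(1, doses, doses^2), vmax)
  stats::setNames(as.numeric(cf), c("a0", "a1", "a2"))
}

# Default sex-specific startle quadratics. Anchors: a dose-0 baseline
# (males startle more than females) and the 120 dB responses at the two
# oral-equivalent doses 3.7 and 8.8 mg/kg, where males show a strong
# inverted U (rise at low-to-mid doses, collapse at high) and females a
# flat-then-falling profile.
default_startle_params <- function() {
  list(
    male = as.list(startle_quad_through(c(0, 3.7, 8.8), c(1450, 1733, 558))),
    female = as.list(startle_quad_through(c(0, 3.7, 8.8), c(700, 688, 310))),
    tone_scale = c("null" = 0.02, "80" = 0.05, "90" = 0.12, "100" = 0.30,
                   "105" = 0.50, "110" = 0.70, "120" = 1.00),
    noise_sd = 120
  )
}

#' Synthetic cohort configuration
#'
#' All generator parameters in one validated object. Defaults reproduce the
#' study conditions the analyses assume: triad Emax curves anchored at
#' ED50s of 1.3 (hypolocomotion), 3.9 (tail-flick analgesia) and 14.4
#' (hypothermia) mg/kg; a two-segment intake time course (13.0 -> 4.2
#' mg/min for THC gelatin, 16.3 -> 9.9 for vehicle, changepoint 40 min);
#' oral dosimetry anchored to the observed group-mean consumed doses (29.2
#' mg/kg for 10 mg/15 ml chocolate-Ensure gelatin); an inverted-U
#' sex-specific 120 dB startle quadratic; and brain THC kinetics peaking
#' between 500 and 600 pmol/g.
#'
#' @param n_per_group Animals per sex per group (>= 1).
#' @param sexes Character subset of `c("male", "female")`.
#' @param ip_doses i.p. dose levels, mg/kg (>= 0, vehicle = 0 included).
#' @param gel_concentrations THC mg per 15 ml for the E-gel groups.
#' @param assay_params Named list of [emax_params()] for `locomotion`
#'   (cm per 15 min), `tail_flick` (s latency) and `temperature` (deg C).
#' @param noise_sd Named numeric: additive Gaussian SD per assay on the
#'   difference-score scale.
#' @param baselines Named list of `c(mean, sd)` pre-test baselines per assay.
#' @param oral_dose_means Named numeric: mean consumed dose (mg/kg) per
#'   E-gel concentration (names = concentration).
#' @param oral_dose_cv Lognormal CV of per-animal consumed dose.
#' @param oral_potency Oral:i.p. potency ratio (unitless): triad responses
#'   of orally dosed animals are generated at `oral_potency * consumed
#'   dose` on the i.p. Emax curves, reproducing the right-shifted potency
#'   of consumption relative to injection (29.2 mg/kg consumed over 2 hr is
#'   equivalent to about 3.7 mg/kg i.p.).
#' @param veh_grams_mean Mean grams of vehicle E-gel consumed.
#' @param ctr_dose_mean,ctr_nonconsumer_p Mean consumed dose and
#'   non-consumer probability for the 4 mg sugar-water (CTR) gelatin group.
#' @param consumption_profile_thc,consumption_profile_veh
#'   [consumption_profile()] objects for the 10-min time-course stream.
#' @param startle_params List with per-sex quadratic coefficients
#'   (`a0`, `a1`, `a2`), `tone_scale` and `noise_sd`; see
#'   `triadose:::default_startle_params`.
#' @param pk Pk generator parameters ([pk_params()]).
#' @param pk_cv Lognormal CV of per-animal PK concentrations.
#' @param body_mass Numeric `c(mean, sd)` in grams; truncated at 18 g.
#' @param cup_mass_g Mean pre-access gelatin cup mass, grams.
#' @param seed Default integer seed for [generate_cohort()].
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(
    n_per_group = 10L,
    sexes = c("male", "female"),
    ip_doses = c(0, 0.3, 1, 3, 10, 30),
    gel_concentrations = c(2, 5, 10),
    assay_params = list(
      locomotion = emax_params(0, -3500, 1.3),
      tail_flick = emax_params(0, 8, 3.9),
      temperature = emax_params(0, -8.64, 14.4)
    ),
    noise_sd = c(locomotion = 700, tail_flick = 1.6, temperature = 1.7),
    baselines = list(
      locomotion = c(mean = 4000, sd = 400),
      tail_flick = c(mean = 1.5, sd = 0.2),
      temperature = c(mean = 37.2, sd = 0.3)
    ),
    oral_dose_means = c("2" = 10.5, "5" = 17.2, "10" = 29.2),
    oral_dose_cv = 0.25,
    oral_potency = 3.7 / 29.2,
    veh_grams_mean = 1.9,
    ctr_dose_mean = 8.4,
    ctr_nonconsumer_p = 7 / 17,
    consumption_profile_thc = consumption_profile(13.0, 4.2, 40, 120,
                                                  animal_rate_cv = 0.3),
    consumption_profile_veh = consumption_profile(16.3, 9.9, 40, 120,
                                                  animal_rate_cv = 0.3),
    startle_params = default_startle_params(),
    pk = pk_params(),
    pk_cv = 0.2,
    body_mass = c(mean = 25, sd = 2),
    cup_mass_g = 16,
    seed = 20230901L) {
  cfg <- structure(
    list(n_per_group = as.integer(n_per_group), sexes = sexes,
         ip_doses = ip_doses, gel_concentrations = gel_concentrations,
         assay_params = assay_params, noise_sd = noise_sd,
         baselines = baselines, oral_dose_means = oral_dose_means,
         oral_dose_cv = oral_dose_cv, oral_potency = oral_potency,
         veh_grams_mean = veh_grams_mean,
         ctr_dose_mean = ctr_dose_mean, ctr_nonconsumer_p = ctr_nonconsumer_p,
         consumption_profile_thc = consumption_profile_thc,
         consumption_profile_veh = consumption_profile_veh,
         startle_params = startle_params, pk = pk, pk_cv = pk_cv,
         body_mass = body_mass, cup_mass_g = cup_mass_g,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_per_group < 1L) {
    stop("cohort_config: n_per_group must be >= 1", call. = FALSE)
  }
  if (length(cfg$sexes) == 0L || !all(cfg$sexes %in% c("male", "female"))) {
    stop("cohort_config: sexes must be a nonempty subset of male/female",
         call. = FALSE)
  }
  if (length(cfg$ip_doses) == 0L || any(cfg$ip_doses < 0)) {
    stop("cohort_config: ip_doses must be nonempty and >= 0", call. = FALSE)
  }
  if (any(cfg$noise_sd < 0) || cfg$oral_dose_cv < 0 || cfg$pk_cv < 0) {
    stop("cohort_config: noise parameters must be >= 0", call. = FALSE)
  }
  if (cfg$oral_potency <= 0) {
    stop("cohort_config: oral_potency must be > 0", call. = FALSE)
  }
  assays <- c("locomotion", "tail_flick", "temperature")
  if (!all(assays %in% names(cfg$assay_params))) {
    stop("cohort_config: assay_params must cover ", paste(assays, collapse = ", "),
         call. = FALSE)
  }
  if (!all(assays %in% names(cfg$noise_sd))) {
    stop("cohort_config: noise_sd must cover every assay", call. = FALSE)
  }
  if (!all(as.character(cfg$gel_concentrations) %in% names(cfg$oral_dose_means))) {
    stop("cohort_config: oral_dose_means must cover every gel concentration",
         call. = FALSE)
  }
  for (sx in cfg$sexes) {
    if (!all(c("a0", "a1", "a2") %in% names(cfg$startle_params[[sx]]))) {
      stop("cohort_config: startle_params missing coefficients for ", sx,
           call. = FALSE)
    }
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  n per sex per group: %d; sexes: %s\n",
              x$n_per_group, paste(x$sexes, collapse = ", ")))
  cat(sprintf("  i.p. doses (mg/kg): %s\n", paste(x$ip_doses, collapse = ", ")))
  cat(sprintf("  E-gel concentrations (mg/15 ml): %s\n",
              paste(x$gel_concentrations, collapse = ", ")))
  for (a in names(x$assay_params)) {
    p <- x$assay_params[[a]]
    cat(sprintf("  %-12s B = %.4g, T = %.4g, ED50 = %.3g mg/kg, noise SD %.3g\n",
                a, p$bottom, p$top, p$ed50, x$noise_sd[[a]]))
  }
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Simulate cumulative gelatin consumption series
#'
#' Piecewise-linear mean intake (early rate to the changepoint, late rate
#' after), recorded every `bin` minutes, with per-animal multiplicative
#' lognormal rate noise. Series are nondecreasing and start at 0.
#'
#' @param profile A [consumption_profile()].
#' @param bin Recording bin in minutes; must divide the duration.
#' @param n Number of animals.
#' @param seed Integer seed (noise is animal-level only).
#' @return Numeric matrix, `n` rows (animals) by time points, with column
#'   names the minute marks `0, bin, 2 bin, ..., duration` (mg consumed).
#' @examples
#' simulate_consumption(consumption_profile(13.0, 4.2, 40, 120), bin = 10)
#' @export
simulate_consumption <- function(profile, bin = 10, n = 1L, seed = 1L) {
  stopifnot(inherits(profile, "consumption_profile"))
  if (bin <= 0) stop("simulate_consumption(): bin must be > 0", call. = FALSE)
  if (abs(profile$duration / bin - round(profile$duration / bin)) > 1e-9) {
    stop("simulate_consumption(): bin must divide the duration", call. = FALSE)
  }
  minutes <- seq(0, profile$duration, by = bin)
  onset <- profile$onset_delay
  cp <- max(profile$changepoint, onset)
  mean_cum <- profile$early_rate * pmax(pmin(minutes, cp) - onset, 0) +
    profile$late_rate * pmax(minutes - cp, 0)
  restore <- local_rng(seed)
  on.exit(restore(), add = TRUE)
  mult <- rlnorm_mult(n, profile$animal_rate_cv)
  out <- outer(mult, mean_cum)
  dimnames(out) <- list(paste0("animal_", seq_len(n)), as.character(minutes))
  out
}

#' Simulate acoustic startle responses
#'
#' Per-animal V_max (cm/min) at each tone of the escalating-tone paradigm.
#' The 120 dB mean follows the sex-specific quadratic
#' `a0 + a1 d + a2 d^2`; lower tones are scaled-down versions of it; noise
#' is additive Gaussian (scaled with the tone) and responses are floored at
#' 0.
#'
#' @param dose i.p. dose, mg/kg (>= 0).
#' @param sex `"male"` or `"female"` (must be a key of `params`).
#' @param params Startle parameter list (see [cohort_config()]).
#' @param n Number of animals.
#' @param seed Integer seed.
#' @return Data frame with columns `animal`, `tone_db`, `vmax_cm_per_min`.
#' @export
simulate_startle <- function(dose, sex, params = default_startle_params(),
                             n = 10L, seed = 1L) {
  if (dose < 0) stop("simulate_startle(): dose must be >= 0", call. = FALSE)
  if (!sex %in% names(params) || !is.list(params[[sex]])) {
    stop("simulate_startle(): unknown sex key: ", sex, call. = FALSE)
  }
  cf <- params[[sex]]
  mean_120 <- max(cf$a0 + cf$a1 * dose + cf$a2 * dose^2, 0)
  tone_scale <- params$tone_scale
  noise_sd <- params$noise_sd
  restore <- local_rng(seed)
  on.exit(restore(), add = TRUE)
  rows <- lapply(names(tone_scale), function(tn) {
    mu <- mean_120 * tone_scale[[tn]]
    v <- mu + stats::rnorm(n, 0, noise_sd * tone_scale[[tn]])
    data.frame(animal = seq_len(n), tone_db = tn,
               vmax_cm_per_min = pmax(v, 0), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Amount in the terminal compartment of a linear first-order chain with
# distinct rates (Bateman generalization); unit input dose.
bateman_chain <- function(t, rates) {
  n <- length(rates)
  coef_num <- prod(rates[-n])
  # clamp tiny negative floating-point residue (the sum is analytically >= 0)
  pmax(vapply(t, function(tt) {
    s <- 0
    for (i in seq_len(n)) {
      denom <- prod(rates[-i] - rates[i])
      s <- s + exp(-rates[i] * tt) / denom
    }
    coef_num * s
  }, numeric(1)), 0)
}

#' Simulate brain and plasma cannabinoid concentrations
#'
#' Deterministic mean concentration curves from the one-compartment
#' first-order absorption model with a sequential metabolite chain:
#' THC -> 11-OH-THC -> 11-COOH-THC. Concentrations are zero at `t = 0`,
#' rise to a single interior maximum, and each metabolite peaks at or after
#' its parent.
#'
#' @param dose Consumed dose, mg/kg (>= 0).
#' @param times Hours from access start (>= 0).
#' @param params A [pk_params()].
#' @return Data frame with columns `time_hr`, `tissue`, `analyte`,
#'   `conc_pmol_per_g`.
#' @examples
#' simulate_pk(29.2, c(0, 1, 2, 2.5, 26))
#' @export
simulate_pk <- function(dose, times, params = pk_params()) {
  stopifnot(inherits(params, "pk_params"))
  if (dose < 0) stop("simulate_pk(): dose must be >= 0", call. = FALSE)
  if (any(times < 0)) stop("simulate_pk(): times must be >= 0", call. = FALSE)
  unit_thc <- bateman_chain(times, c(params$ka, params$ke))
  unit_oh <- bateman_chain(times, c(params$ka, params$ke, params$k_oh))
  unit_cooh <- bateman_chain(times, c(params$ka, params$ke, params$k_oh,
                                      params$k_cooh))
  # normalize each metabolite shape to unit peak so frac_* scales are
  # interpretable as peak concentrations relative to the THC scale
  peak_of <- function(rates) {
    opt <- stats::optimize(function(tt) bateman_chain(tt, rates),
                           interval = c(1e-6, 200), maximum = TRUE)
    opt$objective
  }
  p_oh <- peak_of(c(params$ka, params$ke, params$k_oh))
  p_cooh <- peak_of(c(params$ka, params$ke, params$k_oh, params$k_cooh))
  brain <- list(
    THC = params$scale * dose * unit_thc,
    `11-OH-THC` = params$scale * params$frac_oh * dose * unit_oh / p_oh,
    `11-COOH-THC` = params$scale * params$frac_cooh * dose * unit_cooh / p_cooh
  )
  rows <- list()
  for (an in names(brain)) {
    rows[[length(rows) + 1L]] <- data.frame(
      time_hr = times, tissue = "brain", analyte = an,
      conc_pmol_per_g = brain[[an]], stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      time_hr = times, tissue = "plasma", analyte = an,
      conc_pmol_per_g = brain[[an]] / params$brain_plasma,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a full synthetic cohort
#'
#' Produces every table the downstream analyses consume, with the
#' statistical structure the study design assumes: per-animal consumption
#' dosimetry (anchored group-mean doses, lognormal spread, non-consumers in
#' the bitter control-gelatin group), triad pre/post scores whose
#' difference follows the assay Emax curve at the animal's dose (i.p.
#' nominal dose, or individually consumed dose for oral routes) plus
#' additive Gaussian noise, 10-min cumulative intake series, per-sex
#' startle responses across tones, and noisy PK samples around the
#' deterministic kinetic curves. Identical `(config, seed)` yields
#' byte-identical tables.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A `thc_cohort` list of data frames: `consumption`, `triad`,
#'   `timeseries`, `startle`, `pk`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  validate_cohort_config(config)
  assays <- names(config$assay_params)
  sexes <- config$sexes
  n <- config$n_per_group

  restore <- local_rng(child_seed(seed, 1L))
  on.exit(restore(), add = TRUE)

  next_id <- local({
    counter <- 0L
    function(k) {
      ids <- sprintf("m%04d", counter + seq_len(k))
      counter <<- counter + k
      ids
    }
  })

  draw_body_mass <- function(k) {
    rnorm_trunc(k, config$body_mass[["mean"]], config$body_mass[["sd"]], 18)
  }

  triad_rows <- list()
  consumption_rows <- list()

  add_triad <- function(ids, sex, route, nominal, consumed, dose_for_curve) {
    for (a in assays) {
      p <- config$assay_params[[a]]
      base <- config$baselines[[a]]
      pre <- stats::rnorm(length(ids), base[["mean"]], base[["sd"]])
      diff <- emax_curve(dose_for_curve, p$bottom, p$top, p$ed50) +
        stats::rnorm(length(ids), 0, config$noise_sd[[a]])
      triad_rows[[length(triad_rows) + 1L]] <<- data.frame(
        animal_id = ids, sex = sex, route = route,
        nominal_dose_or_conc = nominal,
        consumed_mg_per_kg = consumed,
        assay = a, pre = pre, post = pre + diff,
        stringsAsFactors = FALSE)
    }
  }

  # --- i.p. arms: one group per sex per dose --------------------------------
  for (sx in sexes) {
    for (d in config$ip_doses) {
      ids <- next_id(n)
      add_triad(ids, sx, "ip", d, NA_real_, rep(d, n))
    }
  }

  # --- oral arms ------------------------------------------------------------
  add_oral_group <- function(sex, route, conc, treatment, label,
                             dose_mean, nonconsumer_p = 0) {
    ids <- next_id(n)
    bm <- draw_body_mass(n)
    if (treatment == "VEH") {
      grams <- config$veh_grams_mean * rlnorm_mult(n, config$oral_dose_cv)
      doses <- rep(0, n)
    } else {
      doses <- dose_mean * rlnorm_mult(n, config$oral_dose_cv)
      if (nonconsumer_p > 0) {
        doses[stats::runif(n) < nonconsumer_p] <- 0
      }
      grams <- doses * (bm / 1000) / (conc / 15)
    }
    pre_mass <- stats::rnorm(n, config$cup_mass_g, 0.3)
    consumption_rows[[length(consumption_rows) + 1L]] <<- data.frame(
      animal_id = ids, sex = sex, day = 2L, gel_label = label,
      treatment = treatment, conc_mg_per_15ml = conc,
      pre_mass_g = pre_mass, post_mass_g = pre_mass - grams,
      body_mass_g = bm, stringsAsFactors = FALSE)
    add_triad(ids, sex, route, conc, doses, doses * config$oral_potency)
  }

  for (sx in sexes) {
    add_oral_group(sx, "e_gel", 0, "VEH", "E", NA_real_)
    for (conc in config$gel_concentrations) {
      add_oral_group(sx, "e_gel", conc, "THC", "E",
                     config$oral_dose_means[[as.character(conc)]])
    }
    add_oral_group(sx, "ctr_gel", 4, "THC", "CTR",
                   config$ctr_dose_mean, config$ctr_nonconsumer_p)
  }

  consumption <- do.call(rbind, consumption_rows)
  triad <- do.call(rbind, triad_rows)
  rownames(consumption) <- rownames(triad) <- NULL

  # --- 10-min intake time course (day-2 THC vs VEH E-gel cohorts) ----------
  ts_tab <- local({
    mats <- list(
      THC = simulate_consumption(config$consumption_profile_thc, bin = 10,
                                 n = n, seed = child_seed(seed, 2L)),
      VEH = simulate_consumption(config$consumption_profile_veh, bin = 10,
                                 n = n, seed = child_seed(seed, 3L))
    )
    rows <- lapply(names(mats), function(tr) {
      m <- mats[[tr]]
      ids <- next_id(nrow(m))
      data.frame(
        animal_id = rep(ids, each = ncol(m)),
        day = 2L,
        treatment = tr,
        minute = rep(as.numeric(colnames(m)), times = nrow(m)),
        cumulative_mg = as.vector(t(m)),
        stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })

  # --- startle: i.p. per sex per dose --------------------------------------
  startle_doses <- c(0, 0.1, 1, 5, 10)
  startle_rows <- list()
  k <- 4L
  for (sx in sexes) {
    for (d in startle_doses) {
      sim <- simulate_startle(d, sx, config$startle_params, n = n,
                              seed = child_seed(seed, k))
      k <- k + 1L
      ids <- next_id(n)
      startle_rows[[length(startle_rows) + 1L]] <- data.frame(
        animal_id = ids[sim$animal], sex = sx, route = "ip",
        dose_mg_per_kg = d, access_hr = NA_real_,
        tone_db = sim$tone_db, vmax_cm_per_min = sim$vmax_cm_per_min,
        stringsAsFactors = FALSE)
    }
  }
  startle <- do.call(rbind, startle_rows)
  rownames(startle) <- NULL

  # --- PK samples around the deterministic curves --------------------------
  pk_tab <- local({
    times <- c(1, 2, 2.5, 26)
    mean_dose <- config$oral_dose_means[[as.character(max(config$gel_concentrations))]]
    curves <- simulate_pk(mean_dose, times, config$pk)
    restore2 <- local_rng(child_seed(seed, 99L))
    on.exit(restore2(), add = TRUE)
    # terminal sampling: one set of animals per time point, each measured
    # for every tissue x analyte
    rows <- lapply(times, function(tt) {
      ids <- next_id(n)
      sub <- curves[curves$time_hr == tt, , drop = FALSE]
      per <- lapply(seq_len(nrow(sub)), function(i) {
        data.frame(
          animal_id = ids,
          sex = rep(sexes, length.out = n),
          tissue = sub$tissue[i], analyte = sub$analyte[i],
          time_hr = tt,
          conc_pmol_per_g = sub$conc_pmol_per_g[i] * rlnorm_mult(n, config$pk_cv),
          stringsAsFactors = FALSE)
      })
      do.call(rbind, per)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })

  structure(
    list(consumption = consumption, triad = triad, timeseries = ts_tab,
         startle = startle, pk = pk_tab, seed = as.integer(seed)),
    class = "thc_cohort"
  )
}

#' @export
print.thc_cohort <- function(x, ...) {
  cat("Synthetic THC consumption cohort (seed", x$seed, ")\n")
  for (tb in c("consumption", "triad", "timeseries", "startle", "pk")) {
    cat(sprintf("  $%-12s %5d rows\n", tb, nrow(x[[tb]])))
  }
  invisible(x)
}
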