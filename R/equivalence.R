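#' Invert a fitted Emax curve at an observed response
#'
#' The heart of the cross-route dose-prediction model: given the i.p.
#' dose-response fit for one triad behavior and the group-mean response
#' observed after oral consumption, solve the curve for the i.p.-equivalent
#' dose, `d = ED50 (y - B) / (T - y)`. The observed response must lie
#' strictly between Bottom and Top (direction-aware); responses outside the
#' fitted dynamic range fail loudly rather than extrapolating, unless
#' `allow_extrapolation = TRUE`, which permits inversion up to twice the
#' largest tested dose.
#'
#' @param fit A converged [fit_emax()] object.
#' @param observed Observed response, assay units.
#' @param allow_extrapolation Permit responses beyond the fitted range so
#'   long as the implied dose is at most `2 * max(tested dose)`.
#' @return Predicted i.p. dose in mg/kg.
#' @examples
#' d <- c(0, 1, 3, 10, 30, 100)
#' fit <- fit_emax(d, emax_predict_curve(d, 0, 100, 10))
#' invert_emax(fit, 50) # 10, the ED50
#' @export
invert_emax <- function(fit, observed, allow_extrapolation = FALSE) {
  stopifnot(inherits(fit, "emax_fit"))
  if (!isTRUE(fit$converged)) {
    stop("invert_emax(): refusing a non-converged fit", call. = FALSE)
  }
  b <- fit$bottom
  t <- fit$top
  e <- fit$ed50
  sgn <- sign(t - b)
  y <- (observed - b) * sgn # progress toward Top on a positive scale
  span <- abs(t - b)
  if (abs(observed - t) < .Machine$double.eps * (1 + abs(t))) {
    stop("invert_emax(): observed equals Top; implied dose is infinite",
         call. = FALSE)
  }
  if (y < 0 || y >= span) {
    if (!allow_extrapolation || y >= span) {
      stop(sprintf(
        "invert_emax(): observed response %.4g outside the fitted dynamic range (%.4g, %.4g)",
        observed, b, t), call. = FALSE)
    }
  }
  d <- e * (observed - b) / (t - observed)
  if (!allow_extrapolation && d > max(fit$doses) * (1 + 1e-9)) {
    stop(sprintf(
      "invert_emax(): implied dose %.3g mg/kg exceeds the largest tested dose %.3g; pass allow_extrapolation = TRUE to permit up to 2x",
      d, max(fit$doses)), call. = FALSE)
  }
  if (allow_extrapolation && d > 2 * max(fit$doses)) {
    stop(sprintf(
      "invert_emax(): implied dose %.3g mg/kg exceeds 2x the largest tested dose",
      d), call. = FALSE)
  }
  d
}

#' Aggregate per-behavior predicted doses
#'
#' Arithmetic mean and SEM (sample SD over the square root of the number of
#' behaviors) of the predicted i.p.-equivalent doses across the triad
#' behaviors.
#'
#' @param doses Predicted doses, mg/kg, one per behavior.
#' @return List with `mean`, `sem` (`NA` when only one behavior), `k`.
#' @examples
#' aggregate_predicted(c(10.3, 11.6, 4.5)) # mean 8.8, SEM 2.2
#' @export
aggregate_predicted <- function(doses) {
  doses <- as.numeric(doses)
  doses <- doses[!is.na(doses)]
  if (length(doses) == 0L) {
    stop("aggregate_predicted(): need at least one predicted dose", call. = FALSE)
  }
  list(mean = mean(doses), sem = sem(doses), k = length(doses))
}

#' Fold ratio between two predicted doses
#'
#' @param a,b Doses in mg/kg; `b` must be positive.
#' @return `a / b` (report at 1 decimal).
#' @examples
#' fold_ratio(8.8, 3.7) # 2.4
#' @export
fold_ratio <- function(a, b) {
  if (any(b <= 0)) stop("fold_ratio(): denominator must be > 0", call. = FALSE)
  a / b
}

#' Predicted startle response at a dose
#'
#' Evaluates the sex-specific second-order startle polynomial at a predicted
#' i.p.-equivalent dose. Negative predictions are floored at 0 cm/min with a
#' warning (V_max cannot be negative).
#'
#' @param poly A `startle_poly` from [fit_startle_polynomial()].
#' @param dose Dose in mg/kg (>= 0).
#' @return Predicted V_max, cm/min.
#' @export
predict_startle <- function(poly, dose) {
  stopifnot(inherits(poly, "startle_poly"))
  if (any(dose < 0)) stop("predict_startle(): dose must be >= 0", call. = FALSE)
  v <- poly$a0 + poly$a1 * dose + poly$a2 * dose^2
  if (any(v < 0)) {
    warning("predict_startle(): negative predicted V_max floored at 0")
    v <- pmax(v, 0)
  }
  v
}

#' Validate a predicted startle response against the measured one
#'
#' @param predicted Predicted V_max, cm/min.
#' @param measured_mean,measured_sem Measured group mean and SEM, cm/min
#'   (`measured_sem` >= 0).
#' @return `"within_sem"` if `|predicted - measured_mean| <= measured_sem`,
#'   else `"outside_sem"`.
#' @export
validate_within_sem <- function(predicted, measured_mean, measured_sem) {
  if (any(measured_sem < 0)) {
    stop("validate_within_sem(): SEM must be >= 0", call. = FALSE)
  }
  ifelse(abs(predicted - measured_mean) <= measured_sem,
         "within_sem", "outside_sem")
}

#' Bootstrap confidence interval for one behavior's predicted dose
#'
#' Nonparametric bootstrap of the inversion for a single behavior: resample
#' animals within each i.p. dose group and the oral group, refit the Emax
#' curve, re-invert at the resampled oral group mean. This quantifies
#' fit-and-inversion uncertainty for one behavior, distinct from the
#' across-behavior spread reported by [aggregate_predicted()].
#'
#' @param doses,responses Per-animal i.p. doses and difference scores.
#' @param oral_responses Per-animal oral-group difference scores.
#' @param reps Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @param allow_extrapolation Passed to [invert_emax()].
#' @return List with `estimate`, `lower`, `upper`, `reps_used`.
#' @export
bootstrap_predicted_dose <- function(doses, responses, oral_responses,
                                     reps = 1000L, seed = 1L, level = 0.95,
                                     allow_extrapolation = FALSE) {
  fit <- fit_emax(doses, responses)
  est <- invert_emax(fit, mean(oral_responses),
                     allow_extrapolation = allow_extrapolation)
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  groups <- split(seq_along(doses), doses)
  draws <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    idx <- unlist(lapply(groups, function(g) sample(g, length(g), replace = TRUE)),
                  use.names = FALSE)
    oral_idx <- sample(seq_along(oral_responses), length(oral_responses),
                       replace = TRUE)
    draws[r] <- tryCatch({
      f <- fit_emax(doses[idx], responses[idx])
      invert_emax(f, mean(oral_responses[oral_idx]),
                  allow_extrapolation = allow_extrapolation)
    }, error = function(e) NA_real_)
  }
  ok <- draws[!is.na(draws)]
  alpha <- (1 - level) / 2
  list(
    estimate = est,
    lower = unname(stats::quantile(ok, alpha)),
    upper = unname(stats::quantile(ok, 1 - alpha)),
    reps_used = length(ok)
  )
}

#' Build a dose-equivalence report for one oral condition
#'
#' Runs the full prediction chain for one oral-exposure condition: invert
#' each behavior's i.p. fit at the oral group-mean response, aggregate the
#' per-behavior doses, optionally compare against a second condition as a
#' fold ratio, then propagate the aggregate dose through the sex-specific
#' startle polynomials and validate against measured startle.
#'
#' @param fits Named list of converged `emax_fit` objects, one per behavior.
#' @param oral_means Named numeric vector of oral group-mean difference
#'   scores; names must match `fits`.
#' @param startle_polys Optional named list (by sex) of `startle_poly`
#'   objects.
#' @param measured_startle Optional data frame with columns `sex`,
#'   `mean_vmax`, `sem_vmax` (measured 120 dB startle after oral exposure).
#' @param comparison_dose Optional reference aggregate dose (mg/kg) for the
#'   fold ratio (numerator is this condition's aggregate mean).
#' @param allow_extrapolation Passed to [invert_emax()].
#' @param label Condition label (e.g. `"1hr"`).
#' @return An `equivalence_report` list; see Details in the vignette.
#' @export
equivalence_report <- function(fits, oral_means, startle_polys = NULL,
                               measured_startle = NULL,
                               comparison_dose = NULL,
                               allow_extrapolation = FALSE,
                               label = NULL) {
  stopifnot(is.list(fits), length(fits) >= 1)
  if (is.null(names(fits)) || is.null(names(oral_means))) {
    stop("equivalence_report(): fits and oral_means must be named", call. = FALSE)
  }
  behaviors <- names(fits)
  miss <- setdiff(behaviors, names(oral_means))
  if (length(miss) > 0) {
    stop("equivalence_report(): no oral mean for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  failures <- character(0)
  per_behavior <- vapply(behaviors, function(bh) {
    tryCatch(
      invert_emax(fits[[bh]], oral_means[[bh]],
                  allow_extrapolation = allow_extrapolation),
      error = function(e) {
        failures[[bh]] <<- conditionMessage(e)
        NA_real_
      })
  }, numeric(1))
  if (all(is.na(per_behavior))) {
    stop("equivalence_report(): inversion failed for every behavior:\n  ",
         paste(failures, collapse = "\n  "), call. = FALSE)
  }
  if (length(failures) > 0) {
    warning("equivalence_report(): inversion failed for ",
            paste(names(failures), collapse = ", "),
            "; aggregating over the remaining behaviors")
  }
  agg <- aggregate_predicted(per_behavior)
  fold <- if (!is.null(comparison_dose)) fold_ratio(agg$mean, comparison_dose) else NULL

  startle <- NULL
  if (!is.null(startle_polys)) {
    startle <- lapply(names(startle_polys), function(sx) {
      pred <- predict_startle(startle_polys[[sx]], agg$mean)
      verdict <- NA_character_
      meas_mean <- NA_real_
      meas_sem <- NA_real_
      if (!is.null(measured_startle)) {
        row <- measured_startle[measured_startle$sex == sx, , drop = FALSE]
        if (nrow(row) == 1L) {
          meas_mean <- row$mean_vmax
          meas_sem <- row$sem_vmax
          verdict <- validate_within_sem(pred, meas_mean, meas_sem)
        }
      }
      list(sex = sx, predicted_vmax = pred,
           measured_mean = meas_mean, measured_sem = meas_sem,
           verdict = verdict)
    })
    names(startle) <- names(startle_polys)
  }

  structure(
    list(label = label,
         per_behavior_dose = per_behavior,
         aggregate_mean = agg$mean,
         aggregate_sem = agg$sem,
         k_behaviors = agg$k,
         inversion_failures = if (length(failures) > 0) as.list(failures) else NULL,
         fold_ratio = fold,
         startle = startle,
         fit_params = lapply(fits, function(f) {
           list(bottom = f$bottom, top = f$top, ed50 = f$ed50,
                extrapolated_top = f$extrapolated_top)
         }),
         oral_means = as.list(oral_means)),
    class = "equivalence_report"
  )
}

#' @export
print.equivalence_report <- function(x, ...) {
  cat("Dose-equivalence report",
      if (!is.null(x$label)) sprintf("[%s]", x$label) else "", "\n")
  for (bh in names(x$per_behavior_dose)) {
    cat(sprintf("  %-14s -> %.1f mg/kg i.p.\n", bh, x$per_behavior_dose[[bh]]))
  }
  sem_txt <- if (is.na(x$aggregate_sem)) "n/a" else sprintf("%.1f", x$aggregate_sem)
  cat(sprintf("  aggregate: %.1f +/- %s mg/kg i.p. (k = %d behaviors)\n",
              x$aggregate_mean, sem_txt, x$k_behaviors))
  if (!is.null(x$fold_ratio)) {
    cat(sprintf("  fold ratio vs reference: %.1f\n", x$fold_ratio))
  }
  for (s in x$startle) {
    line <- sprintf("  startle (%s): predicted %.0f cm/min", s$sex, s$predicted_vmax)
    if (!is.na(s$verdict)) {
      line <- sprintf("%s vs measured %.0f +/- %.0f -> %s",
                      line, s$measured_mean, s$measured_sem, s$verdict)
    }
    cat(line, "\n")
  }
  invisible(x)
}
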