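#' Tones used in the acoustic startle paradigm
#'
#' The escalating tone set: a null (no-stimulus) trial plus 80, 90, 100,
#' 105, 110 and 120 dB. `"null"` rows are retained for QC but excluded from
#' dose-response fitting.
#' @export
STARTLE_TONES <- c("null", "80", "90", "100", "105", "110", "120")

#' Group summaries of startle responses per tone
#'
#' Mean and SEM of the peak startle velocity (V_max, cm/min) per tone within
#' each (sex, route, dose or access-duration) group.
#'
#' @param records Data frame with columns `animal_id`, `sex`, `route`,
#'   `dose_mg_per_kg` (i.p.; `NA` for oral), `access_hr` (oral; `NA` for
#'   i.p.), `tone_db`, `vmax_cm_per_min`.
#' @return Data frame keyed by (sex, route, dose_mg_per_kg, access_hr,
#'   tone_db) with columns `n`, `mean_vmax`, `sem_vmax`.
#' @export
startle_curve <- function(records) {
  required <- c("animal_id", "sex", "route", "tone_db", "vmax_cm_per_min")
  miss <- setdiff(required, names(records))
  if (length(miss) > 0) {
    stop("startle_curve(): missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tone <- as.character(records$tone_db)
  bad <- setdiff(unique(tone), STARTLE_TONES)
  if (length(bad) > 0) {
    stop("startle_curve(): unknown tone level(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(records$vmax_cm_per_min < 0, na.rm = TRUE)) {
    stop("startle_curve(): V_max must be >= 0", call. = FALSE)
  }
  if (!"dose_mg_per_kg" %in% names(records)) records$dose_mg_per_kg <- NA_real_
  if (!"access_hr" %in% names(records)) records$access_hr <- NA_real_
  key <- interaction(records$sex, records$route,
                     ifelse(is.na(records$dose_mg_per_kg), "-", records$dose_mg_per_kg),
                     ifelse(is.na(records$access_hr), "-", records$access_hr),
                     tone, drop = TRUE, sep = "\r")
  pieces <- split(seq_len(nrow(records)), key)
  rows <- lapply(pieces, function(idx) {
    v <- records$vmax_cm_per_min[idx]
    data.frame(
      sex = records$sex[idx[1]],
      route = records$route[idx[1]],
      dose_mg_per_kg = records$dose_mg_per_kg[idx[1]],
      access_hr = records$access_hr[idx[1]],
      tone_db = tone[idx[1]],
      n = length(v),
      mean_vmax = mean(v),
      sem_vmax = sem(v),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$sex, out$route, out$dose_mg_per_kg, out$access_hr,
            match(out$tone_db, STARTLE_TONES)), , drop = FALSE]
}

#' Fit the second-order startle dose-response polynomial
#'
#' Least-squares quadratic `V_max = a0 + a1 d + a2 d^2` through the 120 dB
#' dose-response, fitted to per-dose group means (vehicle included as dose
#' 0). Sexes are always fitted separately; the startle effects are
#' sex-dependent.
#'
#' @param doses Dose levels, mg/kg, at least 3 distinct values.
#' @param vmax_means Mean 120 dB V_max (cm/min) at each dose.
#' @param sex Sex label carried into the fit object.
#' @return A `startle_poly` object with elements `sex`, `a0`, `a1`, `a2`,
#'   `rss`, `n`.
#' @export
fit_startle_polynomial <- function(doses, vmax_means, sex = NA_character_) {
  keep <- stats::complete.cases(doses, vmax_means)
  doses <- as.numeric(doses[keep])
  vmax_means <- as.numeric(vmax_means[keep])
  if (length(unique(doses)) < 3L) {
    stop("fit_startle_polynomial(): need >= 3 distinct doses", call. = FALSE)
  }
  X <- cbind(1, doses, doses^2)
  fit <- stats::lm.fit(X, vmax_means)
  cf <- unname(fit$coefficients)
  structure(
    list(sex = sex, a0 = cf[1], a1 = cf[2], a2 = cf[3],
         rss = sum(fit$residuals^2), n = length(doses),
         doses = doses, vmax_means = vmax_means),
    class = "startle_poly"
  )
}

#' @export
print.startle_poly <- function(x, ...) {
  cat(sprintf("Startle quadratic (%s): Vmax = %.4g %+.4g d %+.4g d^2  (RSS = %.4g, n = %d)\n",
              ifelse(is.na(x$sex), "sex pooled", x$sex),
              x$a0, x$a1, x$a2, x$rss, x$n))
  if (!is.na(x$a2) && x$a2 < 0) {
    cat(sprintf("  inverted U; vertex at %.3g mg/kg\n", -x$a1 / (2 * x$a2)))
  }
  invisible(x)
}

#' Dose at the vertex of an inverted-U startle polynomial
#'
#' @param poly A `startle_poly` with `a2 != 0`.
#' @return `-a1 / (2 a2)`, the dose of the curve's extremum.
#' @export
startle_vertex <- function(poly) {
  stopifnot(inherits(poly, "startle_poly"))
  if (poly$a2 == 0) stop("startle_vertex(): a2 is 0 (no vertex)", call. = FALSE)
  -poly$a1 / (2 * poly$a2)
}
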