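#' Gelatin specification
#'
#' Describes one gelatin cup: formulation label (`"CTR"` sugar-water control
#' or `"E"` chocolate-Ensure), treatment (`"VEH"` or `"THC"`), and THC
#' concentration expressed as mg THC per 15 ml gelatin. Gelatin density is
#' taken as 1 g/ml throughout, so mg per 15 ml and mg per 15 g coincide.
#'
#' @param label `"CTR"` or `"E"`.
#' @param treatment `"VEH"` or `"THC"`.
#' @param conc_mg_per_15ml THC concentration, mg per 15 ml gelatin
#'   (0 for vehicle).
#' @return A `gelatin_spec` list.
#' @export
gelatin_spec <- function(label = c("E", "CTR"),
                         treatment = c("THC", "VEH"),
                         conc_mg_per_15ml = 0) {
  label <- match.arg(label)
  treatment <- match.arg(treatment)
  conc_mg_per_15ml <- as.numeric(conc_mg_per_15ml)
  if (is.na(conc_mg_per_15ml) || conc_mg_per_15ml < 0) {
    stop("gelatin_spec(): concentration must be >= 0", call. = FALSE)
  }
  if (treatment == "VEH" && conc_mg_per_15ml != 0) {
    stop("gelatin_spec(): vehicle gelatin must have concentration 0",
         call. = FALSE)
  }
  structure(
    list(label = label, treatment = treatment,
         conc_mg_per_15ml = conc_mg_per_15ml),
    class = "gelatin_spec"
  )
}

#' Grams of gelatin consumed
#'
#' Pre-access minus post-access cup mass. Small negative differences within
#' the evaporation/scale tolerance clamp to zero; a mass *gain* beyond the
#' tolerance is a data error (the cup cannot gain mass during access).
#'
#' @param pre_mass,post_mass Cup masses in grams, both > 0.
#' @param tolerance Allowed apparent mass gain in grams before the row is
#'   rejected; default 0.05 g (drying/scale noise).
#' @return Grams consumed (>= 0).
#' @examples
#' grams_consumed(10.00, 8.10) # 1.90
#' @export
grams_consumed <- function(pre_mass, post_mass, tolerance = 0.05) {
  if (any(pre_mass <= 0) || any(post_mass <= 0)) {
    stop("grams_consumed(): masses must be positive", call. = FALSE)
  }
  if (tolerance < 0) stop("grams_consumed(): tolerance must be >= 0", call. = FALSE)
  diff <- pre_mass - post_mass
  if (any(diff < -tolerance)) {
    stop(sprintf(
      "grams_consumed(): post mass exceeds pre mass by more than %.3g g (cup gained mass)",
      tolerance), call. = FALSE)
  }
  pmax(diff, 0)
}

#' Consumed THC dose in mg per kg body mass
#'
#' Converts grams of gelatin eaten into a THC dose using the gelatin
#' concentration (X mg THC per 15 ml, density 1 g/ml so per 15 g) and the
#' animal's body mass.
#'
#' @param grams Grams of gelatin consumed (>= 0).
#' @param spec A [gelatin_spec()], or a plain numeric concentration in
#'   mg per 15 ml.
#' @param body_mass_g Body mass in grams (> 0).
#' @return Dose in mg/kg.
#' @examples
#' dose_mg_per_kg(1.0, gelatin_spec("E", "THC", 10), 25) # 26.67
#' @export
dose_mg_per_kg <- function(grams, spec, body_mass_g) {
  conc <- if (inherits(spec, "gelatin_spec")) spec$conc_mg_per_15ml else as.numeric(spec)
  if (any(grams < 0)) stop("dose_mg_per_kg(): grams must be >= 0", call. = FALSE)
  if (any(body_mass_g <= 0)) stop("dose_mg_per_kg(): body mass must be > 0", call. = FALSE)
  grams * (conc / 15) / (body_mass_g / 1000)
}

#' Early/late intake rates around a changepoint
#'
#' Splits a cumulative consumption series at a fixed changepoint (default
#' 40 min, the observed plateau onset) and reports the mean intake rate in
#' each segment plus the percent reduction from the early to the late rate.
#'
#' @param minutes Minute marks of the cumulative series (must include 0 or
#'   start from the first bin; the series is taken as 0 at minute 0).
#' @param cumulative_mg Cumulative mass consumed (mg) at each minute mark;
#'   nondecreasing.
#' @param changepoint Changepoint in minutes, strictly inside the window.
#' @return A `rate_pair` list: `r1`, `r2` (mg/min), `percent_reduction`
#'   (`NA` with a flag when `r1` is 0 and `r2` > 0), `changepoint`.
#' @examples
#' m <- seq(0, 120, by = 10)
#' cum <- ifelse(m <= 40, 13 * m, 13 * 40 + 4.2 * (m - 40))
#' piecewise_rates(m, cum) # 13.0, 4.2, 67.7%
#' @export
piecewise_rates <- function(minutes, cumulative_mg, changepoint = 40) {
  minutes <- as.numeric(minutes)
  cumulative_mg <- as.numeric(cumulative_mg)
  ord <- order(minutes)
  minutes <- minutes[ord]
  cumulative_mg <- cumulative_mg[ord]
  if (any(diff(cumulative_mg) < -1e-9)) {
    stop("piecewise_rates(): cumulative series must be nondecreasing", call. = FALSE)
  }
  end <- max(minutes)
  if (!(changepoint > min(0, minutes[1]) && changepoint < end)) {
    stop("piecewise_rates(): changepoint must lie strictly inside the window",
         call. = FALSE)
  }
  if (minutes[1] != 0) {
    minutes <- c(0, minutes)
    cumulative_mg <- c(0, cumulative_mg)
  }
  cum_at <- function(t) {
    stats::approx(minutes, cumulative_mg, xout = t, rule = 2)$y
  }
  c_cp <- cum_at(changepoint)
  c_end <- cumulative_mg[length(cumulative_mg)]
  r1 <- c_cp / changepoint
  r2 <- (c_end - c_cp) / (end - changepoint)
  if (r1 > 0) {
    pr <- 100 * (r1 - r2) / r1
    flag <- FALSE
  } else {
    pr <- if (r2 > 0) NA_real_ else 0
    flag <- r2 > 0
  }
  structure(
    list(r1 = r1, r2 = r2, percent_reduction = pr,
         undefined_reduction = flag, changepoint = changepoint, end = end),
    class = "rate_pair"
  )
}

#' @export
print.rate_pair <- function(x, ...) {
  cat(sprintf("Intake rates: %.2f mg/min (first %g min) -> %.2f mg/min (after)\n",
              x$r1, x$changepoint, x$r2))
  if (isTRUE(x$undefined_reduction)) {
    cat("  percent reduction undefined (zero early rate, positive late rate)\n")
  } else {
    cat(sprintf("  %.1f%% reduction\n", x$percent_reduction))
  }
  invisible(x)
}

#' Least-squares changepoint search for a two-segment intake profile
#'
#' Optional alternative to the fixed 40 min changepoint: scans interior
#' minute marks and returns the changepoint minimizing the residual sum of
#' squares of a continuous two-segment linear fit through the origin.
#'
#' @inheritParams piecewise_rates
#' @return A `rate_pair` with an extra element `rss` at the selected
#'   changepoint.
#' @export
estimate_changepoint <- function(minutes, cumulative_mg) {
  minutes <- as.numeric(minutes)
  cumulative_mg <- as.numeric(cumulative_mg)
  ord <- order(minutes)
  minutes <- minutes[ord]
  cumulative_mg <- cumulative_mg[ord]
  interior <- minutes[minutes > min(minutes) & minutes < max(minutes)]
  if (length(interior) == 0L) {
    stop("estimate_changepoint(): need interior minute marks", call. = FALSE)
  }
  best <- NULL
  for (cp in interior) {
    # continuous piecewise-linear basis through the origin
    x1 <- pmin(minutes, cp)
    x2 <- pmax(minutes - cp, 0)
    fit <- stats::lm.fit(cbind(x1, x2), cumulative_mg)
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(cp = cp, rss = rss)
    }
  }
  out <- piecewise_rates(minutes, cumulative_mg, changepoint = best$cp)
  out$rss <- best$rss
  out
}

#' Fraction of non-consuming animals
#'
#' Proportion of animals whose consumed mass is at or below the detection
#' threshold (default 0 g at 0.01 g scale resolution; the field criterion is
#' an unbroken gelatin surface).
#'
#' @param grams Numeric vector of grams consumed per animal.
#' @param threshold Threshold in grams (>= 0).
#' @return Proportion in `[0, 1]`.
#' @examples
#' nonconsumer_fraction(c(rep(0, 7), runif(10, 0.5, 2))) # 7/17
#' @export
nonconsumer_fraction <- function(grams, threshold = 0) {
  grams <- as.numeric(grams)
  if (length(grams) == 0L) stop("nonconsumer_fraction(): empty input", call. = FALSE)
  if (threshold < 0) stop("nonconsumer_fraction(): threshold must be >= 0", call. = FALSE)
  mean(grams <= threshold)
}
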