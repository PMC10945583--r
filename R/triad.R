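#' Gelatin-dependent difference score
#'
#' The triad response measure: assay value after access minus the value
#' before (`post_pre` mode), or minus the vehicle group's mean post value
#' (`post_minus_veh` mode, used when pre-tests would confound the assay,
#' e.g. open-field habituation).
#'
#' @param pre Pre-access assay value(s); ignored in `post_minus_veh` mode.
#' @param post Post-access assay value(s).
#' @param mode `"post_pre"` (default) or `"post_minus_veh"`.
#' @param veh_post_mean Vehicle-group mean post value; required in
#'   `post_minus_veh` mode.
#' @return Difference score(s) in assay units.
#' @examples
#' difference_score(37.0, 35.2) # -1.8 degrees C
#' @export
difference_score <- function(pre, post, mode = c("post_pre", "post_minus_veh"),
                             veh_post_mean = NULL) {
  mode <- match.arg(mode)
  if (mode == "post_pre") {
    return(post - pre)
  }
  if (is.null(veh_post_mean) || is.na(veh_post_mean)) {
    stop("difference_score(): post_minus_veh mode requires veh_post_mean",
         call. = FALSE)
  }
  post - veh_post_mean
}

# Emax mean function: y = B + (T - B) d / (d + ED50); defined at d = 0.
emax_curve <- function(d, bottom, top, ed50) {
  bottom + (top - bottom) * d / (d + ed50)
}

#' Fit a three-parameter Emax dose-response curve
#'
#' Nonlinear least squares for `y = B + (T - B) d / (d + ED50)` on linear
#' dose, the Hill-slope-1 three-parameter model, defined at dose 0 so that
#' the vehicle group anchors the baseline. Decreasing responses
#' (hypolocomotion, hypothermia) are fitted on signed difference scores
#' with `T < B`. The ED50 is initialized on a log-spaced multistart grid
#' spanning `[min positive dose / 10, max dose * 10]`; the start with the
#' lowest residual sum of squares wins, ties broken toward the smaller ED50.
#'
#' @param doses Dose vector, mg/kg, including 0 (vehicle) or a vehicle
#'   anchor; at least 3 distinct levels and 4 points.
#' @param responses Difference scores, same length as `doses`.
#' @param assay Optional assay label carried into the fit object.
#' @param n_starts Number of multistart grid points for the ED50.
#' @return An object of class `emax_fit` with elements `bottom`, `top`,
#'   `ed50`, `rss`, `vcov`, `n`, `converged`, `extrapolated_top` (TRUE when
#'   the largest tested dose is below 2 x ED50, i.e. the plateau was not
#'   reached and `top` is an extrapolated asymptote), `doses`, `responses`.
#' @examples
#' d <- c(0, 0.3, 1, 3, 10, 30)
#' y <- emax_predict_curve(d, bottom = 0, top = -6, ed50 = 14.4)
#' fit_emax(d, y)
#' @export
fit_emax <- function(doses, responses, assay = NULL, n_starts = 9L) {
  keep <- stats::complete.cases(doses, responses)
  doses <- as.numeric(doses[keep])
  responses <- as.numeric(responses[keep])
  if (any(doses < 0)) stop("fit_emax(): doses must be >= 0", call. = FALSE)
  if (length(doses) < 4L || length(unique(doses)) < 3L) {
    stop("fit_emax(): need >= 4 points over >= 3 distinct dose levels",
         call. = FALSE)
  }
  pos <- unique(doses[doses > 0])
  if (length(pos) == 0L) {
    stop("fit_emax(): need at least one positive dose", call. = FALSE)
  }
  grid <- exp(seq(log(min(pos) / 10), log(max(doses) * 10),
                  length.out = n_starts))
  dat <- data.frame(d = doses, y = responses)
  b0 <- mean(responses[doses == min(doses)])
  t0 <- mean(responses[doses == max(doses)])

  one_start <- function(ed50_start, engine = c("nls", "nlsLM")) {
    engine <- match.arg(engine)
    start <- list(B = b0, T = t0, ED50 = ed50_start)
    form <- y ~ B + (T - B) * d / (d + ED50)
    fit <- if (engine == "nls") {
      try(stats::nls(form, data = dat, start = start, algorithm = "port",
                     lower = c(B = -Inf, T = -Inf, ED50 = 1e-9),
                     control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
          silent = TRUE)
    } else {
      try(minpack.lm::nlsLM(form, data = dat, start = start,
                            lower = c(-Inf, -Inf, 1e-9),
                            control = minpack.lm::nls.lm.control(maxiter = 200)),
          silent = TRUE)
    }
    if (inherits(fit, "try-error")) return(NULL)
    fit
  }

  best <- NULL
  best_rss <- Inf
  for (s in grid) {
    fit <- one_start(s, "nls")
    if (is.null(fit)) fit <- one_start(s, "nlsLM")
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    cf <- stats::coef(fit)
    better <- rss < best_rss - 1e-12 ||
      (abs(rss - best_rss) <= 1e-12 && !is.null(best) &&
         cf[["ED50"]] < stats::coef(best)[["ED50"]])
    if (is.null(best) || better) {
      best <- fit
      best_rss <- rss
    }
  }

  if (is.null(best)) {
    out <- structure(
      list(assay = assay, bottom = NA_real_, top = NA_real_, ed50 = NA_real_,
           rss = NA_real_, vcov = NULL, n = length(doses),
           converged = FALSE, extrapolated_top = NA,
           doses = doses, responses = responses),
      class = "emax_fit"
    )
    return(out)
  }

  cf <- stats::coef(best)
  vc <- tryCatch(stats::vcov(best), error = function(e) NULL)
  span <- abs(cf[["T"]] - cf[["B"]])
  resp_scale <- max(abs(responses - mean(responses)), 1e-12)
  # Degenerate (flat) data: the span is indistinguishable from noise and the
  # ED50 is unidentifiable.
  degenerate <- span < 1e-8 * max(resp_scale, 1) ||
    !is.finite(cf[["ED50"]]) || cf[["ED50"]] > max(doses) * 1e4
  structure(
    list(assay = assay,
         bottom = unname(cf[["B"]]), top = unname(cf[["T"]]),
         ed50 = unname(cf[["ED50"]]), rss = best_rss, vcov = vc,
         n = length(doses), converged = !degenerate,
         extrapolated_top = max(doses) < 2 * cf[["ED50"]],
         doses = doses, responses = responses),
    class = "emax_fit"
  )
}

#' Predicted Emax response at given doses
#'
#' @param object An `emax_fit`.
#' @param dose Doses (mg/kg) at which to evaluate the fitted curve.
#' @param ... Unused.
#' @return Predicted difference scores.
#' @export
predict.emax_fit <- function(object, dose, ...) {
  stopifnot(inherits(object, "emax_fit"))
  if (!isTRUE(object$converged)) {
    stop("predict.emax_fit(): fit did not converge", call. = FALSE)
  }
  emax_curve(dose, object$bottom, object$top, object$ed50)
}

#' Evaluate an Emax curve from explicit parameters
#'
#' Convenience wrapper around the mean function, used by the synthetic
#' generator and in examples.
#'
#' @param dose Doses (mg/kg).
#' @param bottom,top,ed50 Curve parameters (`ed50` > 0).
#' @return Response values.
#' @export
emax_predict_curve <- function(dose, bottom, top, ed50) {
  if (ed50 <= 0) stop("emax_predict_curve(): ed50 must be > 0", call. = FALSE)
  emax_curve(dose, bottom, top, ed50)
}

#' @export
print.emax_fit <- function(x, ...) {
  lbl <- if (is.null(x$assay)) "Emax dose-response fit" else
    sprintf("Emax dose-response fit [%s]", x$assay)
  cat(lbl, "\n")
  if (!isTRUE(x$converged)) {
    cat("  NOT CONVERGED (flagged); downstream inversion will refuse this fit\n")
    return(invisible(x))
  }
  cat(sprintf("  Bottom = %.4g  Top = %.4g  ED50 = %.4g mg/kg  (n = %d, RSS = %.4g)\n",
              x$bottom, x$top, x$ed50, x$n, x$rss))
  if (isTRUE(x$extrapolated_top)) {
    cat("  note: largest tested dose < 2 x ED50; Top is an extrapolated asymptote\n")
  }
  invisible(x)
}

#' Median effective dose of a converged fit
#'
#' The fitted ED50, the dose at which the predicted response is halfway
#' between Bottom and Top.
#'
#' @param fit An `emax_fit`.
#' @return ED50 in mg/kg.
#' @export
ed50 <- function(fit) {
  stopifnot(inherits(fit, "emax_fit"))
  if (!isTRUE(fit$converged)) {
    stop("ed50(): fit is flagged as non-converged", call. = FALSE)
  }
  fit$ed50
}

#' Regression of individual behavioral response on consumed dose
#'
#' Ordinary least squares of per-animal difference scores on per-animal
#' consumed doses (mg/kg) with the F test of zero slope; the same machinery
#' used for the CB1R-blockade (SR141716) contrast, where the expected slope
#' is zero.
#'
#' @param consumed_doses Per-animal consumed dose, mg/kg.
#' @param diffs Per-animal difference scores.
#' @return A `regression_result` (see [linreg_ftest()]).
#' @export
consumption_response_regression <- function(consumed_doses, diffs) {
  linreg_ftest(consumed_doses, diffs)
}
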