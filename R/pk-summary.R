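#' Peak of a concentration time course
#'
#' Maximum group-mean concentration (Cmax) and its time (Tmax) for each
#' analyte x tissue combination.
#'
#' @param pk Data frame with columns `tissue`, `analyte`, `time_hr`,
#'   `conc_pmol_per_g` (per-animal rows are averaged within each time).
#' @return Data frame with columns `tissue`, `analyte`, `cmax_pmol_per_g`,
#'   `tmax_hr` (ties broken toward the earliest time).
#' @export
peak_summary <- function(pk) {
  required <- c("tissue", "analyte", "time_hr", "conc_pmol_per_g")
  miss <- setdiff(required, names(pk))
  if (length(miss) > 0) {
    stop("peak_summary(): missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(pk) == 0L) stop("peak_summary(): empty series", call. = FALSE)
  if (any(pk$conc_pmol_per_g < 0, na.rm = TRUE)) {
    stop("peak_summary(): concentrations must be >= 0", call. = FALSE)
  }
  key <- interaction(pk$tissue, pk$analyte, drop = TRUE, sep = "\r")
  pieces <- split(seq_len(nrow(pk)), key)
  rows <- lapply(pieces, function(idx) {
    sub <- pk[idx, , drop = FALSE]
    means <- tapply(sub$conc_pmol_per_g, sub$time_hr, mean)
    tms <- as.numeric(names(means))
    ord <- order(tms)
    means <- means[ord]
    tms <- tms[ord]
    imax <- which.max(means) # first max on ties
    data.frame(tissue = sub$tissue[1], analyte = sub$analyte[1],
               cmax_pmol_per_g = unname(means[imax]), tmax_hr = tms[imax],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$tissue, out$analyte), , drop = FALSE]
}

#' Normalize group-mean concentrations to a reference time
#'
#' Divides the group-mean concentration at every time by the group mean at
#' the reference time (the shorter 1 hr access condition in the original
#' design), per analyte x tissue. Invariant to global rescaling of the
#' concentration units.
#'
#' @param pk As in [peak_summary()].
#' @param reference_time Reference time in hours; must be present with a
#'   nonzero mean in every analyte x tissue stratum.
#' @return Data frame with columns `tissue`, `analyte`, `time_hr`, `ratio`.
#' @export
normalize_to_reference <- function(pk, reference_time = 1) {
  required <- c("tissue", "analyte", "time_hr", "conc_pmol_per_g")
  miss <- setdiff(required, names(pk))
  if (length(miss) > 0) {
    stop("normalize_to_reference(): missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  key <- interaction(pk$tissue, pk$analyte, drop = TRUE, sep = "\r")
  pieces <- split(seq_len(nrow(pk)), key)
  rows <- lapply(pieces, function(idx) {
    sub <- pk[idx, , drop = FALSE]
    means <- tapply(sub$conc_pmol_per_g, sub$time_hr, mean)
    tms <- as.numeric(names(means))
    ref <- means[match(reference_time, tms)]
    if (is.na(ref)) {
      stop(sprintf("normalize_to_reference(): reference time %g absent for %s/%s",
                   reference_time, sub$tissue[1], sub$analyte[1]), call. = FALSE)
    }
    if (ref == 0) {
      stop("normalize_to_reference(): zero mean at the reference time",
           call. = FALSE)
    }
    data.frame(tissue = sub$tissue[1], analyte = sub$analyte[1],
               time_hr = tms, ratio = unname(means / ref),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$tissue, out$analyte, out$time_hr), , drop = FALSE]
}

#' Regress triad responses on per-animal PK concentrations
#'
#' Pairs per-animal concentration values with per-animal triad difference
#' scores by animal id and delegates to the regression F test. In the
#' original data no significant PK-behavior relationship was found; the
#' synthetic generator likewise produces the two streams independently.
#'
#' @param pk_values Data frame with columns `animal_id`,
#'   `conc_pmol_per_g`.
#' @param triad_diffs Data frame with columns `animal_id`, `diff`.
#' @return A `regression_result` (see [linreg_ftest()]).
#' @export
correlate_pk_behavior <- function(pk_values, triad_diffs) {
  if (!all(c("animal_id", "conc_pmol_per_g") %in% names(pk_values)) ||
      !all(c("animal_id", "diff") %in% names(triad_diffs))) {
    stop("correlate_pk_behavior(): need animal_id + conc_pmol_per_g and animal_id + diff",
         call. = FALSE)
  }
  merged <- merge(pk_values, triad_diffs, by = "animal_id")
  if (nrow(merged) == 0L) {
    stop("correlate_pk_behavior(): no animals in common between the inputs",
         call. = FALSE)
  }
  linreg_ftest(merged$conc_pmol_per_g, merged$diff)
}
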