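# CSV schemas shared between the generator and the analysis stages.
table_schemas <- list(
  consumption = c("animal_id", "sex", "day", "gel_label", "treatment",
                  "conc_mg_per_15ml", "pre_mass_g", "post_mass_g",
                  "body_mass_g"),
  timeseries = c("animal_id", "day", "minute", "cumulative_mg"),
  triad = c("animal_id", "sex", "route", "nominal_dose_or_conc",
            "consumed_mg_per_kg", "assay", "pre", "post"),
  startle = c("animal_id", "sex", "route", "dose_mg_per_kg", "access_hr",
              "tone_db", "vmax_cm_per_min"),
  pk = c("animal_id", "sex", "tissue", "analyte", "time_hr",
         "conc_pmol_per_g")
)

validate_table <- function(df, what, tolerance = 0.05) {
  need <- table_schemas[[what]]
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop(sprintf("%s table: missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  problems <- character(0)
  flag <- function(rows, msg) {
    if (length(rows) > 0) {
      problems <<- c(problems, sprintf("row %d: %s", rows, msg))
    }
  }
  if (what == "consumption") {
    flag(which(df$pre_mass_g <= 0 | df$post_mass_g <= 0),
         "non-positive cup mass")
    flag(which(df$body_mass_g <= 0), "non-positive body mass")
    flag(which(df$post_mass_g - df$pre_mass_g > tolerance),
         "post mass exceeds pre mass beyond tolerance (cup gained mass)")
    flag(which(df$conc_mg_per_15ml < 0), "negative concentration")
    flag(which(df$treatment == "VEH" & df$conc_mg_per_15ml != 0),
         "vehicle gelatin with nonzero concentration")
  } else if (what == "timeseries") {
    flag(which(df$cumulative_mg < 0), "negative cumulative mass")
    for (id in unique(df$animal_id)) {
      sub <- df[df$animal_id == id, , drop = FALSE]
      sub <- sub[order(sub$minute), , drop = FALSE]
      if (any(diff(sub$cumulative_mg) < -1e-9)) {
        problems <- c(problems,
                      sprintf("animal %s: cumulative series decreases", id))
      }
    }
  } else if (what == "triad") {
    flag(which(!df$assay %in% c("locomotion", "tail_flick", "temperature")),
         "unknown assay")
    flag(which(df$consumed_mg_per_kg < 0), "negative consumed dose")
  } else if (what == "startle") {
    flag(which(df$vmax_cm_per_min < 0), "negative V_max")
    flag(which(!as.character(df$tone_db) %in% STARTLE_TONES), "unknown tone")
  } else if (what == "pk") {
    flag(which(df$conc_pmol_per_g < 0), "negative concentration")
  }
  if (length(problems) > 0) {
    stop(sprintf("%s table: %d invalid row(s):\n  %s", what, length(problems),
                 paste(utils::head(problems, 10), collapse = "\n  ")),
         call. = FALSE)
  }
  invisible(df)
}

#' Read and validate cohort CSV tables
#'
#' Reads any subset of the pipeline's five CSV schemas (comma-delimited,
#' UTF-8, fixed lower-snake headers), checks headers and row-level
#' invariants, and reports offending rows with their positions.
#'
#' @param paths Named character vector or list; names from
#'   `consumption`, `timeseries`, `triad`, `startle`, `pk`.
#' @param tolerance Evaporation/scale tolerance (g) for the consumption
#'   pre/post check.
#' @return Named list of validated data frames.
#' @export
read_tables <- function(paths, tolerance = 0.05) {
  paths <- as.list(paths)
  bad <- setdiff(names(paths), names(table_schemas))
  if (length(bad) > 0 || is.null(names(paths))) {
    stop("read_tables(): unknown table name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (what in names(paths)) {
    p <- paths[[what]]
    if (!file.exists(p)) stop("read_tables(): no such file: ", p, call. = FALSE)
    df <- utils::read.csv(p, stringsAsFactors = FALSE)
    if (nrow(df) == 0L) {
      warning(sprintf("read_tables(): %s table is empty", what))
    }
    out[[what]] <- validate_table(df, what, tolerance = tolerance)
  }
  out
}

#' Write cohort tables to CSV
#'
#' @param cohort A `thc_cohort` (or plain named list of the pipeline's
#'   data frames).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_tables <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- intersect(names(table_schemas),
                    names(cohort)[vapply(cohort, is.data.frame, logical(1))])
  paths <- character(0)
  for (what in tabs) {
    p <- file.path(dir, paste0(what, ".csv"))
    utils::write.csv(cohort[[what]], p, row.names = FALSE, quote = FALSE)
    paths[what] <- p
  }
  invisible(paths)
}

#' Pipeline run configuration
#'
#' Exactly one of `simulation` (a [cohort_config()]) or `input` (named CSV
#' paths, see [read_tables()]) drives a run.
#'
#' @param simulation Optional [cohort_config()].
#' @param input Optional named paths.
#' @param changepoint Changepoint for intake rates, minutes.
#' @param nonconsumer_threshold Grams at or below which an animal counts as
#'   a non-consumer.
#' @param allow_extrapolation Permit curve inversion beyond the largest
#'   tested i.p. dose (up to 2x).
#' @param bootstrap_reps Bootstrap replicates for per-behavior predicted
#'   dose CIs (0 disables).
#' @param seed Integer seed (defaults to the simulation config's seed).
#' @param out_dir Optional output directory for the JSON report and CSVs.
#' @return A `run_config` list.
#' @export
run_config <- function(simulation = NULL, input = NULL, changepoint = 40,
                       nonconsumer_threshold = 0, allow_extrapolation = FALSE,
                       bootstrap_reps = 0L, seed = NULL, out_dir = NULL) {
  if (is.null(simulation) == is.null(input)) {
    stop("run_config(): exactly one of simulation/input must be given",
         call. = FALSE)
  }
  if (!is.null(simulation)) validate_cohort_config(simulation)
  if (is.null(seed)) {
    seed <- if (!is.null(simulation)) simulation$seed else 1L
  }
  structure(
    list(simulation = simulation, input = input, changepoint = changepoint,
         nonconsumer_threshold = nonconsumer_threshold,
         allow_extrapolation = allow_extrapolation,
         bootstrap_reps = as.integer(bootstrap_reps),
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Flat-key YAML mapping 1:1 onto [run_config()] and, under the
#' `simulation` block, onto [cohort_config()] (with `assay_params` given as
#' nested `bottom`/`top`/`ed50` maps).
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(raw$simulation)) {
    s <- raw$simulation
    args <- list()
    for (key in c("n_per_group", "sexes", "ip_doses", "gel_concentrations",
                  "oral_dose_cv", "oral_potency", "veh_grams_mean",
                  "ctr_dose_mean", "ctr_nonconsumer_p", "pk_cv",
                  "cup_mass_g", "seed")) {
      if (!is.null(s[[key]])) args[[key]] <- s[[key]]
    }
    if (!is.null(s$oral_dose_means)) args$oral_dose_means <- unlist(s$oral_dose_means)
    if (!is.null(s$noise_sd)) args$noise_sd <- unlist(s$noise_sd)
    if (!is.null(s$body_mass)) args$body_mass <- unlist(s$body_mass)
    if (!is.null(s$assay_params)) {
      args$assay_params <- lapply(s$assay_params, function(p) {
        emax_params(p$bottom, p$top, p$ed50)
      })
    }
    for (key in c("consumption_profile_thc", "consumption_profile_veh")) {
      if (!is.null(s[[key]])) args[[key]] <- do.call(consumption_profile, s[[key]])
    }
    if (!is.null(s$pk)) args$pk <- do.call(pk_params, s$pk)
    if (!is.null(s$startle_params)) {
      sp <- default_startle_params()
      for (nm in names(s$startle_params)) sp[[nm]] <- s$startle_params[[nm]]
      if (!is.null(sp$tone_scale)) sp$tone_scale <- unlist(sp$tone_scale)
      args$startle_params <- sp
    }
    sim <- do.call(cohort_config, args)
  }
  run_config(
    simulation = sim,
    input = raw$input,
    changepoint = raw$changepoint %||% 40,
    nonconsumer_threshold = raw$nonconsumer_threshold %||% 0,
    allow_extrapolation = isTRUE(raw$allow_extrapolation),
    bootstrap_reps = raw$bootstrap_reps %||% 0L,
    seed = raw$seed,
    out_dir = raw$out_dir
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tiny FNV-1a hash over a JSON rendering of the config, for provenance.
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) a cohort, then runs every stage: consumption
#' dosimetry and group summaries, piecewise intake rates, triad Emax fits
#' and ED50s, consumption-response regressions, startle curves and per-sex
#' polynomials, the dose-equivalence prediction chain, PK summaries, and
#' the supporting ANOVA tables. Deterministic given the config and seed.
#'
#' @param config A [run_config()].
#' @return A `pipeline_report` list; if `config$out_dir` is set, the JSON
#'   report and per-stage CSVs are written there as a side effect.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  tables <- if (!is.null(config$simulation)) {
    cohort <- generate_cohort(config$simulation, seed = config$seed)
    cohort[intersect(names(table_schemas), names(cohort))]
  } else {
    read_tables(config$input)
  }
  for (what in names(tables)) validate_table(tables[[what]], what)

  report <- list(
    provenance = list(
      package_version = as.character(utils::packageVersion("triadose")),
      r_version = as.character(getRversion()),
      seed = config$seed,
      simulated = !is.null(config$simulation),
      config_hash = config_hash(config[c("changepoint", "nonconsumer_threshold",
                                         "allow_extrapolation", "seed")])
    )
  )

  # --- consumption ---------------------------------------------------------
  if (!is.null(tables$consumption)) {
    cons <- tables$consumption
    cons$grams <- grams_consumed(cons$pre_mass_g, cons$post_mass_g)
    cons$dose_mg_per_kg <- dose_mg_per_kg(cons$grams, cons$conc_mg_per_15ml,
                                          cons$body_mass_g)
    key <- interaction(cons$gel_label, cons$treatment, cons$conc_mg_per_15ml,
                       drop = TRUE, sep = "/")
    groups <- split(seq_len(nrow(cons)), key)
    summary_rows <- lapply(names(groups), function(g) {
      idx <- groups[[g]]
      data.frame(
        group = g, n = length(idx),
        grams_mean = mean(cons$grams[idx]), grams_sem = sem(cons$grams[idx]),
        dose_mean = mean(cons$dose_mg_per_kg[idx]),
        dose_sem = sem(cons$dose_mg_per_kg[idx]),
        nonconsumer_fraction = nonconsumer_fraction(
          cons$grams[idx], config$nonconsumer_threshold),
        stringsAsFactors = FALSE)
    })
    grams_by_group <- lapply(groups, function(idx) cons$grams[idx])
    usable <- grams_by_group[vapply(grams_by_group, length, integer(1)) >= 2]
    report$consumption <- list(
      groups = do.call(rbind, summary_rows),
      anova_grams = if (length(usable) >= 2) one_way_anova(usable) else NULL
    )
    tables$consumption <- cons
  }

  # --- intake time course --------------------------------------------------
  if (!is.null(tables$timeseries)) {
    ts <- tables$timeseries
    ts$group <- if ("treatment" %in% names(ts)) ts$treatment else "all"
    rate_rows <- lapply(split(ts, ts$group), function(sub) {
      per_animal <- lapply(split(sub, sub$animal_id), function(an) {
        an <- an[order(an$minute), , drop = FALSE]
        piecewise_rates(an$minute, an$cumulative_mg,
                        changepoint = config$changepoint)
      })
      r1 <- vapply(per_animal, function(r) r$r1, numeric(1))
      r2 <- vapply(per_animal, function(r) r$r2, numeric(1))
      # rates are per-animal then averaged; the percent reduction is taken
      # on the mean rates
      pr <- if (mean(r1) > 0) 100 * (mean(r1) - mean(r2)) / mean(r1) else NA_real_
      data.frame(group = sub$group[1], n = length(r1),
                 r1_mean = mean(r1), r1_sem = sem(r1),
                 r2_mean = mean(r2), r2_sem = sem(r2),
                 percent_reduction = pr, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rate_rows)
    rownames(out) <- NULL
    report$intake_rates <- out
  }

  # --- triad ---------------------------------------------------------------
  fits <- NULL
  if (!is.null(tables$triad)) {
    triad <- tables$triad
    triad$diff <- difference_score(triad$pre, triad$post)
    ip <- triad[triad$route == "ip", , drop = FALSE]
    fits <- lapply(split(ip, ip$assay), function(sub) {
      fit_emax(sub$nominal_dose_or_conc, sub$diff, assay = sub$assay[1])
    })
    eg <- triad[triad$route == "e_gel" & !is.na(triad$consumed_mg_per_kg) &
                  triad$consumed_mg_per_kg > 0, , drop = FALSE]
    regressions <- lapply(split(eg, eg$assay), function(sub) {
      if (nrow(sub) < 3 || length(unique(sub$consumed_mg_per_kg)) < 2) {
        return(NULL)
      }
      consumption_response_regression(sub$consumed_mg_per_kg, sub$diff)
    })
    report$triad <- list(
      fits = fits,
      ed50 = vapply(fits, function(f) if (isTRUE(f$converged)) f$ed50 else NA_real_,
                    numeric(1)),
      consumption_regressions = regressions
    )
    tables$triad <- triad
  }

  # --- startle -------------------------------------------------------------
  polys <- NULL
  if (!is.null(tables$startle)) {
    st <- tables$startle
    curves <- startle_curve(st)
    ip120 <- curves[curves$route == "ip" & curves$tone_db == "120", ,
                    drop = FALSE]
    polys <- lapply(split(ip120, ip120$sex), function(sub) {
      if (length(unique(sub$dose_mg_per_kg)) < 3) return(NULL)
      fit_startle_polynomial(sub$dose_mg_per_kg, sub$mean_vmax,
                             sex = sub$sex[1])
    })
    polys <- polys[!vapply(polys, is.null, logical(1))]
    report$startle <- list(curves = curves, polynomials = polys)
  } else {
    warning("run_pipeline(): startle table absent; startle prediction skipped")
  }

  # --- dose equivalence ----------------------------------------------------
  if (!is.null(fits) && !is.null(tables$triad)) {
    triad <- tables$triad
    # oral condition: highest-concentration E-gel group
    egel <- triad[triad$route == "e_gel" &
                    !is.na(triad$nominal_dose_or_conc) &
                    triad$nominal_dose_or_conc > 0, , drop = FALSE]
    if (nrow(egel) > 0) {
      top_conc <- max(egel$nominal_dose_or_conc)
      cond <- egel[egel$nominal_dose_or_conc == top_conc, , drop = FALSE]
      oral_means <- vapply(split(cond, cond$assay),
                           function(sub) mean(sub$diff), numeric(1))
      conv <- fits[vapply(fits, function(f) isTRUE(f$converged), logical(1))]
      oral_means <- oral_means[names(conv)]
      measured <- NULL
      if (!is.null(tables$startle)) {
        oral_st <- tables$startle[tables$startle$route == "e_gel" &
                                    as.character(tables$startle$tone_db) == "120", ,
                                  drop = FALSE]
        if (nrow(oral_st) > 0) {
          sc <- startle_curve(oral_st)
          measured <- data.frame(sex = sc$sex, mean_vmax = sc$mean_vmax,
                                 sem_vmax = sc$sem_vmax,
                                 stringsAsFactors = FALSE)
        }
      }
      report$equivalence <- tryCatch(
        equivalence_report(conv, oral_means,
                           startle_polys = polys,
                           measured_startle = measured,
                           allow_extrapolation = config$allow_extrapolation,
                           label = sprintf("E-gel %g mg/15 ml", top_conc)),
        error = function(e) {
          warning("run_pipeline(): equivalence stage failed: ",
                  conditionMessage(e))
          NULL
        })
    }
  }

  # --- PK ------------------------------------------------------------------
  if (!is.null(tables$pk)) {
    report$pk <- list(
      peaks = peak_summary(tables$pk),
      normalized = normalize_to_reference(tables$pk, reference_time = 1),
      reference_note = paste("reference 1 hr samples come from a shorter",
                             "access condition; ratios retain that provenance")
    )
  }

  class(report) <- "pipeline_report"
  if (!is.null(config$out_dir)) {
    write_tables(tables, config$out_dir)
    write_report_json(report, file.path(config$out_dir, "report.json"))
  }
  report
}

# Rounding used in printed reports: doses and folds at 1 decimal, startle
# at integer cm/min.
display_block <- function(report) {
  eq <- report$equivalence
  if (is.null(eq)) return(NULL)
  out <- list(
    per_behavior_dose = round(unlist(eq$per_behavior_dose), 1),
    aggregate = sprintf("%.1f +/- %s mg/kg i.p.", eq$aggregate_mean,
                        ifelse(is.na(eq$aggregate_sem), "n/a",
                               sprintf("%.1f", eq$aggregate_sem)))
  )
  if (!is.null(eq$fold_ratio)) out$fold_ratio <- sprintf("%.1f", eq$fold_ratio)
  if (!is.null(eq$startle)) {
    out$predicted_startle <- vapply(
      eq$startle, function(s) sprintf("%.0f cm/min", s$predicted_vmax),
      character(1))
  }
  out
}

#' Serialize a pipeline report to JSON
#'
#' Numbers are written at full precision; the key equivalence quantities are
#' duplicated in a `display` block rounded to report precision (doses and
#' fold ratios at 1 decimal, startle at integer cm/min).
#'
#' @param report A `pipeline_report` (or any list).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(report, path) {
  payload <- unclass(report)
  payload$display <- display_block(report)
  payload <- rapply(payload, function(x) {
    if (inherits(x, c("emax_fit", "startle_poly"))) unclass(x) else x
  }, how = "replace", classes = c("emax_fit", "startle_poly"))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report\n")
  if (!is.null(x$consumption)) {
    cat(sprintf("  consumption groups: %d\n", nrow(x$consumption$groups)))
  }
  if (!is.null(x$intake_rates)) {
    for (i in seq_len(nrow(x$intake_rates))) {
      r <- x$intake_rates[i, ]
      cat(sprintf("  intake [%s]: %.1f -> %.1f mg/min (%.1f%% reduction)\n",
                  r$group, r$r1_mean, r$r2_mean, r$percent_reduction))
    }
  }
  if (!is.null(x$triad)) {
    ed <- x$triad$ed50
    cat("  ED50 (mg/kg):",
        paste(sprintf("%s = %.2f", names(ed), ed), collapse = ", "), "\n")
  }
  if (!is.null(x$equivalence)) print(x$equivalence)
  invisible(x)
}
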