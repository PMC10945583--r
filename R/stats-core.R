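#' Standard error of the mean
#'
#' Sample standard deviation (n - 1 denominator) divided by the square root
#' of the number of observations, the dispersion measure reported alongside
#' every group mean in this pipeline.
#'
#' @param x Numeric vector of observations.
#' @return The SEM in the units of `x`; `NA_real_` for a single observation
#'   (SEM is not defined at n = 1).
#' @examples
#' sem(c(10.3, 11.6, 4.5)) # 2.19
#' @export
sem <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0L || all(is.na(x))) {
    stop("sem(): need at least one non-missing value", call. = FALSE)
  }
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  m <- sum(x) / n
  sd_samp <- sqrt(sum((x - m)^2) / (n - 1))
  sd_samp / sqrt(n)
}

#' One-way analysis of variance
#'
#' Between/within sums-of-squares decomposition computed directly from the
#' group structure (no model matrix), with the F statistic referred to the
#' F distribution.
#'
#' @param groups A list of numeric vectors, one per group.
#' @return An object of class `anova_result`: a data frame with one row per
#'   effect (`between`, `within`) and columns `ss`, `df`, `ms`, `F`, `p`.
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(5, 6, 7)))
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("one_way_anova(): need a list of at least two groups", call. = FALSE)
  }
  groups <- lapply(groups, function(g) as.numeric(g[!is.na(g)]))
  n_i <- vapply(groups, length, integer(1))
  if (any(n_i < 2L)) {
    stop("one_way_anova(): every group needs n >= 2", call. = FALSE)
  }
  all_vals <- unlist(groups, use.names = FALSE)
  n <- length(all_vals)
  k <- length(groups)
  grand <- mean(all_vals)
  means <- vapply(groups, mean, numeric(1))
  ss_between <- sum(n_i * (means - grand)^2)
  ss_within <- sum(vapply(seq_len(k), function(i) {
    sum((groups[[i]] - means[i])^2)
  }, numeric(1)))
  df_b <- k - 1L
  df_w <- n - k
  ms_b <- ss_between / df_b
  ms_w <- ss_within / df_w
  f_stat <- if (ms_w > 0) ms_b / ms_w else if (ms_b == 0) 0 else Inf
  p <- stats::pf(f_stat, df_b, df_w, lower.tail = FALSE)
  res <- data.frame(
    effect = c("between", "within"),
    ss = c(ss_between, ss_within),
    df = c(df_b, df_w),
    ms = c(ms_b, ms_w),
    F = c(f_stat, NA_real_),
    p = c(p, NA_real_),
    stringsAsFactors = FALSE
  )
  class(res) <- c("anova_result", "data.frame")
  res
}

#' Two-way analysis of variance on a balanced complete design
#'
#' Cell-mean sums-of-squares decomposition for two crossed factors with
#' equal replication, optionally with a subject blocking key for
#' repeated-measures designs. When `subject` is supplied and each subject
#' appears in exactly one level of factor A (the between factor) while
#' crossing all levels of factor B (the within factor), the split-plot
#' decomposition is used: the A effect is tested against the
#' subject-within-A stratum and B and A:B against the residual
#' subject-by-B stratum.
#'
#' @param values Numeric response vector.
#' @param a,b Factor (or coercible) vectors of the same length as `values`.
#' @param subject Optional subject identifier vector for repeated measures.
#' @return An `anova_result` data frame with one row per tested effect.
#' @export
two_way_anova <- function(values, a, b, subject = NULL) {
  values <- as.numeric(values)
  a <- factor(a)
  b <- factor(b)
  if (length(values) != length(a) || length(values) != length(b)) {
    stop("two_way_anova(): values, a, b must have equal length", call. = FALSE)
  }
  if (anyNA(values)) stop("two_way_anova(): missing values not supported", call. = FALSE)
  tab <- table(a, b)
  if (length(unique(as.vector(tab))) != 1L || tab[1] < 1L) {
    stop("two_way_anova(): design must be balanced and complete", call. = FALSE)
  }
  n_rep <- as.vector(tab)[1]
  la <- nlevels(a)
  lb <- nlevels(b)
  n <- length(values)
  grand <- mean(values)
  mean_a <- tapply(values, a, mean)
  mean_b <- tapply(values, b, mean)
  mean_ab <- tapply(values, list(a, b), mean)
  ss_a <- lb * n_rep * sum((mean_a - grand)^2)
  ss_b <- la * n_rep * sum((mean_b - grand)^2)
  ss_ab <- n_rep * sum((mean_ab - outer(mean_a - grand, mean_b - grand, "+") - grand)^2)
  ss_tot <- sum((values - grand)^2)

  if (is.null(subject)) {
    if (n_rep < 2L) {
      stop("two_way_anova(): need replication (or a subject key) to estimate error",
           call. = FALSE)
    }
    ss_err <- ss_tot - ss_a - ss_b - ss_ab
    df <- c(la - 1L, lb - 1L, (la - 1L) * (lb - 1L), n - la * lb)
    ss <- c(ss_a, ss_b, ss_ab, ss_err)
    ms <- ss / df
    f_stat <- c(safe_f(ms[1:3], ms[4]), NA_real_)
    p <- c(stats::pf(f_stat[1:3], df[1:3], df[4], lower.tail = FALSE), NA_real_)
    res <- data.frame(
      effect = c("A", "B", "A:B", "residual"),
      ss = ss, df = df, ms = ms, F = f_stat, p = p,
      stringsAsFactors = FALSE
    )
    class(res) <- c("anova_result", "data.frame")
    return(res)
  }

  subject <- factor(subject)
  # subjects must be nested in A and crossed with B
  subj_a <- table(subject, a)
  if (any(rowSums(subj_a > 0) != 1L)) {
    stop("two_way_anova(): each subject must appear in exactly one level of a",
         call. = FALSE)
  }
  subj_b <- table(subject, b)
  if (any(subj_b != 1L)) {
    stop("two_way_anova(): each subject must appear exactly once per level of b",
         call. = FALSE)
  }
  n_subj_per_a <- n_rep # subjects per A level
  mean_subj <- tapply(values, subject, mean)
  # SS for subjects (includes A); subject-within-A removes the A part
  ss_subj_total <- lb * sum((mean_subj - grand)^2)
  ss_subj_within_a <- ss_subj_total - ss_a
  ss_err <- ss_tot - ss_subj_total - ss_b - ss_ab
  df_a <- la - 1L
  df_sw <- la * (n_subj_per_a - 1L)
  df_b <- lb - 1L
  df_ab <- (la - 1L) * (lb - 1L)
  df_err <- df_sw * df_b
  ms_a <- ss_a / df_a
  ms_sw <- ss_subj_within_a / df_sw
  ms_b <- ss_b / df_b
  ms_ab <- ss_ab / df_ab
  ms_err <- ss_err / df_err
  f_a <- safe_f(ms_a, ms_sw)
  f_b <- safe_f(ms_b, ms_err)
  f_ab <- safe_f(ms_ab, ms_err)
  res <- data.frame(
    effect = c("A", "subject(A)", "B", "A:B", "residual"),
    ss = c(ss_a, ss_subj_within_a, ss_b, ss_ab, ss_err),
    df = c(df_a, df_sw, df_b, df_ab, df_err),
    ms = c(ms_a, ms_sw, ms_b, ms_ab, ms_err),
    F = c(f_a, NA_real_, f_b, f_ab, NA_real_),
    p = c(stats::pf(f_a, df_a, df_sw, lower.tail = FALSE), NA_real_,
          stats::pf(f_b, df_b, df_err, lower.tail = FALSE),
          stats::pf(f_ab, df_ab, df_err, lower.tail = FALSE), NA_real_),
    stringsAsFactors = FALSE
  )
  class(res) <- c("anova_result", "data.frame")
  res
}

#' Sidak multiplicity adjustment
#'
#' Adjusts a raw p-value for `m` independent comparisons:
#' `1 - (1 - p)^m`, capped at 1.
#'
#' @param p Raw p-value(s) in `[0, 1]`.
#' @param m Number of comparisons in the family (>= 1).
#' @return Adjusted p-value(s).
#' @examples
#' sidak_adjust(0.01, 3) # 0.029701
#' @export
sidak_adjust <- function(p, m) {
  if (any(m < 1)) stop("sidak_adjust(): m must be >= 1", call. = FALSE)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("sidak_adjust(): p must lie in [0, 1]", call. = FALSE)
  }
  # m = 1 is an exact fixed point (avoids 1 - (1 - p) rounding)
  n <- max(length(p), length(m))
  p <- rep_len(p, n)
  m <- rep_len(m, n)
  adj <- pmin(1, 1 - (1 - p)^m)
  adj[m == 1] <- p[m == 1]
  adj
}

#' Simple linear regression with F test of zero slope
#'
#' Ordinary least squares through the normal equations, reporting the slope,
#' intercept, R-squared and the F test of the slope with (1, n - 2) degrees
#' of freedom. This F equals the square of the slope's t statistic.
#'
#' @param x,y Numeric vectors of equal length (>= 3 points).
#' @return An object of class `regression_result` (a list) with elements
#'   `slope`, `intercept`, `F`, `df1`, `df2`, `p`, `r_squared`, `n`.
#' @export
linreg_ftest <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- as.numeric(x[keep])
  y <- as.numeric(y[keep])
  n <- length(x)
  if (n < 3L) stop("linreg_ftest(): need at least 3 complete points", call. = FALSE)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("linreg_ftest(): x is constant", call. = FALSE)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  ss_reg <- slope^2 * sxx
  ss_res <- syy - ss_reg
  df2 <- n - 2L
  ms_res <- ss_res / df2
  f_stat <- if (ms_res > 0) ss_reg / ms_res else if (ss_reg == 0) 0 else Inf
  r2 <- if (syy > 0) ss_reg / syy else NA_real_
  res <- list(
    slope = slope, intercept = intercept,
    F = f_stat, df1 = 1L, df2 = df2,
    p = stats::pf(f_stat, 1, df2, lower.tail = FALSE),
    r_squared = r2, n = n
  )
  class(res) <- "regression_result"
  res
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("Linear regression (n = %d)\n", x$n))
  cat(sprintf("  slope = %.4g, intercept = %.4g, R^2 = %.4f\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  F(%d, %d) = %.4g, p %s\n", x$df1, x$df2, x$F,
              format_p(x$p)))
  invisible(x)
}

# F ratio with the 0/0 (no-variance) case defined as 0.
safe_f <- function(ms_effect, ms_error) {
  n <- max(length(ms_effect), length(ms_error))
  ms_effect <- rep_len(ms_effect, n)
  ms_error <- rep_len(ms_error, n)
  out <- ms_effect / ms_error
  out[ms_error <= 0] <- ifelse(ms_effect[ms_error <= 0] == 0, 0, Inf)
  out
}

# Threshold-style p formatting used in printed reports.
format_p <- function(p) {
  if (is.na(p)) return("= NA")
  if (p < 1e-15) return("< 1e-15")
  if (p < 0.001) return("< 0.001")
  sprintf("= %.3g", p)
}
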