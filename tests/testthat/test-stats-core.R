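test_that("sem matches its definition and edge rules", {
  expect_equal(sem(c(1, 1, 1)), 0)
  expect_equal(sem(c(0, 2)), 1) # SD sqrt(2), / sqrt(2)
  expect_equal(round(sem(c(10.3, 11.6, 4.5)), 1), 2.2)
  expect_true(is.na(sem(5)))
  expect_error(sem(numeric(0)), "non-missing")
  # brute-force oracle on random vectors
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(sample(2:30, 1))
    expect_equal(sem(x), sd(x) / sqrt(length(x)), tolerance = 1e-12)
  }
})

test_that("one-way ANOVA reproduces the sums-of-squares decomposition", {
  # identical groups: no between-group variance
  g <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  res <- one_way_anova(g)
  expect_equal(res$F[1], 0)
  expect_equal(res$p[1], 1)

  # two groups: F equals the squared pooled t statistic
  set.seed(21)
  a <- rnorm(8, 0, 1)
  b <- rnorm(10, 0.7, 1)
  res2 <- one_way_anova(list(a, b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res2$F[1], unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res2$p[1], tt$p.value, tolerance = 1e-10)

  # three-group fixture against both a brute-force oracle and aov
  g3 <- list(c(5.1, 4.8, 5.5, 5.0), c(6.2, 6.8, 6.0, 6.4), c(4.0, 4.4, 3.8, 4.1))
  res3 <- one_way_anova(g3)
  vals <- unlist(g3)
  grp <- factor(rep(seq_along(g3), lengths(g3)))
  ss_b <- sum(lengths(g3) * (sapply(g3, mean) - mean(vals))^2)
  ss_w <- sum(sapply(g3, function(x) sum((x - mean(x))^2)))
  expect_equal(res3$ss, c(ss_b, ss_w), tolerance = 1e-12)
  aov_tab <- summary(aov(vals ~ grp))[[1]]
  expect_equal(res3$F[1], aov_tab[["F value"]][1], tolerance = 1e-10)
  expect_equal(res3$p[1], aov_tab[["Pr(>F)"]][1], tolerance = 1e-10)

  expect_error(one_way_anova(list(c(1, 2), c(3))), "n >= 2")
  expect_error(one_way_anova(list(c(1, 2))), "two groups")
})

test_that("ANOVA F is location invariant and scale invariant", {
  set.seed(31)
  g <- list(rnorm(6), rnorm(6, 1), rnorm(6, 2))
  f0 <- one_way_anova(g)$F[1]
  expect_equal(one_way_anova(lapply(g, `+`, 100))$F[1], f0, tolerance = 1e-9)
  expect_equal(one_way_anova(lapply(g, `*`, 3.7))$F[1], f0, tolerance = 1e-9)
})

test_that("two-way ANOVA matches aov on balanced designs", {
  set.seed(41)
  df <- expand.grid(a = factor(1:2), b = factor(1:3), rep = 1:4)
  df$y <- rnorm(nrow(df)) + as.numeric(df$a) + 0.5 * as.numeric(df$b)
  res <- two_way_anova(df$y, df$a, df$b)
  aov_tab <- summary(aov(y ~ a * b, data = df))[[1]]
  expect_equal(res$F[1:3], aov_tab[["F value"]][1:3], tolerance = 1e-10)
  expect_equal(res$p[1:3], aov_tab[["Pr(>F)"]][1:3], tolerance = 1e-10)
  # SS decomposition is exhaustive on balanced data
  expect_equal(sum(res$ss), sum((df$y - mean(df$y))^2), tolerance = 1e-10)
})

test_that("two-way ANOVA degenerate structures behave", {
  df <- expand.grid(a = factor(1:2), b = factor(1:2), rep = 1:3)
  df$y <- 5
  res <- two_way_anova(df$y, df$a, df$b)
  expect_true(all(res$F[1:3] == 0))
  # purely additive data: interaction F ~ 0
  df$y <- 2 * as.numeric(df$a) + 3 * as.numeric(df$b)
  res2 <- two_way_anova(df$y, df$a, df$b)
  expect_equal(res2$ss[res2$effect == "A:B"], 0, tolerance = 1e-18)
  # unbalanced designs are out of scope
  expect_error(two_way_anova(df$y[-1], df$a[-1], df$b[-1]), "balanced")
})

test_that("subject-blocked two-way ANOVA matches aov's split-plot strata", {
  set.seed(51)
  n_subj <- 8
  df <- expand.grid(subject = factor(1:(2 * n_subj)), b = factor(1:4))
  df$a <- factor(ifelse(as.integer(df$subject) <= n_subj, "thc", "veh"))
  subj_eff <- rnorm(2 * n_subj, 0, 0.8)
  df$y <- rnorm(nrow(df)) + subj_eff[as.integer(df$subject)] +
    (df$a == "thc") * 1.2 + as.numeric(df$b) * 0.3
  res <- two_way_anova(df$y, df$a, df$b, subject = df$subject)
  ref <- summary(aov(y ~ a * b + Error(subject/b), data = df))
  f_a <- ref[["Error: subject"]][[1]][["F value"]][1]
  f_b <- ref[[2]][[1]][["F value"]][1]
  f_ab <- ref[[2]][[1]][["F value"]][2]
  expect_equal(res$F[res$effect == "A"], f_a, tolerance = 1e-8)
  expect_equal(res$F[res$effect == "B"], f_b, tolerance = 1e-8)
  expect_equal(res$F[res$effect == "A:B"], f_ab, tolerance = 1e-8)
  expect_equal(res$df[res$effect == "A"], 1)
  expect_equal(res$df[res$effect == "subject(A)"], 2 * (n_subj - 1))
})

test_that("Sidak adjustment identities and monotonicity hold", {
  expect_equal(sidak_adjust(0.05, 1), 0.05)
  expect_equal(sidak_adjust(0.01, 3), 1 - 0.99^3) # 0.029701
  expect_equal(sidak_adjust(0.5, 2), 0.75)
  expect_equal(sidak_adjust(1, 5), 1)
  p <- seq(0, 1, by = 0.05)
  for (m in c(1, 2, 5, 10)) {
    adj <- sidak_adjust(p, m)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj) >= 0)) # monotone in p
  }
  expect_true(all(sidak_adjust(0.2, 1:10) == cummax(sidak_adjust(0.2, 1:10))))
  expect_error(sidak_adjust(0.05, 0), "m must be")
})

test_that("regression F test agrees with lm and its algebraic identities", {
  set.seed(61)
  x <- runif(20, 0, 10)
  y <- 2 + 0.8 * x + rnorm(20)
  res <- linreg_ftest(x, y)
  ref <- summary(lm(y ~ x))
  expect_equal(res$slope, unname(coef(ref)["x", "Estimate"]), tolerance = 1e-10)
  expect_equal(res$F, unname(ref$fstatistic["value"]), tolerance = 1e-10)
  expect_equal(res$r_squared, ref$r.squared, tolerance = 1e-10)
  # F = t^2 for the slope
  expect_equal(res$F, unname(coef(ref)["x", "t value"])^2, tolerance = 1e-10)

  # perfect line
  res2 <- linreg_ftest(1:5, 2 * (1:5) + 1)
  expect_equal(res2$r_squared, 1)
  # constant y
  res3 <- linreg_ftest(1:5, rep(3, 5))
  expect_equal(res3$slope, 0)
  expect_equal(res3$F, 0)
  expect_error(linreg_ftest(rep(1, 5), rnorm(5)), "constant")
})
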