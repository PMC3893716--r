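test_that("mixed ANOVA reproduces the brute-force SS oracle exactly", {
  d <- make_mixed_table(n_per_group = 3, seed = 1)
  fit <- mixed_anova(d, dv = "y", subject = "subject", between = "group",
                     within = c("a", "b"))
  orc <- anova_oracle(d, dv = "y", subject = "subject", between = "group",
                      within = c("a", "b"))
  expect_setequal(fit$effect, orc$effect)
  for (e in orc$effect) {
    i <- match(e, fit$effect); j <- match(e, orc$effect)
    expect_equal(fit$statistic[i], orc$statistic[j], tolerance = 1e-10,
                 label = paste("F for", e))
    expect_identical(as.numeric(fit$df_num[i]), as.numeric(orc$df_num[j]))
    expect_identical(as.numeric(fit$df_den[i]), as.numeric(orc$df_den[j]))
    expect_equal(fit$p_value[i], orc$p_value[j], tolerance = 1e-10)
  }
})

test_that("one within factor designs also match the oracle", {
  d <- make_mixed_table(n_per_group = 4, seed = 3, a_levels = 3, b_levels = 1)
  d$b <- NULL
  fit <- mixed_anova(d, dv = "y", subject = "subject", between = "group",
                     within = "a")
  orc <- anova_oracle(d, dv = "y", subject = "subject", between = "group",
                      within = "a")
  for (e in orc$effect) {
    expect_equal(fit$statistic[match(e, fit$effect)],
                 orc$statistic[match(e, orc$effect)], tolerance = 1e-10)
  }
})

test_that("duplicating every subject doubles the error df consistently", {
  d <- make_mixed_table(n_per_group = 2, seed = 5)
  d2 <- rbind(d, transform(d, subject = paste0(subject, "_copy")))
  fit2 <- mixed_anova(d2, dv = "y", subject = "subject", between = "group",
                      within = c("a", "b"))
  orc2 <- anova_oracle(d2, dv = "y", subject = "subject", between = "group",
                       within = c("a", "b"))
  fit1 <- mixed_anova(d, dv = "y", subject = "subject", between = "group",
                      within = c("a", "b"))
  for (e in orc2$effect) {
    expect_equal(fit2$statistic[match(e, fit2$effect)],
                 orc2$statistic[match(e, orc2$effect)], tolerance = 1e-10)
  }
  expect_identical(fit2$df_den[fit2$effect == "group"],
                   2 * fit1$df_den[fit1$effect == "group"] + 2)
})

test_that("identical group cell means give a zero between-group F", {
  # exactly mirrored subjects in each group: zero between-group SS,
  # nonzero within-group noise
  d <- expand.grid(subject = paste0("s", 1:4), a = c("a1", "a2"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(d$subject %in% c("s1", "s2"), "g1", "g2")
  base <- c(s1 = -1, s2 = 1, s3 = -1, s4 = 1)
  d$y <- base[d$subject] + ifelse(d$a == "a1", 0, 2)
  fit <- mixed_anova(d, dv = "y", subject = "subject", between = "group",
                     within = "a")
  expect_equal(fit$statistic[fit$effect == "group"], 0, tolerance = 1e-12)
})

test_that("with no within factors the fit reduces to a one-way ANOVA", {
  set.seed(8)
  d <- data.frame(subject = paste0("s", 1:12),
                  group = rep(c("g1", "g2", "g3"), each = 4),
                  y = rnorm(12))
  fit <- mixed_anova(d, dv = "y", subject = "subject", between = "group")
  orc <- oneway_oracle(d$y, d$group)
  expect_equal(fit$statistic, orc$statistic, tolerance = 1e-10)
  expect_equal(fit$p_value, orc$p_value, tolerance = 1e-10)
  expect_identical(as.numeric(fit$df_den), as.numeric(orc$df_den))
})

test_that("statistics are invariant to row order and tolerate constant levels", {
  d <- make_mixed_table(n_per_group = 3, seed = 11)
  fit <- mixed_anova(d, dv = "y", subject = "subject", between = "group",
                     within = c("a", "b"))
  set.seed(1)
  dp <- d[sample(nrow(d)), ]
  fitp <- mixed_anova(dp, dv = "y", subject = "subject", between = "group",
                      within = c("a", "b"))
  expect_equal(fit$statistic, fitp$statistic, tolerance = 1e-12)

  # a zero-variance factor level (like a normalized baseline block) must not
  # break the decomposition
  d$y[d$b == "b1"] <- 1
  fitc <- mixed_anova(d, dv = "y", subject = "subject", between = "group",
                      within = c("a", "b"))
  expect_true(all(is.finite(fitc$statistic)))
})

test_that("unbalanced or underpowered designs raise informative errors", {
  d <- make_mixed_table(n_per_group = 2, seed = 13)
  expect_error(mixed_anova(d[-1, ], dv = "y", subject = "subject",
                           between = "group", within = c("a", "b")),
               "unbalanced")
  d1 <- d[d$subject != "s1", ]
  expect_error(mixed_anova(d1, dv = "y", subject = "subject",
                           between = "group", within = c("a", "b")),
               "at least 2 subjects")
})

test_that("the pooled t test matches its closed form and conventions", {
  a <- c(1, 2, 3, 5, 8)
  expect_equal(student_t(a, a)$statistic, 0)
  expect_equal(student_t(a, a)$p_value, 1)

  b <- c(1, 2, 3) + 10
  t1 <- student_t(c(1, 2, 3), b)
  orc <- t_oracle(c(1, 2, 3), b)
  expect_equal(t1$statistic, orc$statistic, tolerance = 1e-10)
  expect_equal(t1$p_value, orc$p_value, tolerance = 1e-10)
  expect_identical(t1$df, orc$df)

  t2 <- student_t(b, c(1, 2, 3))
  expect_equal(t2$statistic, -t1$statistic)
  expect_equal(t2$p_value, t1$p_value)

  tdeg <- student_t(c(2, 2), c(5, 5))
  expect_true(tdeg$degenerate)
  expect_identical(tdeg$p_value, 0)
  expect_true(is.infinite(tdeg$statistic))
  expect_error(student_t(1, c(1, 2)), "at least 2")
})

test_that("Pearson correlation matches the covariance-ratio oracle", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, 2 * x + 1)$estimate, 1)
  expect_equal(pearson_r(x, -x)$estimate, -1)

  y <- c(1, 3, 2, 4)
  r1 <- pearson_r(x, y)
  orc <- r_oracle(x, y)
  expect_equal(r1$estimate, orc$estimate, tolerance = 1e-12)
  expect_equal(r1$statistic, orc$statistic, tolerance = 1e-10)
  expect_equal(r1$p_value, orc$p_value, tolerance = 1e-10)

  # invariant to positive affine rescaling of either variable
  r2 <- pearson_r(3 * x + 7, y)
  r3 <- pearson_r(x, 0.1 * y - 2)
  expect_equal(r2$estimate, r1$estimate, tolerance = 1e-12)
  expect_equal(r3$estimate, r1$estimate, tolerance = 1e-12)

  rdeg <- pearson_r(c(1, 1, 1), c(1, 2, 3))
  expect_true(rdeg$degenerate)
  expect_true(is.na(rdeg$estimate))
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})
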