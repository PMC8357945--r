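test_that("one-way ANOVA matches the direct sum-of-squares formula", {
  # classic 3-group layout, F computed from first principles
  df <- data.frame(
    g = rep(c("a", "b", "c"), each = 5),
    y = c(6.9, 5.4, 5.8, 4.6, 4.0,
          8.3, 6.8, 7.8, 9.2, 6.5,
          8.0, 10.5, 8.1, 6.9, 9.3)
  )
  grand <- mean(df$y)
  ssb <- sum(tapply(df$y, df$g, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(df$y, df$g, function(v) sum((v - mean(v))^2)))
  f_oracle <- (ssb / 2) / (ssw / 12)
  fit <- anova_oneway_tukey(df, y, g)
  expect_equal(glance(fit)$statistic, f_oracle, tolerance = 1e-10)
  expect_equal(nrow(tidy(fit, "contrasts")), 3)
})

test_that("degenerate and extreme-separation inputs are handled", {
  flat <- data.frame(g = rep(c("a", "b"), each = 3), y = rep(1, 6))
  fit <- anova_oneway_tukey(flat, y, g)
  expect_true(glance(fit)$no_test)
  expect_equal(nrow(tidy(fit)), 0)

  withr::local_seed(31)
  sep <- data.frame(
    g = rep(c("a", "b"), each = 3),
    y = c(rnorm(3, 0, 1e-4), rnorm(3, 10, 1e-4))
  )
  expect_lt(glance(anova_oneway_tukey(sep, y, g))$p.value, 1e-6)

  expect_error(anova_oneway_tukey(data.frame(g = "a", y = 1), y, g), "groups")
})

test_that("two-way type-II reduces to classical ANOVA on balanced designs", {
  withr::local_seed(32)
  df <- expand.grid(handling = c("TH", "CC"),
                    treatment = c("Veh", "DIPH", "PS150"),
                    rep = 1:8)
  df$y <- rnorm(nrow(df)) + 2 * (df$handling == "CC")
  fit <- anova_twoway_bonferroni(df, y, handling, treatment)
  # classical (sequential, balanced) decomposition from aov
  cl <- summary(aov(y ~ handling * treatment, data = df))[[1]]
  rownames(cl) <- trimws(rownames(cl))
  eff <- tidy(fit)
  expect_equal(eff$sumsq[eff$term == "handling"], cl["handling", "Sum Sq"],
               tolerance = 1e-10)
  expect_equal(eff$sumsq[eff$term == "treatment"], cl["treatment", "Sum Sq"],
               tolerance = 1e-10)
  expect_equal(eff$sumsq[eff$term == "handling:treatment"],
               cl["handling:treatment", "Sum Sq"], tolerance = 1e-10)
  # planned contrasts: treatment pairs within handling + handling pairs
  # within treatment
  expect_equal(nrow(tidy(fit, "contrasts")), 2 * 3 + 3 * 1)
})

test_that("F statistics are invariant to affine response transforms", {
  withr::local_seed(33)
  df <- expand.grid(handling = c("TH", "CC"),
                    treatment = c("Veh", "DIPH"), rep = 1:6)
  df$y <- rnorm(nrow(df)) + (df$treatment == "DIPH")
  f1 <- tidy(anova_twoway_bonferroni(df, y, handling, treatment))
  df$y2 <- 100 + 7 * df$y
  f2 <- tidy(anova_twoway_bonferroni(df, y2, handling, treatment))
  expect_equal(f1$statistic, f2$statistic, tolerance = 1e-10)
})

test_that("a single planned contrast is not penalized by Bonferroni", {
  withr::local_seed(34)
  df <- expand.grid(handling = c("TH", "CC"), treatment = c("Veh", "DIPH"),
                    rep = 1:6)
  df$y <- rnorm(nrow(df))
  fit <- anova_twoway_bonferroni(df, y, handling, treatment)
  ct <- tidy(fit, "contrasts")
  # with two treatments each within-handling family holds one contrast, so
  # the Bonferroni-adjusted p equals the raw t-test p from the model fit
  mod <- lm(y ~ handling * treatment, data = df)
  em <- emmeans::emmeans(mod, "treatment", by = "handling")
  raw <- as.data.frame(emmeans::contrast(em, "pairwise", adjust = "none"))
  got <- ct$adj.p.value[grepl("handling=TH", ct$contrast)][1]
  expect_equal(got, raw$p.value[raw$handling == "TH"], tolerance = 1e-10)
})

test_that("missing design cells raise an error naming the cell", {
  df <- expand.grid(handling = c("TH", "CC"), treatment = c("Veh", "DIPH"),
                    rep = 1:3)
  df$y <- rnorm(nrow(df))
  df <- df[!(df$handling == "CC" & df$treatment == "DIPH"), ]
  expect_error(anova_twoway_bonferroni(df, y, handling, treatment), "CC:DIPH")
})

test_that("a planted handling shift is detected with high power", {
  withr::local_seed(35)
  hits <- 0
  reps <- 120
  for (i in seq_len(reps)) {
    df <- expand.grid(handling = c("TH", "CC"),
                      treatment = c("Veh", "DIPH", "PS150"), rep = 1:8)
    df$y <- rnorm(nrow(df)) + 3 * (df$handling == "CC") # 3x residual SD
    eff <- tidy(anova_twoway_bonferroni(df, y, handling, treatment))
    p_h <- eff$p.value[eff$term == "handling"]
    p_i <- eff$p.value[eff$term == "handling:treatment"]
    if (p_h < 0.05 && p_i > 0.05) hits <- hits + 1
  }
  expect_gt(hits / reps, 0.9)
})

test_that("one-way type-I error stays near nominal under the null", {
  withr::local_seed(36)
  reps <- 600
  p <- vapply(seq_len(reps), function(i) {
    df <- data.frame(g = rep(c("a", "b", "c"), each = 8), y = rnorm(24))
    glance(anova_oneway_tukey(df, y, g))$p.value
  }, numeric(1))
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.025)
  # and the p distribution is uniform
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("group summaries report mean, SEM and n", {
  df <- data.frame(g = rep(c("a", "b"), each = 4),
                   y = c(1, 2, 3, 4, 10, 10, 10, 10))
  gs <- group_summary(df, y, g)
  expect_equal(gs$mean, c(2.5, 10))
  expect_equal(gs$sem[1], sd(1:4) / 2)
  expect_equal(gs$sem[2], 0)
  expect_equal(gs$n, c(4L, 4L))
})

test_that("cohort_stats drives both procedures from the long table", {
  withr::local_seed(37)
  tab <- expand.grid(handling = c("TH", "CC"),
                     treatment = c("Veh", "DIPH"), animal = 1:4)
  tab$animal_id <- paste0(tab$handling, tab$treatment, tab$animal)
  tab$window <- "light"
  tab$metric <- "total_N"
  tab$value <- rnorm(nrow(tab)) - 2 * (tab$handling == "CC")
  tab$censored <- 0
  out <- cohort_stats(tibble::as_tibble(tab), metrics = "total_N")
  expect_true("handling" %in% out$term)
  expect_lt(out$p.value[out$term == "handling"], 0.05)

  one <- tab[tab$handling == "TH", ]
  out1 <- cohort_stats(tibble::as_tibble(one), metrics = "total_N")
  expect_true("group" %in% out1$term)
})
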