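test_that("split-plot SS decomposition matches hand computation and aov", {
  # 2 groups x 2 subjects x 2 conditions, hand-computable
  tab <- data.frame(
    subject_id = rep(c("s1", "s2", "s3", "s4"), each = 2),
    group = rep(c("young", "young", "old", "old"), each = 2),
    condition = rep(c("ST", "DT1"), 4),
    pm = 1L,
    y = c(1, 2, 2, 4, 3, 5, 4, 8))
  res <- splitPlotAnova(tab, "y", 1)
  get <- function(eff, col) res[res$effect == eff, col]
  # frozen hand values: SS_group 15.125 / SS_subj 6.25 (df 1,2);
  # SS_cond 10.125 / SS_err 1.25 (df 1,2); SS_int 1.125
  expect_equal(get("group", "F"), 4.84, tolerance = 1e-10)
  expect_equal(get("condition", "F"), 16.2, tolerance = 1e-10)
  expect_equal(get("condition:group", "F"), 1.8, tolerance = 1e-10)
  expect_equal(get("group", "df2"), 2)
  expect_equal(get("condition", "df2"), 2)

  orc <- aovOracle(tab)
  expect_equal(get("group", "F"), unname(orc$F_group), tolerance = 1e-10)
  expect_equal(get("condition", "F"), unname(orc$F_cond), tolerance = 1e-10)
  expect_equal(get("condition:group", "F"), unname(orc$F_int),
               tolerance = 1e-10)
})

test_that("balanced 5-condition designs reproduce aov exactly", {
  set.seed(71)
  tab <- makeMeasureTable(n_per_group = c(8L, 8L), n_cond = 5L,
                          cond_effects = c(0, 0.4, 0.7, 0.4, 0))
  res <- splitPlotAnova(tab, "y", 1, correct = "never")
  orc <- aovOracle(tab)
  expect_equal(res$F[res$effect == "condition"], unname(orc$F_cond),
               tolerance = 1e-10)
  expect_equal(res$F[res$effect == "group"], unname(orc$F_group),
               tolerance = 1e-10)
  expect_equal(res$F[res$effect == "condition:group"], unname(orc$F_int),
               tolerance = 1e-10)
})

test_that("study-sized design yields the printed df structure", {
  set.seed(5)
  tab <- makeMeasureTable(n_per_group = c(23L, 18L), n_cond = 5L)
  res <- splitPlotAnova(tab, "y", 1)
  expect_equal(res[res$effect == "group", c("df1", "df2")],
               data.frame(df1 = 1, df2 = 39), ignore_attr = TRUE)
  expect_equal(res[res$effect == "condition", c("df1", "df2")],
               data.frame(df1 = 4, df2 = 156), ignore_attr = TRUE)
  expect_equal(res[res$effect == "condition:group", c("df1", "df2")],
               data.frame(df1 = 4, df2 = 156), ignore_attr = TRUE)
  expect_equal(res$n_subjects[1], 41)
})

test_that("Mauchly test and epsilons match the car oracle, HF >= GG", {
  skip_if_not_installed("car")
  for (s in 1:5) {
    set.seed(100 + s)
    N <- 14; cl <- 4
    Y <- matrix(rnorm(N * cl), N, cl)
    Y[, 2] <- Y[, 2] + 0.7 * Y[, 1]  # induce non-sphericity
    grp <- factor(rep(c("a", "b"), c(8, 6)))
    ours <- mauchlyEpsilon(Y, grp)

    mod <- lm(Y ~ grp)
    idata <- data.frame(cond = factor(paste0("c", seq_len(cl))))
    s4 <- summary(car::Anova(mod, idata = idata, idesign = ~cond, type = 3),
                  multivariate = FALSE)
    expect_equal(ours$mauchly_w,
                 unname(s4$sphericity.tests["cond", "Test statistic"]),
                 tolerance = 1e-6)
    expect_equal(ours$mauchly_p,
                 unname(s4$sphericity.tests["cond", "p-value"]),
                 tolerance = 1e-6)
    expect_equal(ours$epsilon_gg,
                 unname(s4$pval.adjustments["cond", "GG eps"]),
                 tolerance = 1e-6)
    expect_equal(min(ours$epsilon_hf, 1),
                 min(unname(s4$pval.adjustments["cond", "HF eps"]), 1),
                 tolerance = 1e-6)
    expect_gte(ours$epsilon_hf, ours$epsilon_gg)
  }
})

test_that("epsilon hits its lower bound for rank-one covariance and 1 under compound symmetry", {
  # rank-1 within-subject structure: epsilon_gg = 1/(levels-1)
  set.seed(12)
  pattern <- c(2, -1, 0.5, -0.5, -1)
  Y <- outer(rnorm(12), pattern)
  expect_warning(sph <- mauchlyEpsilon(Y, factor(rep("g", 12))), "singular")
  expect_equal(sph$epsilon_gg, 0.25)

  # compound symmetry: epsilon -> 1 with many subjects
  set.seed(13)
  Ycs <- matrix(rnorm(400 * 4), 400, 4) + rnorm(400)
  sph2 <- mauchlyEpsilon(Ycs, factor(rep("g", 400)))
  expect_gt(sph2$epsilon_gg, 0.95)
})

test_that("the correction rule picks GG below 0.75, HF above, none when Mauchly holds", {
  base <- data.frame(effect = "condition", ss = 1, df1 = 4, df2 = 156,
                     F = 3.0, mauchly_p = 0.01, epsilon_gg = 0.6,
                     epsilon_hf = 0.68)
  gg <- applyCorrection(base)
  expect_equal(gg$correction, "GG")
  expect_equal(gg$df1_corr, 4 * 0.6)
  expect_equal(gg$p, pf(3.0, 2.4, 93.6, lower.tail = FALSE))

  base$epsilon_gg <- 0.9; base$epsilon_hf <- 0.95
  hf <- applyCorrection(base)
  expect_equal(hf$correction, "HF")
  expect_equal(hf$df2_corr, 156 * 0.95)

  base$mauchly_p <- 0.5
  none <- applyCorrection(base)
  expect_equal(none$correction, "none")
  expect_equal(none$df1_corr, 4)
  always <- applyCorrection(base, mode = "always")
  expect_equal(always$correction, "HF")
})

test_that("effect size and observed power reproduce the standard conventions", {
  expect_equal(partialEtaSq(8.74, 1, 39), 0.1830, tolerance = 1e-3)
  expect_equal(round(partialEtaSq(8.74, 1, 39), 2), 0.18)
  expect_equal(partialEtaSq(0, 4, 100), 0)
  expect_gt(partialEtaSq(1e9, 1, 39), 0.9999)

  expect_equal(round(observedPower(8.74, 1, 39), 2), 0.82)
  expect_equal(observedPower(0, 1, 39), 0.05, tolerance = 1e-10)
  # F exactly at the critical value -> power ~ 0.5 for large df2
  crit <- qf(0.95, 1, 5000)
  expect_equal(observedPower(crit, 1, 5000), 0.5, tolerance = 0.05)
})

test_that("Sidak post-hocs use the full pairwise family and percent changes", {
  set.seed(41)
  a <- 2 * c(0, 0.9, 1, 0.9, 0)
  tab <- makeMeasureTable(n_per_group = c(10L, 10L), n_cond = 5L,
                          cond_effects = a, subj_sd = 1, noise_sd = 1,
                          group_effects = c(5, 5))  # keep means positive
  ph <- sidakPosthoc(tab, "y", 1)
  expect_equal(nrow(ph), 10)
  expect_equal(attr(ph, "family_size"), 10)
  expect_equal(ph$p_sidak, 1 - (1 - ph$p_raw)^10, tolerance = 1e-12)
  expect_true(all(ph$p_sidak >= ph$p_raw))

  # extreme-vs-peak contrast significant, adjacent peak contrasts not
  pick <- function(a, b) ph[(ph$condition_a == a & ph$condition_b == b) |
                            (ph$condition_a == b & ph$condition_b == a), ]
  expect_lt(pick("ST", "DT2")$p_sidak, 0.05)
  expect_lt(pick("DT2", "DT4")$p_sidak, 0.05)
  expect_gt(pick("DT1", "DT2")$p_sidak, 0.05)

  # identical conditions -> all null
  tab0 <- tab
  wide <- tab0$y[tab0$condition == "ST"]
  for (cc in unique(tab0$condition)) tab0$y[tab0$condition == cc] <- wide
  ph0 <- sidakPosthoc(tab0, "y", 1)
  expect_true(all(ph0$p_sidak == 1))

  # percent change signs follow the condition means
  expect_equal(sign(pick("ST", "DT2")$percent_change), 1)
})

test_that("assumption checks report per-cell normality and Levene tests", {
  set.seed(61)
  tab <- makeMeasureTable(n_per_group = c(12L, 12L), n_cond = 3L)
  rep <- assumptionChecks(tab, "y", 1)
  expect_equal(nrow(rep$normality), 6)  # 2 groups x 3 conditions
  expect_true(all(rep$normality$n == 12))
  expect_true(all(rep$normality$ks_p > 0 & rep$normality$ks_p <= 1))
  expect_equal(nrow(rep$levene), 3)
  expect_true(all(rep$levene$p > 0 & rep$levene$p <= 1))

  # heavy-tailed data are rejected more often than Gaussian by Shapiro-Wilk
  sw_p <- function(gen) {
    mean(vapply(1:40, function(i) {
      set.seed(i)
      shp <- makeMeasureTable(n_per_group = c(12L, 12L), n_cond = 3L)
      shp$y <- gen(nrow(shp))
      min(assumptionChecks(shp, "y", 1)$normality$sw_p)
    }, numeric(1)) < 0.05)
  }
  expect_gt(sw_p(function(n) rt(n, df = 2)), sw_p(function(n) rnorm(n)))

  # tiny cells are skipped with NA
  small <- makeMeasureTable(n_per_group = c(2L, 2L), n_cond = 3L)
  rep2 <- assumptionChecks(small, "y", 1)
  expect_true(all(is.na(rep2$normality$ks_p)))
})

test_that("subjects with undefined cells are removed listwise with a log", {
  set.seed(81)
  tab <- makeMeasureTable(n_per_group = c(10L, 10L), n_cond = 5L)
  tab$y[tab$subject_id == "s003" & tab$condition == "DT2"] <- NA
  expect_message(res <- splitPlotAnova(tab, "y", 1), "listwise")
  expect_equal(res$n_subjects[1], 19)
  expect_equal(res$n_dropped[1], 1)
})
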