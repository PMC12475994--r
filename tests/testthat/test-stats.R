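test_that("summary t-test reproduces published group comparisons", {
  sbp <- ttest_from_summary(142.62, 18.57, 50, 131.78, 20.55, 65)
  expect_equal(sbp$df, 113)
  expect_equal(round(sbp$p, 3), 0.004)
  expect_gt(sbp$direction, 0)
  same <- ttest_from_summary(10, 2, 30, 10, 2, 30)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
})

test_that("summary tests agree with raw-data tests (two-path)", {
  set.seed(21)
  x <- rnorm(40, 5, 2)
  y <- rnorm(55, 5.8, 2.4)
  ours <- ttest_from_summary(mean(x), sd(x), 40, mean(y), sd(y), 55)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  ours_w <- ttest_from_summary(mean(x), sd(x), 40, mean(y), sd(y), 55,
                               variant = "welch")
  ref_w <- t.test(x, y)
  expect_equal(ours_w$p, ref_w$p.value, tolerance = 1e-10)

  g <- gl(3, 30)
  v <- rnorm(90) + as.numeric(g) * 0.3
  ms <- tapply(v, g, mean)
  ss <- tapply(v, g, sd)
  ours_f <- anova_from_summary(ms, ss, rep(30, 3))
  ref_f <- anova(lm(v ~ g))
  expect_equal(ours_f$statistic, ref_f$`F value`[1], tolerance = 1e-10)
  expect_equal(ours_f$p, ref_f$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("ANOVA from summaries reproduces the published age comparison", {
  age <- anova_from_summary(c(52.82, 53.88, 51.36), c(8.00, 8.80, 11.05),
                            c(50, 65, 70))
  expect_equal(round(age$p, 3), 0.306)
  expect_equal(age$df, c(2, 182))
  eq <- anova_from_summary(c(5, 5, 5), c(1, 1, 1), c(10, 10, 10))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)
})

test_that("LSD post hoc matches a hand-computed contrast", {
  means <- c(A = 10, B = 12, C = 10)
  sds <- c(2, 2, 2)
  ns <- c(5, 5, 5)
  ph <- lsd_posthoc(means, sds, ns)
  # hand calculation: MSW = 4, se = sqrt(4 * (1/5 + 1/5)) = 1.2649, df = 12
  t_ab <- (10 - 12) / sqrt(4 * (2 / 5))
  expect_equal(ph$`A-B`$statistic, t_ab, tolerance = 1e-12)
  expect_equal(ph$`A-B`$df, 12)
  expect_equal(ph$`A-B`$p, 2 * pt(-abs(t_ab), 12), tolerance = 1e-12)
  expect_equal(ph$`A-C`$p, 1)
  # LSD p never exceeds the Bonferroni-adjusted p of the same contrast
  expect_lte(ph$`A-B`$p, min(1, ph$`A-B`$p * 3))
})

test_that("chi-square reproduces the published gender comparison", {
  tab <- rbind(male = c(31, 39, 48), female = c(19, 26, 22))
  res <- chi_square_test(tab)
  expect_equal(res$df, 2)
  expect_equal(round(res$p, 3), 0.558)
  ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  prop <- rbind(c(10, 20), c(5, 10))
  expect_equal(chi_square_test(prop)$statistic, 0)
  expect_error(chi_square_test(rbind(c(0, 0), c(1, 2))),
               class = "morphnet_stats_error")
})

make_cohort <- function(n = 90, seed = 31) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("s%02d", 1:n),
    group = factor(rep(c("HC", "DM", "DKD"), each = n / 3),
                   levels = c("HC", "DM", "DKD")),
    age = rnorm(n, 50, 8), gender = rbinom(n, 1, 0.6),
    education = rnorm(n, 10, 3), TIV = rnorm(n, 1450, 100))
}

test_that("ANCOVA reduces to one-way ANOVA when covariates are orthogonal", {
  co <- make_cohort()
  y <- rnorm(90) + (co$group == "DKD") * 0.8
  x <- model.matrix(~ group, data = co)
  # covariate orthogonalized against the group design and y
  z <- resid(lm(rnorm(90) ~ x + y))
  co$ortho <- z
  res <- ancova_group_test(y, co, covariates = "ortho")
  ref <- anova(lm(y ~ co$group))
  # group SS is untouched; the only difference is the residual df spent on
  # the (null) covariate, so the Fs agree exactly after df correction
  f_corrected <- ref$`F value`[1] * (90 - 4) / (90 - 3)
  expect_equal(res$statistic, f_corrected, tolerance = 1e-10)
  expect_equal(res$statistic, ref$`F value`[1], tolerance = 0.02)
})

test_that("ANCOVA group F is invariant to reference-level coding", {
  co <- make_cohort(seed = 32)
  y <- rnorm(90) + 0.3 * co$age / 10 + (co$group == "DM") * 0.5
  r1 <- ancova_group_test(y, co)
  co2 <- co
  co2$group <- relevel(co2$group, "DKD")
  r2 <- ancova_group_test(y, co2)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-10)
  expect_equal(r1$p, r2$p, tolerance = 1e-10)
})

test_that("adding an orthogonal covariate barely moves the group F", {
  co <- make_cohort(seed = 33)
  y <- rnorm(90) + (co$group == "DKD")
  base <- ancova_group_test(y, co, covariates = "age")
  x_full <- cbind(model.matrix(~ group + age, data = co), y)
  co$ortho <- resid(lm(rnorm(90) ~ x_full))
  both <- ancova_group_test(y, co, covariates = c("age", "ortho"))
  # exact after correcting for the residual df the null covariate consumes
  expect_lt(abs(base$statistic * (90 - 5) / (90 - 4) - both$statistic), 1e-8)
  expect_lt(abs(base$statistic - both$statistic) / base$statistic, 0.02)
})

test_that("collinear covariates are rejected with names", {
  co <- make_cohort(seed = 34)
  co$age2 <- co$age * 2
  expect_error(ancova_group_test(rnorm(90), co,
                                 covariates = c("age", "age2")),
               class = "morphnet_stats_error")
})

test_that("ANCOVA is alpha-calibrated and powered as expected", {
  set.seed(35)
  # null: y depends only on covariates
  reps <- 600
  pvals <- numeric(reps)
  co <- make_cohort(seed = 36)
  for (r in seq_len(reps)) {
    y <- 0.5 * co$age + 0.2 * co$TIV / 100 + rnorm(90)
    pvals[r] <- ancova_group_test(y, co)$p
  }
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
  # power: 1 SD shift at n=50/group with independent covariates
  co2 <- make_cohort(n = 150, seed = 37)
  hits <- 0
  for (r in 1:200) {
    y <- rnorm(150) + (co2$group == "DKD")
    hits <- hits + (ancova_group_test(y, co2)$p < 0.05)
  }
  expect_gt(hits / 200, 0.9)
})

test_that("Bonferroni adjustment is a capped, order-preserving inflation", {
  co <- make_cohort(seed = 38)
  y <- rnorm(90) + (co$group == "DKD") * 0.6
  res <- ancova_group_test(y, co)
  ph <- bonferroni_posthoc(res)
  expect_length(ph, 3)
  for (p in ph) {
    expect_equal(p$p_adjusted, min(1, p$p * 3), tolerance = 1e-12)
    expect_gte(p$p_adjusted, p$p)
    expect_lte(p$p_adjusted, 1)
  }
  raw <- vapply(ph, function(p) p$p, numeric(1))
  adj <- vapply(ph, function(p) p$p_adjusted, numeric(1))
  expect_identical(order(raw), order(adj))
})

test_that("partial correlation behaves at its boundary cases", {
  set.seed(39)
  x <- rnorm(60)
  exact <- adjusted_correlation(x, x)
  expect_equal(exact$estimate, 1)
  co <- data.frame(z = rnorm(200))
  x2 <- co$z + rnorm(200, sd = 0.6)
  y2 <- co$z + rnorm(200, sd = 0.6)
  res <- adjusted_correlation(x2, y2, co, "z")
  expect_lt(abs(res$estimate), 3 / sqrt(200))
  expect_equal(res$df, 200 - 2 - 1)
  # matches the textbook partial-correlation formula
  rxy <- cor(x2, y2); rxz <- cor(x2, co$z); ryz <- cor(y2, co$z)
  formula_r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(res$estimate, formula_r, tolerance = 1e-10)
})

test_that("nodal screen recovers affected nodes and gates post hocs", {
  set.seed(40)
  co <- make_cohort(n = 90, seed = 41)
  n_nodes <- 20
  auc <- matrix(rnorm(90 * n_nodes), 90, n_nodes,
                dimnames = list(NULL, paste0("node", 1:n_nodes)))
  affected <- c(3, 11)
  shift <- (co$group == "DM") * 1 + (co$group == "DKD") * 2
  auc[, affected] <- auc[, affected] - shift
  scr <- nodal_group_screen(auc, co, metric = "degree")
  expect_identical(nrow(scr), 20L)
  top <- order(-scr$F)[1:2]
  expect_setequal(top, affected)
  expect_true(all(scr$p[affected] < 0.05))
  # HC > DM > DKD direction on affected nodes
  expect_true(all(scr$dir_HC_vs_DM[affected] > 0))
  expect_true(all(scr$dir_DM_vs_DKD[affected] > 0))
  # post hoc p gated on overall significance
  ns <- which(scr$p > 0.4)
  if (length(ns)) expect_true(all(is.na(scr$p_bonf_HC_vs_DKD[ns])))
})
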