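#' Two-sample t-test from group summaries
#'
#' Reconstructs the independent two-sample t-test from published means, SDs
#' and group sizes. The default pooled-variance form matches the convention
#' of clinical tables; a Welch variant is available.
#'
#' @param m1,sd1,n1,m2,sd2,n2 group summaries.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return a `stat_result` list: statistic, df, p, effect direction.
#' @export
ttest_from_summary <- function(m1, sd1, n1, m2, sd2, n2,
                               variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2 || sd1 <= 0 || sd2 <= 0) {
    stop_morphnet("need n >= 2 and sd > 0 in both groups",
                  class = "morphnet_stats_error")
  }
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  stat_result(statistic = t, df = df, p = 2 * pt(-abs(t), df),
              direction = sign(m1 - m2), test = paste0("t_", variant))
}

#' One-way ANOVA from group summaries
#'
#' @param means,sds,ns equal-length numeric vectors of group summaries.
#' @return a `stat_result` with the F statistic and `(k-1, N-k)` df.
#' @export
anova_from_summary <- function(means, sds, ns) {
  k <- length(means)
  if (k < 2 || any(ns < 2)) {
    stop_morphnet("need >= 2 groups with n >= 2 each",
                  class = "morphnet_stats_error")
  }
  n_tot <- sum(ns)
  gm <- sum(ns * means) / n_tot
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((ns - 1) * sds^2)
  if (ssw <= 0) {
    stop_morphnet("degenerate within-group variance",
                  class = "morphnet_stats_error")
  }
  f <- (ssb / (k - 1)) / (ssw / (n_tot - k))
  stat_result(statistic = f, df = c(k - 1, n_tot - k),
              p = pf(f, k - 1, n_tot - k, lower.tail = FALSE),
              test = "anova", msw = ssw / (n_tot - k))
}

#' LSD post hoc contrasts from group summaries
#'
#' Fisher's least-significant-difference pairwise t-tests using the ANOVA
#' mean-square-within as common variance, `N - k` df, unadjusted p-values.
#'
#' @inheritParams anova_from_summary
#' @return list of pairwise `stat_result`s named `"i-j"`.
#' @export
lsd_posthoc <- function(means, sds, ns) {
  a <- anova_from_summary(means, sds, ns)
  k <- length(means)
  df <- sum(ns) - k
  labs <- names(means) %||% as.character(seq_len(k))
  out <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt(a$msw * (1 / ns[i] + 1 / ns[j]))
      t <- (means[i] - means[j]) / se
      out[[paste0(labs[i], "-", labs[j])]] <-
        stat_result(statistic = t, df = df, p = 2 * pt(-abs(t), df),
                    direction = sign(means[i] - means[j]), test = "lsd")
    }
  }
  out
}

#' Pearson chi-square test on a contingency table
#'
#' No continuity correction (the convention for r x c tables larger than
#' 2 x 2, and the form clinical tables report).
#'
#' @param table matrix of counts.
#' @return a `stat_result` with `(r-1)(c-1)` df.
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop_morphnet("zero marginal in contingency table",
                  class = "morphnet_stats_error")
  }
  expd <- outer(rowSums(table), colSums(table)) / sum(table)
  stat <- sum((table - expd)^2 / expd)
  df <- (nrow(table) - 1) * (ncol(table) - 1)
  stat_result(statistic = stat, df = df,
              p = pchisq(stat, df, lower.tail = FALSE), test = "chisq")
}

stat_result <- function(statistic, df, p, direction = NA_real_,
                        test = "test", ...) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p = unname(p), direction = unname(direction), test = test,
                 ...),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: stat = %.4g, df = %s, p = %.4g\n",
              x$test, x$statistic, paste(signif(x$df, 6), collapse = ", "),
              x$p))
  invisible(x)
}

group_design <- function(y, cohort, covariates) {
  if (!is.factor(cohort$group)) {
    cohort$group <- factor(cohort$group, levels = c("HC", "DM", "DKD"))
  }
  cohort$group <- droplevels(cohort$group)
  dat <- cohort[, c("group", covariates), drop = FALSE]
  dat$.y <- y
  if (!all(complete.cases(dat))) {
    stop_morphnet("missing values in response or covariates",
                  class = "morphnet_stats_error")
  }
  dat
}

#' Covariate-adjusted group comparison (one-way ANCOVA)
#'
#' Fits `y ~ group + covariates` by least squares (group dummy-coded with the
#' first level as reference) and tests the group effect with the
#' extra-sum-of-squares F against the covariates-only model.
#'
#' @param y per-subject metric values, aligned with `cohort` rows.
#' @param cohort data frame with a `group` column (levels HC, DM, DKD by
#'   convention) and covariate columns.
#' @param covariates character vector of covariate column names (default
#'   `c("age", "gender", "education", "TIV")`).
#' @return a `stat_result` with fields `fit` (the full `lm`) and
#'   `adjusted_means` usable by [bonferroni_posthoc()].
#' @export
ancova_group_test <- function(y, cohort,
                              covariates = c("age", "gender", "education",
                                             "TIV")) {
  dat <- group_design(y, cohort, covariates)
  full <- lm(.y ~ ., data = dat)
  if (any(is.na(coef(full)))) {
    bad <- names(coef(full))[is.na(coef(full))]
    stop_morphnet("rank-deficient design; collinear terms: %s",
                  paste(bad, collapse = ", "),
                  class = "morphnet_stats_error")
  }
  reduced <- lm(.y ~ . - group, data = dat)
  an <- anova(reduced, full)
  f <- an$F[2]
  df1 <- an$Df[2]
  df2 <- full$df.residual
  stat_result(statistic = f, df = c(df1, df2),
              p = pf(f, df1, df2, lower.tail = FALSE), test = "ancova",
              fit = full, groups = levels(dat$group))
}

#' Bonferroni-adjusted pairwise group contrasts from an ANCOVA fit
#'
#' Pairwise covariate-adjusted mean differences with t statistics from the
#' full-model coefficient covariance; adjusted p = `min(1, raw * m)`.
#'
#' @param ancova a result of [ancova_group_test()].
#' @param m number of comparisons for the correction (default: all pairs).
#' @return list of pairwise `stat_result`s with `p_adjusted` fields; the
#'   direction is the sign of (first group - second group) adjusted means.
#' @export
bonferroni_posthoc <- function(ancova, m = NULL) {
  fit <- ancova$fit
  groups <- ancova$groups
  k <- length(groups)
  pairs <- utils::combn(k, 2)
  m <- m %||% ncol(pairs)
  beta <- coef(fit)
  v <- vcov(fit)
  # dummy coefficients: group<level> for non-reference levels
  coef_of <- function(g) {
    nm <- paste0("group", g)
    if (g == groups[1]) NULL else nm
  }
  out <- list()
  for (p in seq_len(ncol(pairs))) {
    g1 <- groups[pairs[1, p]]
    g2 <- groups[pairs[2, p]]
    cvec <- setNames(rep(0, length(beta)), names(beta))
    if (!is.null(coef_of(g1))) cvec[coef_of(g1)] <- 1
    if (!is.null(coef_of(g2))) cvec[coef_of(g2)] <- -1
    est <- sum(cvec * beta)
    se <- sqrt(drop(t(cvec) %*% v %*% cvec))
    t <- est / se
    df <- fit$df.residual
    raw <- 2 * pt(-abs(t), df)
    r <- stat_result(statistic = t, df = df, p = raw,
                     direction = sign(est), test = "bonferroni_contrast")
    r$p_adjusted <- min(1, raw * m)
    r$estimate <- est
    out[[paste0(g1, "-", g2)]] <- r
  }
  out
}

#' Covariate-adjusted (partial) Pearson correlation
#'
#' Residualizes `x` and `y` on the covariates (with intercept) and
#' correlates the residuals; `df = n - 2 - k` where `k` is the number of
#' covariate columns in the design. The p-value is two-sided and
#' uncorrected.
#'
#' @param x,y numeric vectors aligned with `cohort` rows.
#' @param cohort data frame holding the covariates (can be missing/NULL when
#'   `covariates` is empty for a plain Pearson correlation).
#' @param covariates character vector of covariate column names.
#' @return a `stat_result` with the partial `r` as `estimate`.
#' @export
adjusted_correlation <- function(x, y, cohort = NULL,
                                 covariates = character()) {
  n <- length(x)
  k <- 0L
  if (length(covariates)) {
    z <- model.matrix(~., data = cohort[, covariates, drop = FALSE])
    k <- ncol(z) - 1L
    if (qr(z)$rank < ncol(z)) {
      stop_morphnet("rank-deficient covariate matrix",
                    class = "morphnet_stats_error")
    }
    x <- resid(lm.fit(z, x))
    y <- resid(lm.fit(z, y))
  }
  if (n <= k + 3) {
    stop_morphnet("need n > covariates + 3 observations",
                  class = "morphnet_stats_error")
  }
  r <- cor(x, y)
  df <- n - 2L - k
  t <- r * sqrt(df / (1 - r^2))
  res <- stat_result(statistic = t, df = df, p = 2 * pt(-abs(t), df),
                     direction = sign(r), test = "partial_pearson")
  res$estimate <- r
  res
}

#' Per-node covariate-adjusted group screen
#'
#' Runs [ancova_group_test()] on each column of a subjects x nodes AUC table,
#' gating pairwise Bonferroni post hoc contrasts on overall significance.
#' Per-node failures are recorded, not fatal.
#'
#' @param nodal_auc numeric matrix, subjects in rows, nodes in columns.
#' @param cohort cohort data frame aligned with the rows.
#' @param covariates nuisance covariates for the ANCOVA.
#' @param alpha overall-test gate for post hoc contrasts (default 0.05).
#' @param metric label stored in the output.
#' @return data frame with one row per node: F, df, p, and for each group
#'   pair the raw p, Bonferroni p, and direction (sign of adjusted
#'   difference); nodes whose model failed carry `NA` and the error message.
#' @export
nodal_group_screen <- function(nodal_auc, cohort,
                               covariates = c("age", "gender", "education",
                                              "TIV"),
                               alpha = 0.05, metric = "metric") {
  nodes <- colnames(nodal_auc) %||% paste0("n", seq_len(ncol(nodal_auc)))
  lev <- levels(factor(cohort$group,
                       levels = intersect(c("HC", "DM", "DKD"),
                                          unique(cohort$group))))
  pair_keys <- apply(utils::combn(lev, 2), 2, paste, collapse = "_vs_")
  rows <- lapply(seq_len(ncol(nodal_auc)), function(j) {
    base <- data.frame(metric = metric, node = nodes[j], F = NA_real_,
                       df1 = NA_real_, df2 = NA_real_, p = NA_real_,
                       error = NA_character_, stringsAsFactors = FALSE)
    for (key in pair_keys) {
      base[[paste0("p_raw_", key)]] <- NA_real_
      base[[paste0("p_bonf_", key)]] <- NA_real_
      base[[paste0("dir_", key)]] <- NA_real_
    }
    res <- tryCatch(ancova_group_test(nodal_auc[, j], cohort, covariates),
                    error = function(e) e)
    if (inherits(res, "error")) {
      base$error <- conditionMessage(res)
      return(base)
    }
    base$F <- res$statistic
    base$df1 <- res$df[1]
    base$df2 <- res$df[2]
    base$p <- res$p
    ph <- bonferroni_posthoc(res)
    for (nm in names(ph)) {
      key <- gsub("-", "_vs_", nm)
      base[[paste0("p_raw_", key)]] <- ph[[nm]]$p
      base[[paste0("p_bonf_", key)]] <-
        if (isTRUE(res$p < alpha)) ph[[nm]]$p_adjusted else NA_real_
      base[[paste0("dir_", key)]] <- ph[[nm]]$direction
    }
    base
  })
  do.call(rbind, rows)
}
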