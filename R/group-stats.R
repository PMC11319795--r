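#' Two-group summary statistics
#'
#' Container for the "mean +/- SD" pairs of a printed group-comparison table,
#' sufficient to reproduce pooled-variance t statistics and effect sizes.
#'
#' @param n1,mean1,sd1 first group (e.g. young).
#' @param n2,mean2,sd2 second group (e.g. old).
#' @param variable variable name.
#' @return A `summary_stats` object.
#' @export
summary_stats <- function(n1, mean1, sd1, n2, mean2, sd2,
                          variable = "variable") {
  if (n1 < 2 || n2 < 2) stopf("summary_stats: group sizes must be >= 2")
  if (sd1 < 0 || sd2 < 0) stopf("summary_stats: SDs must be >= 0")
  structure(list(n1 = n1, mean1 = mean1, sd1 = sd1,
                 n2 = n2, mean2 = mean2, sd2 = sd2, variable = variable),
            class = "summary_stats")
}

#' Student t-test from group summaries
#'
#' Pooled-variance (Student) two-sample t-test computed from group means and
#' SDs alone, with Cohen's d standardized by the pooled SD (reported as an
#' absolute value). This is the form implied by printed degrees of freedom
#' `n1 + n2 - 2`.
#'
#' @param s a [summary_stats()].
#' @return List of class `ttest_result`: `t`, `df`, `p` (two-sided),
#'   `cohens_d`, `method`.
#' @export
ttest_from_summary <- function(s) {
  stopifnot(inherits(s, "summary_stats"))
  df <- s$n1 + s$n2 - 2
  sp2 <- ((s$n1 - 1) * s$sd1^2 + (s$n2 - 1) * s$sd2^2) / df
  diff <- s$mean1 - s$mean2
  if (sp2 == 0) {
    if (diff == 0) {
      t <- 0; d <- 0
    } else {
      warning("ttest_from_summary: zero pooled SD with unequal means; t overflows",
              call. = FALSE)
      t <- sign(diff) * Inf; d <- Inf
    }
  } else {
    sp <- sqrt(sp2)
    t <- diff / (sp * sqrt(1 / s$n1 + 1 / s$n2))
    d <- abs(diff) / sp
  }
  p <- if (is.infinite(t)) 0 else 2 * pt(-abs(t), df)
  structure(list(t = t, df = df, p = p, cohens_d = d, variable = s$variable,
                 method = "student_t.pooled"),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("%s: t(%g) = %.3f, p = %.4g, Cohen's d = %.2f [%s]\n",
              x$variable, x$df, x$t, x$p, x$cohens_d, x$method))
  invisible(x)
}

#' Student t-test from raw samples
#'
#' Identical, by construction, to [ttest_from_summary()] applied to the
#' samples' own summary statistics.
#'
#' @param x1,x2 numeric vectors (each n >= 2).
#' @param variable variable name.
#' @return A `ttest_result`.
#' @export
ttest_raw <- function(x1, x2, variable = "variable") {
  if (length(x1) < 2 || length(x2) < 2) {
    stopf("ttest_raw: need at least 2 observations per group")
  }
  ttest_from_summary(summary_stats(length(x1), mean(x1), sd(x1),
                                   length(x2), mean(x2), sd(x2),
                                   variable = variable))
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided p-value by summing, over the hypergeometric support, the
#' probabilities of all tables at most as probable as the observed one
#' (relative tolerance 1e-7, the usual convention).
#'
#' @param a,b,c,d cell counts, rows = group, cols = category.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stopf("fisher_exact_2x2: counts must be non-negative integers")
  }
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # col 1 total
  lo <- max(0, k - n); hi <- min(k, m)
  support <- lo:hi
  dens <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(dens[dens <= p_obs * (1 + 1e-7)])
}

#' Test-retest reliability: ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation from the mean squares of a subjects x replicates layout, with
#' the standard F-based 95% confidence interval. Benchmarks: <= 0.5 poor,
#' 0.5-0.75 moderate, 0.75-0.9 good, > 0.9 excellent. Absolute-agreement ICC
#' is invariant to a common shift of all measurements but not to rescaling of
#' individual replicates.
#'
#' @param values numeric matrix, subjects in rows, replicates in columns.
#' @param conf confidence level (default 0.95).
#' @return List of class `icc_result`: `icc`, `ci95`, `model`.
#' @export
icc_test_retest <- function(values, conf = 0.95) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (n < 2 || k < 2) {
    stopf("icc_test_retest: need >= 2 subjects and >= 2 replicates")
  }
  if (anyNA(values)) stopf("icc_test_retest: missing values not supported")
  gm <- mean(values)
  rowm <- rowMeans(values); colm <- colMeans(values)
  ss_rows <- k * sum((rowm - gm)^2)
  ss_cols <- n * sum((colm - gm)^2)
  ss_tot <- sum((values - gm)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  icc <- if (denom == 0) 1 else (msr - mse) / denom
  alpha <- 1 - conf
  if (mse == 0 && msc == 0) {
    ci <- c(1, 1)
  } else {
    # F-based interval for the absolute-agreement single-measure ICC
    r <- icc
    aa <- k * r / (n * (1 - r)); bb <- 1 + k * r * (n - 1) / (n * (1 - r))
    v <- (aa * msc + bb * mse)^2 /
      ((aa * msc)^2 / (k - 1) + (bb * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- qf(1 - alpha / 2, n - 1, v)
    f_u <- qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(lower, upper)
  }
  structure(list(icc = icc, ci95 = ci, model = "icc2_1",
                 ms = c(MSR = msr, MSC = msc, MSE = mse)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.3f, 95%% CI [%.3f, %.3f]\n",
              x$icc, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Two-way ANOVA of sway by condition and age group
#'
#' Fixed-effects condition x group ANOVA with interaction on the (typically
#' block-averaged) per-subject normalized sdCOP, classical eta-squared
#' (`SS_effect / SS_total`) per effect, and Bonferroni-corrected pairwise
#' Student t-tests between conditions as post-hocs.
#'
#' @param table data frame with columns `subject_id`, `group`, `condition`,
#'   and the response named in `response`.
#' @param response response column (default `sdCOP_AP_norm`).
#' @return List of class `anova_result`: `effects` (data frame of F, df, p,
#'   eta squared) and `posthoc` (pairwise condition comparisons).
#' @export
anova_condition_by_age <- function(table, response = "sdCOP_AP_norm") {
  need <- c("group", "condition", response)
  if (!all(need %in% names(table))) {
    stopf("anova_condition_by_age: table needs columns %s",
          paste(need, collapse = ", "))
  }
  tab <- data.frame(y = table[[response]],
                    condition = factor(table$condition),
                    group = factor(table$group))
  cells <- table(tab$condition, tab$group)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    stopf("anova_condition_by_age: empty cell %s x %s",
          rownames(cells)[empty[1]], colnames(cells)[empty[2]])
  }
  fit <- aov(y ~ condition * group, data = tab)
  at <- summary(fit)[[1]]
  ss <- at[["Sum Sq"]]
  ss_tot <- sum(ss)
  eff_names <- trimws(rownames(at))
  keep <- eff_names != "Residuals"
  degenerate <- ss_tot <= 1e-12 * max(1, mean(tab$y)^2) * length(tab$y)
  effects <- data.frame(
    effect = sub("condition:group", "interaction", eff_names[keep]),
    F = if (degenerate) 0 else at[["F value"]][keep],
    df_num = at[["Df"]][keep],
    df_den = at[["Df"]][!keep],
    p = if (degenerate) 1 else at[["Pr(>F)"]][keep],
    eta_squared = if (degenerate) 0 else ss[keep] / ss_tot,
    stringsAsFactors = FALSE
  )
  # post-hoc: pairwise Student t-tests between conditions, Bonferroni
  conds <- levels(tab$condition)
  prs <- combn(conds, 2)
  m <- ncol(prs)
  posthoc <- do.call(rbind, lapply(seq_len(m), function(i) {
    y1 <- tab$y[tab$condition == prs[1, i]]
    y2 <- tab$y[tab$condition == prs[2, i]]
    tt <- ttest_raw(y1, y2)
    data.frame(condition_a = prs[1, i], condition_b = prs[2, i],
               mean_diff = mean(y1) - mean(y2), t = tt$t, df = tt$df,
               p_raw = tt$p, p_bonferroni = min(1, m * tt$p),
               stringsAsFactors = FALSE)
  }))
  structure(list(effects = effects, posthoc = posthoc,
                 method = "two_way_anova.eta2_classical.bonferroni"),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  for (i in seq_len(nrow(x$effects))) {
    e <- x$effects[i, ]
    cat(sprintf("%s: F(%d, %d) = %.2f, p = %.4g, eta^2 = %.3f\n",
                e$effect, e$df_num, e$df_den, e$F, e$p, e$eta_squared))
  }
  invisible(x)
}

#' Qualitative label for a correlation magnitude
#'
#' Maps `|r|` to the conventional verbal scale: below 0.20 "very weak",
#' 0.20-0.39 "weak", 0.40-0.59 "moderate", 0.60-0.79 "strong", 0.80 and
#' above "very strong".
#'
#' @param r correlation in \[-1, 1\].
#' @return Character label.
#' @export
label_correlation_strength <- function(r) {
  a <- abs(r)
  if (a > 1) stopf("label_correlation_strength: |r| must be <= 1")
  cut_labels <- c("very weak", "weak", "moderate", "strong", "very strong")
  cut_labels[findInterval(a, c(0, 0.2, 0.4, 0.6, 0.8))]
}
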