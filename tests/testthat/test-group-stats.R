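test_that("pooled t-test reproduces published worked examples", {
  height <- ttest_from_summary(summary_stats(32, 173.0, 10.0, 34, 166.4, 9.4))
  expect_equal(height$t, 2.75, tolerance = 0.01)
  expect_equal(height$df, 64)

  vl_mt <- ttest_from_summary(summary_stats(32, 2.21, 0.48, 34, 1.38, 0.33))
  expect_equal(vl_mt$t, 8.22, tolerance = 0.01)
  expect_equal(vl_mt$cohens_d, 2.0, tolerance = 0.05)

  vl_ei <- ttest_from_summary(summary_stats(32, 32.3, 7.1, 34, 56.0, 9.2))
  expect_equal(vl_ei$t, -11.6, tolerance = 0.1)
  expect_equal(vl_ei$cohens_d, 2.9, tolerance = 0.05)
})

test_that("raw-sample and summary-statistic t-test paths agree exactly", {
  set.seed(21)
  for (i in 1:10) {
    x1 <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    x2 <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    a <- ttest_raw(x1, x2)
    b <- ttest_from_summary(summary_stats(length(x1), mean(x1), sd(x1),
                                          length(x2), mean(x2), sd(x2)))
    expect_equal(a$t, b$t, tolerance = 1e-12)
    expect_equal(a$p, b$p, tolerance = 1e-12)
    # and both agree with the pooled-variance reference implementation
    ref <- t.test(x1, x2, var.equal = TRUE)
    expect_equal(a$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(a$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("t-test degenerate and monotonicity behaviour", {
  eq <- ttest_raw(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$t, 0); expect_equal(eq$p, 1); expect_equal(eq$cohens_d, 0)
  expect_error(ttest_raw(1, c(1, 2)), "at least 2")
  expect_warning(
    z <- ttest_from_summary(summary_stats(5, 1, 0, 5, 2, 0)), "overflows")
  expect_true(is.infinite(z$t))
  # shifting one group moves t monotonically
  set.seed(3)
  x1 <- rnorm(20); x2 <- rnorm(20)
  ts <- vapply(c(0, 0.5, 1, 2), function(c) ttest_raw(x1 + c, x2)$t,
               numeric(1))
  expect_true(all(diff(ts) > 0))
})

test_that("Fisher exact enumeration matches the reference and closed forms", {
  # the sex-ratio table: enumeration agrees with the base implementation
  p <- fisher_exact_2x2(15, 17, 18, 16)
  expect_equal(p, fisher.test(matrix(c(15, 18, 17, 16), 2))$p.value,
               tolerance = 1e-12)
  expect_equal(p, 0.81, tolerance = 0.01)
  # symmetric table
  expect_equal(fisher_exact_2x2(10, 10, 10, 10), 1)
  # extreme separation: two tail tables of the hypergeometric
  expect_equal(fisher_exact_2x2(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("ICC(2,1) identities and variance-ratio recovery", {
  # identical replicate columns
  m <- matrix(rnorm(30), 30, 1)[, c(1, 1, 1)]
  r <- icc_test_retest(m)
  expect_equal(r$icc, 1)

  # pure-noise replicates at large n: near zero
  set.seed(8)
  noise <- matrix(rnorm(200 * 3), 200, 3)
  expect_lt(abs(icc_test_retest(noise)$icc), 0.1)

  # between-subject SD 3x within-subject SD: icc -> 9/10
  set.seed(9)
  subj <- rnorm(600, sd = 3)
  mm <- sapply(1:3, function(k) subj + rnorm(600, sd = 1))
  r2 <- icc_test_retest(mm)
  expect_equal(r2$icc, 0.9, tolerance = 0.03)
  expect_true(r2$ci95[1] <= r2$icc && r2$icc <= r2$ci95[2])

  # shift invariance (absolute agreement is shift-invariant only)
  expect_equal(icc_test_retest(mm + 100)$icc, r2$icc, tolerance = 1e-12)
  expect_error(icc_test_retest(matrix(1, 1, 3)), ">= 2 subjects")
})

test_that("condition-by-age ANOVA decomposes sums of squares and flags cells", {
  co <- generate_cohort(cohort_spec(seed = 17))
  long <- cohort_sway_long(co)
  res <- anova_condition_by_age(long)
  expect_setequal(res$effects$effect, c("condition", "group", "interaction"))
  expect_true(all(res$effects$eta_squared >= 0))
  expect_lte(sum(res$effects$eta_squared), 1)
  # balanced-design decomposition: eta^2 sums to 1 - SS_err/SS_tot
  fit <- aov(sdCOP_AP_norm ~ condition * group,
             data = transform(long, condition = factor(condition),
                              group = factor(group)))
  ss <- summary(fit)[[1]][["Sum Sq"]]
  expect_equal(sum(res$effects$eta_squared), sum(ss[1:3]) / sum(ss),
               tolerance = 1e-9)

  # ECfoam is planted highest: significant against every other condition
  ph <- res$posthoc
  ec <- ph[ph$condition_a == "ECfoam" | ph$condition_b == "ECfoam", ]
  expect_true(all(ec$p_bonferroni < 0.05))
  expect_true(all(ph$p_bonferroni >= ph$p_raw - 1e-15))

  # all-equal response: no effect has any sum of squares to explain
  flat <- long; flat$sdCOP_AP_norm <- 1
  res0 <- anova_condition_by_age(flat)
  expect_true(all(!is.finite(res0$effects$F) | res0$effects$F == 0))

  # empty cell is named
  broken <- long[!(long$group == "old" & long$condition == "ECfoam"), ]
  expect_error(anova_condition_by_age(broken), "ECfoam")
})

test_that("group-shifted data keep the condition effect at its null level", {
  # no condition effect planted: condition-term type-I error near 5%
  n_sim <- 300
  set.seed(5)
  rej <- 0
  for (i in seq_len(n_sim)) {
    d <- data.frame(
      subject_id = rep(sprintf("s%02d", 1:20), each = 4),
      group = rep(c("young", "old"), each = 40),
      condition = rep(c("EOhard", "EChard", "EOfoam", "ECfoam"), 20),
      sdCOP_AP_norm = rnorm(80) + rep(c(0, 1), each = 40)  # group shift only
    )
    res <- anova_condition_by_age(d)
    rej <- rej + (res$effects$p[res$effects$effect == "condition"] < 0.05)
  }
  expect_gt(rej / n_sim, 0.02)
  expect_lt(rej / n_sim, 0.09)
})

test_that("correlation strength labels use the published boundaries", {
  expect_equal(label_correlation_strength(0.53), "moderate")
  expect_equal(label_correlation_strength(0.0), "very weak")
  expect_equal(label_correlation_strength(-0.25), "weak")
  expect_equal(label_correlation_strength(0.80), "very strong")
  expect_equal(label_correlation_strength(0.6), "strong")
  expect_equal(label_correlation_strength(1), "very strong")
  expect_error(label_correlation_strength(1.2), "<= 1")
})
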