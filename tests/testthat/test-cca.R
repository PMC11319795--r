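test_that("preprocessing standardizes, clamps, and removes the age trend", {
  set.seed(41)
  n <- 60
  ages <- runif(n, 20, 30)
  X <- cbind(a = rnorm(n), b = 2 * ages + rnorm(n, sd = 0.5))
  out <- preprocess_block(X, ages)
  expect_equal(colMeans(out), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(apply(out, 2, sd), c(a = 1, b = 1), tolerance = 1e-12)
  # age-driven column is orthogonal to age after residualization
  expect_lt(abs(cor(out[, "b"], ages)), 1e-10)

  # a column with no outliers and no age trend is just its z-score
  # (uniform draws keep every z-score well inside the 2.5 SD clamp)
  v <- runif(n, -2, 2)
  out2 <- preprocess_block(cbind(a = v), age_covariate = FALSE)
  expect_equal(out2[, "a"], (v - mean(v)) / sd(v), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("winsorization clamps outliers at the stated bound", {
  set.seed(42)
  v <- rnorm(100)
  v[1] <- mean(v[-1]) + 10 * sd(v[-1])      # extreme outlier
  out <- preprocess_block(cbind(x = v), age_covariate = FALSE)
  # before re-standardization the outlier sits exactly at +2.5 SD; after,
  # it is still the maximum and far below its raw z-score
  z_raw <- (v - mean(v)) / sd(v)
  expect_gt(max(z_raw), 2.5)
  expect_equal(which.max(out[, "x"]), 1L)
  clamped <- pmin(2.5, pmax(-2.5, z_raw))
  expect_equal(out[, "x"], (clamped - mean(clamped)) / sd(clamped),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(preprocess_block(cbind(k = rep(1, 10)), age_covariate = FALSE),
               "zero variance")
})

test_that("ridge CCA reduces to classical CCA and to the SVD limit", {
  set.seed(43)
  X <- matrix(rnorm(300), 60, 5); colnames(X) <- letters[1:5]
  Y <- matrix(rnorm(240), 60, 4)
  # identity blocks: perfect correlation
  expect_equal(fit_rcca(X, X)$r, 1, tolerance = 1e-10)
  # lambda = 0 equals the whitening-SVD reference (stats::cancor)
  f <- fit_rcca(X, Y, 0, 0)
  expect_equal(f$r, cancor(scale(X), scale(Y))$cor[1], tolerance = 1e-8)
  # heavy ridge: weights align with the leading singular vectors of Sxy
  fr <- fit_rcca(X, Y, 1e6, 1e6)
  sv <- svd(cov(X, Y))
  expect_gt(abs(sum(fr$wx * sv$u[, 1])), 0.999)
  expect_gt(abs(sum(fr$wy * sv$v[, 1])), 0.999)
  # canonical r is scale-invariant after standardization
  Xs <- sweep(X, 2, c(1, 10, 100, 0.1, 5), `*`)
  expect_equal(fit_rcca(scale(Xs), scale(Y), 0.1, 0.1)$r,
               fit_rcca(scale(X), scale(Y), 0.1, 0.1)$r, tolerance = 1e-10)
})

test_that("a planted shared factor is recovered at large n", {
  set.seed(44)
  n <- 1000
  z1 <- rnorm(n); z2 <- 0.5 * z1 + sqrt(0.75) * rnorm(n)
  X <- z1 %o% rep(1, 5) + matrix(rnorm(n * 5), n) * 1e-3
  Y <- z2 %o% rep(1, 4) + matrix(rnorm(n * 4), n) * 1e-3
  f <- fit_rcca(scale(X), scale(Y), 0.01, 0.01)
  expect_lt(abs(f$r - 0.5), 0.05)
})

test_that("leave-one-out selection returns grid members and behaves at edges", {
  set.seed(45)
  X <- matrix(rnorm(30 * 5), 30); Y <- matrix(rnorm(30 * 4), 30)
  one <- select_lambda_loo(scale(X), scale(Y), grid = 1)
  expect_equal(one$lambda_x, 1); expect_equal(one$lambda_y, 1)
  expect_error(select_lambda_loo(X, Y, grid = numeric(0)), "empty grid")

  # strongly coupled blocks: held-out correlation close to the in-sample r
  b <- cohort_blocks(seed = 46, group = "young", rho_young = 0.8)
  lam <- select_lambda_loo(b$X, b$Y, grid = 10^seq(-2, 2, length.out = 5))
  fit <- fit_rcca(b$X, b$Y, lam$lambda_x, lam$lambda_y)
  expect_gt(lam$loo_r, 0.3)
  expect_lt(abs(lam$loo_r - fit$r), 0.35)
})

test_that("permutation p-values are reproducible, bounded, and monotone", {
  b <- cohort_blocks(seed = 47, group = "young", rho_young = 0.6)
  p1 <- permutation_test(b$X, b$Y, 1, 1, n_perm = 99, seed = 7)
  p2 <- permutation_test(b$X, b$Y, 1, 1, n_perm = 99, seed = 7)
  expect_identical(p1$r_perm, p2$r_perm)
  expect_gte(p1$perm_p, 1 / 100)
  expect_lte(p1$perm_p, 1)
  # r_obs below every permuted value gives the boundary p = 1
  fake_perm <- (1 + sum(p1$r_perm >= 0)) / (99 + 1)
  expect_equal(fake_perm, 1)
  # given a fixed permutation set, p is nonincreasing in r_obs
  ps <- vapply(c(0.1, 0.5, 0.9), function(r0) {
    (1 + sum(p1$r_perm >= r0)) / 100
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_error(permutation_test(b$X, b$Y, 1, 1, n_perm = 0), "n_perm")
})

test_that("pooling is sign-corrected and reduces to Pearson for one column", {
  set.seed(48)
  x <- rnorm(40); Y <- matrix(rnorm(160), 40, 4)
  pa <- pool_and_correlate(cbind(x), Y, wx = 1)
  expect_equal(pa$pooled_us, x)
  expect_equal(pa$pearson_r, cor(x, rowMeans(Y)), tolerance = 1e-12)
  # flipping a column together with its weight sign changes nothing
  X2 <- cbind(a = x, b = rnorm(40))
  p1 <- pool_and_correlate(X2, Y, wx = c(1, -0.5))
  X2f <- X2; X2f[, "b"] <- -X2f[, "b"]
  p2 <- pool_and_correlate(X2f, Y, wx = c(1, 0.5))
  expect_equal(p1$pooled_us, p2$pooled_us)
  expect_equal(p1$pearson_r, p2$pearson_r)
})

test_that("pooled correlation recovers the planted coupling magnitude", {
  # oracle pooling weights: the generator's own muscle-quality directions
  dirs <- us_group_summaries("VL")
  vars <- c("EI", "MT", "ASM", "IDM", "Entropy")
  wx_true <- -dirs$direction[match(vars, dirs$variable)]
  rs <- vapply(1:200, function(s) {
    co <- generate_cohort(cohort_spec(coupling_rho = c(young = 0.53, old = 0),
                                      seed = s))
    sub <- co[co$group == "young", ]
    X <- preprocess_block(sub[, vars], sub$age)
    Y <- preprocess_block(sub[, grep("^sdCOP_", names(sub))] /
                            (sub$height_cm / 100), sub$age)
    pool_and_correlate(X, Y, wx_true)$pearson_r
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.53), 0.06)
})

test_that("the full group analysis returns a coherent result object", {
  co <- generate_cohort(cohort_spec(coupling_rho = c(young = 0.7, old = 0),
                                    seed = 49))
  sub <- co[co$group == "young", ]
  res <- rcca_analysis(sub[, c("EI", "MT", "ASM", "IDM", "Entropy")],
                       sub[, grep("^sdCOP_", names(sub))] /
                         (sub$height_cm / 100),
                       ages = sub$age,
                       grid = 10^seq(-2, 2, length.out = 5),
                       n_perm = 199, seed = 50)
  expect_s3_class(res, "rcca_result")
  expect_equal(sqrt(sum(res$wx^2)), 1, tolerance = 1e-12)
  expect_equal(sqrt(sum(res$wy^2)), 1, tolerance = 1e-12)
  expect_true(res$r >= 0 && res$r <= 1)
  expect_true(res$perm_p >= 1 / 200 && res$perm_p <= 1)
  expect_true(res$lambda_x %in% res$config$grid)
  # a strong planted coupling should be detected
  expect_lt(res$perm_p, 0.05)
})
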