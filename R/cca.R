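#' Preprocess a variable block for canonical correlation
#'
#' Per column, in order: z-score standardize; winsorize by clamping values
#' beyond `winsor_sd` standard deviations to that bound; optionally replace
#' the column by the residuals of its least-squares regression on age; and
#' re-standardize, so the CCA inputs are exactly unit-variance.
#'
#' @param block numeric matrix or data frame, subjects in rows.
#' @param ages age covariate (required when `age_covariate = TRUE`).
#' @param winsor_sd clamping bound in SD units (default 2.5).
#' @param age_covariate remove the linear age trend per column?
#' @return Numeric matrix, columns standardized (mean 0, SD 1).
#' @export
preprocess_block <- function(block, ages = NULL, winsor_sd = 2.5,
                             age_covariate = !is.null(ages)) {
  X <- as.matrix(block)
  if (winsor_sd <= 0) stopf("preprocess_block: winsor_sd must be > 0")
  if (age_covariate && is.null(ages)) {
    stopf("preprocess_block: ages required for age correction")
  }
  if (age_covariate && length(ages) != nrow(X)) {
    stopf("preprocess_block: ages must match the number of rows")
  }
  standardize <- function(v, j) {
    s <- sd(v)
    if (!is.finite(s) || s == 0) {
      stopf("preprocess_block: column '%s' has zero variance",
            if (is.null(colnames(X))) j else colnames(X)[j])
    }
    (v - mean(v)) / s
  }
  for (j in seq_len(ncol(X))) {
    z <- standardize(X[, j], j)
    z <- pmin(winsor_sd, pmax(-winsor_sd, z))
    if (age_covariate) {
      z <- residuals(lm(z ~ ages))
    }
    X[, j] <- standardize(z, j)
  }
  X
}

# symmetric inverse square root of a positive-definite matrix
inv_sqrt_sym <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  if (any(e$values <= 0)) {
    stopf("covariance matrix is not positive definite; add regularization")
  }
  e$vectors %*% diag(1 / sqrt(e$values), length(e$values)) %*% t(e$vectors)
}

#' Ridge-regularized canonical correlation (first pair)
#'
#' First canonical pair of the ridge problem: with sample covariances `Sxx`,
#' `Syy`, `Sxy`, the weights are the leading singular pair of
#' `(Sxx + lambda_x I)^{-1/2} Sxy (Syy + lambda_y I)^{-1/2}`, back-transformed
#' and normalized to unit length. The canonical correlation `r` is the
#' Pearson correlation of the projections, made non-negative by the sign
#' convention: the pair is flipped jointly so `r >= 0`, then the x-weight
#' sign is fixed so the entry for `MT` (or, absent that name, the
#' largest-magnitude entry) is positive.
#'
#' @param X,Y preprocessed blocks (same subjects, standardized columns).
#' @param lambda_x,lambda_y ridge penalties (>= 0) on the standardized scale.
#' @return List: `wx`, `wy` (unit norm), `r` in \[0, 1\], `lambda_x`,
#'   `lambda_y`.
#' @export
fit_rcca <- function(X, Y, lambda_x = 0, lambda_y = 0) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stopf("fit_rcca: X and Y need the same subjects")
  if (lambda_x < 0 || lambda_y < 0) stopf("fit_rcca: lambdas must be >= 0")
  n <- nrow(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  sxx <- crossprod(Xc) / (n - 1) + lambda_x * diag(ncol(X))
  syy <- crossprod(Yc) / (n - 1) + lambda_y * diag(ncol(Y))
  sxy <- crossprod(Xc, Yc) / (n - 1)
  if (!all(is.finite(sxy))) stopf("fit_rcca: non-finite covariance")
  kx <- inv_sqrt_sym(sxx); ky <- inv_sqrt_sym(syy)
  sv <- svd(kx %*% sxy %*% ky)
  wx <- drop(kx %*% sv$u[, 1]); wy <- drop(ky %*% sv$v[, 1])
  wx <- wx / sqrt(sum(wx^2)); wy <- wy / sqrt(sum(wy^2))
  r <- cor(drop(Xc %*% wx), drop(Yc %*% wy))
  if (r < 0) { wy <- -wy; r <- -r }
  # deterministic sign: MT weight positive (or largest-|w| entry positive)
  anchor <- if (!is.null(colnames(X)) && "MT" %in% colnames(X) &&
                wx[match("MT", colnames(X))] != 0) {
    match("MT", colnames(X))
  } else {
    which.max(abs(wx))
  }
  if (wx[anchor] < 0) { wx <- -wx; wy <- -wy }
  list(wx = wx, wy = wy, r = max(0, min(1, r)),
       lambda_x = lambda_x, lambda_y = lambda_y)
}

#' Leave-one-out selection of the ridge penalties
#'
#' For every pair on the grid, fits the regularized CCA on n-1 subjects,
#' projects the held-out subject on the fold's weights (sign-aligned by the
#' deterministic convention of [fit_rcca()]), and scores the pair by the
#' Pearson correlation of the n held-out projection pairs. Returns the
#' arg-max; ties break toward heavier regularization.
#'
#' @param X,Y preprocessed blocks.
#' @param grid numeric vector of candidate penalties (used for both blocks,
#'   all pairs); default 13 points log-spaced 1e-3..1e3.
#' @return List: `lambda_x`, `lambda_y`, `loo_r` (selected held-out
#'   correlation), `scores` (full grid of held-out correlations).
#' @export
select_lambda_loo <- function(X, Y,
                              grid = 10^seq(-3, 3, length.out = 13)) {
  if (length(grid) == 0) stopf("select_lambda_loo: empty grid")
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  pairs <- expand.grid(lambda_x = grid, lambda_y = grid)
  score <- numeric(nrow(pairs))
  for (g in seq_len(nrow(pairs))) {
    px <- numeric(n); py <- numeric(n)
    for (i in seq_len(n)) {
      f <- fit_rcca(X[-i, , drop = FALSE], Y[-i, , drop = FALSE],
                    pairs$lambda_x[g], pairs$lambda_y[g])
      px[i] <- sum(X[i, ] * f$wx)
      py[i] <- sum(Y[i, ] * f$wy)
    }
    score[g] <- if (sd(px) == 0 || sd(py) == 0) -Inf else cor(px, py)
  }
  best <- max(score)
  cand <- which(score >= best - 1e-12)
  # ties toward more regularization: largest lambda_x + lambda_y, then lambda_x
  ord <- order(pairs$lambda_x[cand] + pairs$lambda_y[cand],
               pairs$lambda_x[cand], decreasing = TRUE)
  sel <- cand[ord[1]]
  list(lambda_x = pairs$lambda_x[sel], lambda_y = pairs$lambda_y[sel],
       loo_r = score[sel],
       scores = cbind(pairs, loo_r = score))
}

#' Permutation test of the canonical correlation
#'
#' Re-fits the regularized CCA with the selected (fixed) penalties after
#' shuffling the rows of the muscle block — but not the sway block — and
#' compares the observed canonical correlation to its permutation
#' distribution: `p = (1 + #{r_perm >= r_obs}) / (n_perm + 1)`. Deterministic
#' given the seed. Set `reselect = TRUE` to re-run the leave-one-out penalty
#' selection inside every permutation (slower; the fixed-penalty default is
#' recorded in the result).
#'
#' @param X,Y preprocessed blocks.
#' @param lambda_x,lambda_y penalties selected on the observed data.
#' @param n_perm number of permutations (>= 1; 1000 is conventional).
#' @param seed integer seed.
#' @param reselect re-select penalties per permutation?
#' @param grid penalty grid, used only when `reselect = TRUE`.
#' @return List: `perm_p`, `r_obs`, `r_perm` (vector), `n_perm`, `seed`.
#' @export
permutation_test <- function(X, Y, lambda_x, lambda_y, n_perm = 1000,
                             seed = 1L, reselect = FALSE,
                             grid = 10^seq(-3, 3, length.out = 13)) {
  if (!is_count(n_perm) || n_perm < 1) {
    stopf("permutation_test: n_perm must be >= 1")
  }
  X <- as.matrix(X); Y <- as.matrix(Y)
  r_obs <- fit_rcca(X, Y, lambda_x, lambda_y)$r
  n <- nrow(X)
  r_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      Xp <- X[sample.int(n), , drop = FALSE]
      if (reselect) {
        lam <- select_lambda_loo(Xp, Y, grid)
        fit_rcca(Xp, Y, lam$lambda_x, lam$lambda_y)$r
      } else {
        fit_rcca(Xp, Y, lambda_x, lambda_y)$r
      }
    }, numeric(1))
  })
  list(perm_p = (1 + sum(r_perm >= r_obs)) / (n_perm + 1),
       r_obs = r_obs, r_perm = r_perm, n_perm = n_perm, seed = seed,
       lambda_fixed = !reselect)
}

#' Pooled muscle-quality and sway scores, and their correlation
#'
#' Pools the muscle block into one score per subject — the mean of the
#' standardized US parameters, sign-corrected by the canonical x-weights —
#' and the sway block into the mean of the standardized per-condition values,
#' then reports their Pearson correlation with a two-sided p-value.
#'
#' @param X preprocessed muscle block.
#' @param Y preprocessed sway block.
#' @param wx canonical x-weights whose signs direct the pooling (zero weights
#'   count as positive).
#' @return List of class `pooled_association`: `pooled_us`, `pooled_sway`,
#'   `pearson_r`, `p`, `label`.
#' @export
pool_and_correlate <- function(X, Y, wx) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (length(wx) != ncol(X)) stopf("pool_and_correlate: wx must match ncol(X)")
  sgn <- ifelse(wx >= 0, 1, -1)
  pooled_us <- rowMeans(sweep(X, 2, sgn, `*`))
  pooled_sway <- rowMeans(Y)
  if (sd(pooled_us) == 0 || sd(pooled_sway) == 0) {
    stopf("pool_and_correlate: pooled score has zero variance")
  }
  ct <- cor.test(pooled_us, pooled_sway)
  structure(list(pooled_us = pooled_us, pooled_sway = pooled_sway,
                 pearson_r = unname(ct$estimate), p = ct$p.value,
                 label = label_correlation_strength(unname(ct$estimate))),
            class = "pooled_association")
}

#' @export
print.pooled_association <- function(x, ...) {
  cat(sprintf("pooled muscle-sway correlation: r = %.3f (%s), p = %.4g\n",
              x$pearson_r, x$label, x$p))
  invisible(x)
}

#' Full regularized-CCA association analysis for one group
#'
#' The complete within-group procedure: preprocess both blocks (standardize,
#' winsorize at `winsor_sd` SD, remove the linear age trend, re-standardize),
#' select the ridge penalties by leave-one-out cross-validation, fit the
#' first canonical pair, assess it with a permutation test, and compute the
#' pooled-score Pearson correlation.
#'
#' @param us_block data frame/matrix of US parameters (default the five
#'   published CCA variables: EI, MT, ASM, IDM, Entropy).
#' @param sway_block data frame/matrix of per-condition height-normalized
#'   sdCOP values, same subjects.
#' @param ages age covariate.
#' @param winsor_sd winsorization bound, SD units.
#' @param grid ridge penalty grid.
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutation stream.
#' @return Object of class `rcca_result` with the canonical weights,
#'   canonical `r`, selected penalties, permutation p, pooled association,
#'   and configuration echo.
#' @export
rcca_analysis <- function(us_block, sway_block, ages, winsor_sd = 2.5,
                          grid = 10^seq(-3, 3, length.out = 13),
                          n_perm = 1000, seed = 1L) {
  X <- preprocess_block(us_block, ages, winsor_sd, age_covariate = TRUE)
  Y <- preprocess_block(sway_block, ages, winsor_sd, age_covariate = TRUE)
  lam <- select_lambda_loo(X, Y, grid)
  fit <- fit_rcca(X, Y, lam$lambda_x, lam$lambda_y)
  perm <- permutation_test(X, Y, lam$lambda_x, lam$lambda_y,
                           n_perm = n_perm, seed = seed)
  pooled <- pool_and_correlate(X, Y, fit$wx)
  structure(list(wx = setNames(fit$wx, colnames(as.matrix(us_block))),
                 wy = setNames(fit$wy, colnames(as.matrix(sway_block))),
                 r = fit$r, lambda_x = lam$lambda_x, lambda_y = lam$lambda_y,
                 loo_r = lam$loo_r, perm_p = perm$perm_p, n_perm = n_perm,
                 seed = seed, pooled = pooled,
                 config = list(winsor_sd = winsor_sd, grid = grid,
                               lambda_fixed_in_permutations = TRUE)),
            class = "rcca_result")
}

#' @export
print.rcca_result <- function(x, ...) {
  cat(sprintf(
    "<rcca_result> r = %.3f (lambda_x = %.3g, lambda_y = %.3g), perm p = %.4g (%d perms)\n",
    x$r, x$lambda_x, x$lambda_y, x$perm_p, x$n_perm))
  cat("  wx:", paste(sprintf("%s %+0.2f", names(x$wx), x$wx), collapse = ", "),
      "\n")
  cat(sprintf("  pooled r = %.3f (%s), p = %.4g\n", x$pooled$pearson_r,
              x$pooled$label, x$pooled$p))
  invisible(x)
}
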