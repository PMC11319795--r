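#' Empirical (non-parametric) ROC curve
#'
#' Builds the ROC curve from all distinct score thresholds and computes the
#' area under it by the trapezoidal rule, which equals the Mann-Whitney
#' probability estimate with ties counted one half. The orientation (+1/-1)
#' is applied to the scores before thresholding and must be fixed a priori;
#' data-driven flipping would bias the AUC upward.
#'
#' @param scores numeric predictor values, one per subject.
#' @param labels class labels; `positive_class` marks the cases.
#' @param orientation +1 if higher scores predict the positive class, -1
#'   otherwise.
#' @param positive_class label of the positive class (default: the second
#'   level, or `TRUE` for logicals).
#' @return Object of class `roc_result`: `thresholds`, `fpr`, `tpr`, `auc`,
#'   `positive_class`, `orientation`.
#' @export
empirical_roc <- function(scores, labels, orientation = 1,
                          positive_class = NULL) {
  if (anyNA(scores) || anyNA(labels)) {
    stopf("empirical_roc: missing scores or labels")
  }
  if (!orientation %in% c(-1, 1)) {
    stopf("empirical_roc: orientation must be +1 or -1")
  }
  if (is.null(positive_class)) {
    positive_class <- if (is.logical(labels)) TRUE else sort(unique(labels))[2]
  }
  pos <- labels == positive_class
  if (!any(pos) || all(pos)) {
    stopf("empirical_roc: both classes must be present")
  }
  s <- orientation * scores
  n_pos <- sum(pos); n_neg <- sum(!pos)
  # sweep the distinct thresholds from high to low with cumulative counts
  ord <- order(s, decreasing = TRUE)
  s_sorted <- s[ord]
  pos_sorted <- pos[ord]
  last_of_tie <- c(s_sorted[-1] != s_sorted[-length(s_sorted)], TRUE)
  cum_pos <- cumsum(pos_sorted)[last_of_tie]
  cum_neg <- cumsum(!pos_sorted)[last_of_tie]
  thr <- c(Inf, s_sorted[last_of_tie])
  tpr <- c(0, cum_pos / n_pos)
  fpr <- c(0, cum_neg / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(thresholds = orientation * thr, fpr = fpr, tpr = tpr,
                 auc = auc, positive_class = positive_class,
                 orientation = orientation,
                 method = "empirical_roc.trapezoid"),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (positive class: %s, orientation %+d)\n",
              x$auc, x$positive_class, x$orientation))
  invisible(x)
}

#' Rank-based AUC (Mann-Whitney with tie correction)
#'
#' Independent formulation of the AUC: the proportion of (positive, negative)
#' pairs ranked concordantly, ties counted one half. Equals the trapezoidal
#' area of the empirical ROC exactly on all inputs.
#'
#' @inheritParams empirical_roc
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels, orientation = 1, positive_class = NULL) {
  if (is.null(positive_class)) {
    positive_class <- if (is.logical(labels)) TRUE else sort(unique(labels))[2]
  }
  pos <- labels == positive_class
  if (!any(pos) || all(pos)) stopf("auc_rank: both classes must be present")
  s <- orientation * scores
  r <- rank(s)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# fixed a-priori score orientations: sign of the old-minus-young direction
# of each parameter, so the AUC for the older-positive class sits above 0.5
# when the data follow the published age effects
parameter_orientation <- function(parameter) {
  orient <- c(EI = 1, Entropy = 1, Contrast = 1,
              MT = -1, ASM = -1, IDM = -1, Correlation = -1, SAT = -1)
  if (!parameter %in% names(orient)) {
    stopf("classify_parameter: unknown parameter '%s'", parameter)
  }
  orient[[parameter]]
}

#' Young/old classification from one ultrasound parameter
#'
#' Empirical ROC for classifying subjects as older (positive class) from a
#' single US parameter, with the orientation fixed a priori from the
#' published direction of the age effect.
#'
#' @param cohort data frame with a `group` column (`"young"`/`"old"`) and the
#'   parameter column.
#' @param parameter one of MT, EI, SAT, ASM, Contrast, Correlation, IDM,
#'   Entropy.
#' @return A `roc_result`.
#' @export
classify_parameter <- function(cohort, parameter) {
  orientation <- parameter_orientation(parameter)
  if (!parameter %in% names(cohort)) {
    stopf("classify_parameter: cohort has no column '%s'", parameter)
  }
  empirical_roc(cohort[[parameter]], cohort$group,
                orientation = orientation, positive_class = "old")
}

#' Paired comparison of two AUCs (DeLong z-test)
#'
#' Compares the AUCs of two predictors measured on the same subjects, using
#' the DeLong covariance of the placement values to account for the
#' within-subject correlation: `z = (auc1 - auc2) / se_diff` with a two-sided
#' normal p-value. Identical (or strictly monotone-transformed) score pairs
#' give `z = 0, p = 1`.
#'
#' @param scores_a,scores_b score vectors on the same subjects.
#' @param labels class labels shared by both predictors.
#' @param orientation_a,orientation_b a-priori orientations.
#' @param positive_class label of the positive class.
#' @return List of class `auc_comparison`: `auc1`, `auc2`, `z`, `p`,
#'   `se_diff`.
#' @export
compare_auc_paired <- function(scores_a, scores_b, labels,
                               orientation_a = 1, orientation_b = 1,
                               positive_class = NULL) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stopf("compare_auc_paired: scores and labels must have equal length")
  }
  if (is.null(positive_class)) {
    positive_class <- if (is.logical(labels)) TRUE else sort(unique(labels))[2]
  }
  pos <- labels == positive_class
  if (!any(pos) || all(pos)) {
    stopf("compare_auc_paired: both classes must be present")
  }
  placements <- function(s) {
    sp <- s[pos]; sn <- s[!pos]
    # V10[i]: fraction of controls below case i (ties half)
    v10 <- vapply(sp, function(x) mean((sn < x) + 0.5 * (sn == x)), numeric(1))
    v01 <- vapply(sn, function(x) mean((sp > x) + 0.5 * (sp == x)), numeric(1))
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  pa <- placements(orientation_a * scores_a)
  pb <- placements(orientation_b * scores_b)
  m <- sum(pos); n <- sum(!pos)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d_auc <- pa$auc - pb$auc
  if (var_diff <= 0) {
    z <- 0; p <- 1
  } else {
    z <- d_auc / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(auc1 = pa$auc, auc2 = pb$auc, z = z, p = p,
                 se_diff = sqrt(max(0, var_diff)),
                 method = "delong.paired"),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("AUC %.3f vs %.3f: z = %.3f, p = %.4g [%s]\n",
              x$auc1, x$auc2, x$z, x$p, x$method))
  invisible(x)
}
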