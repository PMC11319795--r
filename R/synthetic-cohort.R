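#' Specification of a synthetic two-group cohort
#'
#' Describes a young/old cohort whose ultrasound (US) parameters and
#' per-condition sway magnitudes are drawn from a Gaussian copula: a joint
#' multivariate normal on z-scores, mapped per variable to the requested
#' marginal (normal, or moment-matched lognormal for the strictly positive
#' right-skewed texture features). The copula is built on the *age-aligned*
#' scale (a positive z always means "more old-like"), so a single exchangeable
#' correlation describes how strongly worse-composition markers travel
#' together.
#'
#' The muscle-sway coupling is planted through a constant cross-correlation
#' between every US z-score and every sway z-score, calibrated so that the
#' correlation between the muscle-quality-signed mean of the standardized
#' coupling variables (default: the five CCA variables EI, MT, ASM, IDM,
#' Entropy; quality sign = minus the age direction) and the mean of the
#' standardized per-condition sway values equals `coupling_rho` exactly in
#' population. A positive `coupling_rho` therefore plants "better muscle
#' composition, larger sway".
#'
#' @param n_young,n_old group sizes (>= 2).
#' @param us_params per-group marginals: data frame as returned by
#'   [us_group_summaries()] (columns `variable`, `mean_young`, `sd_young`,
#'   `mean_old`, `sd_old`, `family`, `direction`).
#' @param us_correlation correlation matrix among US variables on the
#'   age-aligned z scale (default exchangeable 0.3 — an assumption, not an
#'   estimate; no within-group correlations are published).
#' @param sway_means per-group per-condition sdCOP_AP targets, data frame as
#'   [sway_targets()].
#' @param sway_correlation correlation among the four conditions' sway
#'   z-scores (default exchangeable 0.6: sway magnitudes of the same subject
#'   co-vary strongly across conditions).
#' @param coupling_rho named vector `c(young = , old = )` of latent
#'   muscle-sway correlations in \[-1, 1\]; defaults emulate a moderate
#'   association in the young group (0.53) and none in the old group.
#' @param coupling_vars US variables entering the calibrated pooled mean.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_young = 32, n_old = 34,
                        us_params = us_group_summaries("VL"),
                        us_correlation = NULL,
                        sway_means = sway_targets(),
                        sway_correlation = NULL,
                        coupling_rho = c(young = 0.53, old = 0),
                        coupling_vars = c("EI", "MT", "ASM", "IDM", "Entropy"),
                        seed = 1L) {
  if (!is_count(n_young) || !is_count(n_old) || n_young < 2 || n_old < 2) {
    stopf("cohort_spec: group sizes must be integers >= 2")
  }
  req <- c("variable", "mean_young", "sd_young", "mean_old", "sd_old",
           "family", "direction")
  if (!all(req %in% names(us_params))) {
    stopf("cohort_spec: us_params must have columns %s",
          paste(req, collapse = ", "))
  }
  if (any(us_params$sd_young <= 0) || any(us_params$sd_old <= 0)) {
    stopf("cohort_spec: all us_params SDs must be > 0")
  }
  p <- nrow(us_params)
  if (is.null(us_correlation)) {
    us_correlation <- matrix(0.3, p, p); diag(us_correlation) <- 1
  }
  if (is.null(sway_correlation)) {
    sway_correlation <- matrix(0.6, 4, 4); diag(sway_correlation) <- 1
  }
  check_corr(us_correlation, p, "us_correlation")
  check_corr(sway_correlation, 4, "sway_correlation")
  if (any(sway_means$sd_mm <= 0)) stopf("cohort_spec: sway SDs must be > 0")
  if (is.null(names(coupling_rho))) names(coupling_rho) <- c("young", "old")
  if (any(abs(coupling_rho) > 1)) {
    stopf("cohort_spec: |coupling_rho| must be <= 1")
  }
  if (!all(coupling_vars %in% us_params$variable)) {
    stopf("cohort_spec: coupling_vars must name rows of us_params")
  }
  structure(list(n_young = as.integer(n_young), n_old = as.integer(n_old),
                 us_params = us_params, us_correlation = us_correlation,
                 sway_means = sway_means, sway_correlation = sway_correlation,
                 coupling_rho = coupling_rho, coupling_vars = coupling_vars,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

check_corr <- function(R, d, name) {
  R <- as.matrix(R)
  if (nrow(R) != d || ncol(R) != d) {
    stopf("%s must be %d x %d", name, d, d)
  }
  if (max(abs(R - t(R))) > 1e-8) stopf("%s is not symmetric", name)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stopf("%s is not positive semi-definite (min eigenvalue %.3g)",
          name, min(ev))
  }
  invisible(TRUE)
}

# joint (US + sway) correlation matrix for one group. The US z's live on the
# age-aligned scale (higher = worse muscle), so a muscle-QUALITY factor is
# minus their mean; the constant cross-block correlation is calibrated so
# that corr(quality-signed mean of the coupling-variable z's, mean of sway
# z's) = rho — the paper-style "better muscle, larger sway" coupling for
# rho > 0
joint_correlation <- function(spec, rho) {
  Rx <- spec$us_correlation
  Ry <- spec$sway_correlation
  p <- nrow(Rx); q <- nrow(Ry)
  idx <- match(spec$coupling_vars, spec$us_params$variable)
  k <- length(idx)
  v_pool_x <- sum(Rx[idx, idx]) / k^2    # var of the k-variable mean
  v_pool_y <- sum(Ry) / q^2
  cross <- -rho * sqrt(v_pool_x * v_pool_y)
  if (abs(cross) > 1) {
    stopf("coupling_rho = %.3g is not attainable with these correlation matrices",
          rho)
  }
  R <- rbind(cbind(Rx, matrix(cross, p, q)),
             cbind(matrix(cross, q, p), Ry))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stopf(paste("joint US-sway correlation matrix is not positive",
                "semi-definite for coupling_rho = %.3g; weaken the coupling",
                "or the within-block correlations"), rho)
  }
  R
}

# map age-aligned z-scores to a variable's marginal; direction = +1 when the
# variable increases with age (higher z = more old-like)
marginal_from_z <- function(z, mean, sd, family, direction) {
  zz <- direction * z
  if (family == "lognormal") {
    s2 <- log(1 + (sd / mean)^2)
    exp(log(mean) - s2 / 2 + sqrt(s2) * zz)
  } else {
    mean + sd * zz
  }
}

#' Generate a synthetic young/old cohort
#'
#' Draws one row per subject: demographics (age uniform over the group's
#' recruitment range, sex by the group's female proportion, height and weight
#' normal), the eight US parameters from the per-group Gaussian copula with
#' the requested marginals, and the four per-condition anterior-posterior
#' sway magnitudes (sdCOP_AP, mm) coupled to muscle quality with the planted
#' latent correlation. Deterministic given the spec (including its seed).
#'
#' @param spec a [cohort_spec()].
#' @return A data frame of class `cohort_table`, one row per subject, with
#'   columns `subject_id`, `group`, `age`, `sex`, `height_cm`, `weight_kg`,
#'   the US variables, and `sdCOP_<condition>` in mm.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    demo <- cohort_demographics()
    conds <- unique(spec$sway_means$condition)
    rows <- lapply(c("young", "old"), function(g) {
      n <- if (g == "young") spec$n_young else spec$n_old
      rho <- spec$coupling_rho[[g]]
      R <- joint_correlation(spec, rho)
      Z <- MASS::mvrnorm(n, mu = rep(0, nrow(R)), Sigma = R)
      Z <- matrix(Z, nrow = n)
      p <- nrow(spec$us_params)
      us <- sapply(seq_len(p), function(j) {
        pr <- spec$us_params[j, ]
        m <- if (g == "young") pr$mean_young else pr$mean_old
        s <- if (g == "young") pr$sd_young else pr$sd_old
        marginal_from_z(Z[, j], m, s, pr$family, pr$direction)
      })
      colnames(us) <- spec$us_params$variable
      sw <- sapply(seq_along(conds), function(c_i) {
        tg <- spec$sway_means[spec$sway_means$group == g &
                                spec$sway_means$condition == conds[c_i], ]
        tg$mean_mm + tg$sd_mm * Z[, p + c_i]
      })
      colnames(sw) <- paste0("sdCOP_", conds)
      dg <- demo[[g]]
      data.frame(
        subject_id = sprintf("%s%02d", toupper(substr(g, 1, 1)), seq_len(n)),
        group = g,
        age = runif(n, dg$age_range[1], dg$age_range[2]),
        sex = ifelse(runif(n) < dg$n_female / dg$n, "F", "M"),
        height_cm = rnorm(n, dg$height_mean, dg$height_sd),
        weight_kg = rnorm(n, dg$weight_mean, dg$weight_sd),
        us, sw,
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "spec") <- spec
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}

#' Write a cohort as a long-format CSV
#'
#' One row per subject x condition; a header comment documents the columns.
#'
#' @param cohort a `cohort_table` from [generate_cohort()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  conds <- sub("^sdCOP_", "", grep("^sdCOP_", names(cohort), value = TRUE))
  base_cols <- setdiff(names(cohort), paste0("sdCOP_", conds))
  long <- do.call(rbind, lapply(conds, function(cn) {
    d <- cohort[, base_cols, drop = FALSE]
    d$condition <- cn
    d$sdCOP_AP_mm <- cohort[[paste0("sdCOP_", cn)]]
    d
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# cohort table: one row per subject x condition;",
                   "US variables in native units (cm / 0-255 a.u. /",
                   "unitless), sdCOP_AP_mm in mm"), con)
  write.csv(long, con, row.names = FALSE)
  invisible(path)
}
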