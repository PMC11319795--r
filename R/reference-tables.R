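#' Published group summaries used as defaults
#'
#' Per-group (young / old) mean and SD of the ultrasound parameters of the
#' vastus lateralis (VL) and biceps brachii (BB), together with cohort
#' demographics, as reported for a 32 + 34 young/older cohort. These printed
#' summaries serve two roles: default marginals for the synthetic cohort
#' generator and inputs to summary-statistic tests. The `family` column marks
#' the marginal used when simulating: `lognormal` for strictly positive,
#' heavily right-skewed features (ASM and Correlation, whose SD rivals or
#' exceeds the mean), `normal` otherwise. `direction` is the sign of the
#' old-minus-young difference (+1 when values rise with age).
#'
#' @param muscle `"VL"` or `"BB"`.
#' @return Data frame with columns `variable`, `mean_young`, `sd_young`,
#'   `mean_old`, `sd_old`, `family`, `direction`.
#' @export
us_group_summaries <- function(muscle = c("VL", "BB")) {
  muscle <- match.arg(muscle)
  if (muscle == "VL") {
    df <- data.frame(
      variable    = c("MT", "EI", "SAT", "ASM", "Contrast", "Correlation",
                      "IDM", "Entropy"),
      mean_young  = c(2.21, 32.3, 0.98, 0.008, 66.9, 0.001, 0.295, 7.17),
      sd_young    = c(0.48, 7.1, 0.48, 0.02, 25.9, 0.0006, 0.06, 0.50),
      mean_old    = c(1.38, 56.0, 0.93, 0.001, 86.1, 0.001, 0.224, 7.77),
      sd_old      = c(0.33, 9.2, 0.49, 0.0003, 30.6, 0.0004, 0.03, 0.31),
      stringsAsFactors = FALSE
    )
  } else {
    df <- data.frame(
      variable    = c("MT", "EI", "SAT", "ASM", "Contrast", "Correlation",
                      "IDM", "Entropy"),
      mean_young  = c(2.79, 30.0, 0.52, 0.013, 119.1, 0.001, 0.249, 7.33),
      sd_young    = c(0.65, 6.9, 0.28, 0.02, 45.8, 0.0004, 0.07, 0.66),
      mean_old    = c(2.68, 42.3, 0.60, 0.001, 138.6, 0.0008, 0.176, 8.09),
      sd_old      = c(0.66, 8.4, 0.29, 0.002, 59.0, 0.0001, 0.04, 0.39),
      stringsAsFactors = FALSE
    )
  }
  df$family <- ifelse(df$variable %in% c("ASM", "Correlation"),
                      "lognormal", "normal")
  df$direction <- sign(df$mean_old - df$mean_young)
  # VL Correlation means tie at the printed precision; the underlying
  # difference is young > old (as in the BB), so age-direction is -1
  df$direction[df$variable == "Correlation"] <- -1
  df
}

#' Cohort demographic summaries used as defaults
#'
#' Demographics of the reference young (n = 32, 15 women, ages 19-31) and
#' older (n = 34, 18 women, ages 65-85) groups: height and weight mean/SD,
#' the female proportion, and the recruitment age ranges.
#'
#' @return Named list with one entry per group.
#' @export
cohort_demographics <- function() {
  list(
    young = list(n = 32L, n_female = 15L, age_range = c(19, 31),
                 height_mean = 173.0, height_sd = 10.0,
                 weight_mean = 74.8, weight_sd = 14.6),
    old   = list(n = 34L, n_female = 18L, age_range = c(65, 85),
                 height_mean = 166.4, height_sd = 9.4,
                 weight_mean = 72.0, weight_sd = 12.2)
  )
}

#' Default per-condition sway targets
#'
#' Mean and SD (mm) of the anterior-posterior centre-of-pressure standard
#' deviation (sdCOP_AP) per standing condition and age group, used as
#' synthetic-generator marginals. The values are assumptions chosen to match
#' the qualitative pattern of bipedal-stance posturography: sway rises from
#' eyes-open/hard through eyes-closed/foam, older adults sway more in every
#' condition, and the old/young gap is largest (about 57%) with eyes closed on
#' foam.
#'
#' @return Data frame with columns `condition`, `group`, `mean_mm`, `sd_mm`.
#' @export
sway_targets <- function() {
  cond <- c("EOhard", "EChard", "EOfoam", "ECfoam")
  data.frame(
    condition = rep(cond, 2),
    group = rep(c("young", "old"), each = 4),
    mean_mm = c(4.0, 4.5, 5.5, 8.0,
                5.2, 6.0, 7.5, 12.6),
    sd_mm = c(1.0, 1.1, 1.4, 2.0,
              1.3, 1.5, 1.9, 3.2),
    stringsAsFactors = FALSE
  )
}
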