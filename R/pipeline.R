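#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. All randomness flows from
#' one master seed through named substreams, so a rerun with the same
#' configuration is bit-identical.
#'
#' @param output_dir directory for result files (created if missing).
#' @param cohort a [cohort_spec()]; the cohort simulated from it feeds the
#'   group tables, ROC matrix and CCA.
#' @param glcm a [glcm_config()].
#' @param filter_band COP filter band, Hz.
#' @param winsor_sd CCA winsorization bound.
#' @param lambda_grid ridge penalty grid.
#' @param n_perm permutations for the CCA test (>= 1).
#' @param n_demo_images synthetic images run through the texture stage per
#'   group (0 disables the stage).
#' @param n_demo_recordings synthetic force-plate recordings run through the
#'   posturography stage (0 disables).
#' @param demo_duration_s duration of each demo recording, s.
#' @param groups groups analysed by the CCA stage.
#' @param cca_vars US variables entering the CCA block.
#' @param seed master seed.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(output_dir,
                            cohort = cohort_spec(),
                            glcm = glcm_config(),
                            filter_band = c(0.1, 10),
                            winsor_sd = 2.5,
                            lambda_grid = 10^seq(-3, 3, length.out = 13),
                            n_perm = 1000,
                            n_demo_images = 1,
                            n_demo_recordings = 1,
                            demo_duration_s = 60,
                            groups = c("young", "old"),
                            cca_vars = c("EI", "MT", "ASM", "IDM", "Entropy"),
                            seed = 1L) {
  if (!is_count(n_perm) || n_perm < 1) {
    stopf("pipeline_config: n_perm must be a positive integer")
  }
  if (!(0 < filter_band[1] && filter_band[1] < filter_band[2])) {
    stopf("pipeline_config: invalid filter band")
  }
  if (winsor_sd <= 0) stopf("pipeline_config: winsor_sd must be > 0")
  if (length(lambda_grid) == 0) stopf("pipeline_config: empty lambda grid")
  stopifnot(inherits(cohort, "cohort_spec"), inherits(glcm, "glcm_config"))
  structure(list(output_dir = output_dir, cohort = cohort, glcm = glcm,
                 filter_band = filter_band, winsor_sd = winsor_sd,
                 lambda_grid = lambda_grid, n_perm = n_perm,
                 n_demo_images = n_demo_images,
                 n_demo_recordings = n_demo_recordings,
                 demo_duration_s = demo_duration_s,
                 groups = groups, cca_vars = cca_vars,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# hash of the scientific configuration; the output location does not alter
# the analysis, so reruns into different directories stay comparable
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$output_dir <- NULL
  h <- fnv1a32(paste(deparse(cfg), collapse = ""))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

write_stamped_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# echosway %s config %s",
                     as.character(packageVersion("echosway")), hash), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

run_stage <- function(stage, code) {
  tryCatch(code, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort simulation; a texture demonstration (synthetic
#' images through EI/thickness/GLCM); a posturography demonstration
#' (synthetic recordings through COP reconstruction, filtering and sway
#' summary); the group-comparison table (pooled t-tests and effect sizes per
#' US variable); the ROC classification matrix with pairwise DeLong
#' comparisons; the two-way condition-by-age ANOVA of height-normalized sway;
#' and the per-group regularized CCA with permutation inference. Writes
#' human-readable CSV tables plus a machine-readable `results.json`; every
#' file embeds the package version and a configuration hash.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, the results list (also serialized to
#'   `results.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  results <- list(package_version = as.character(packageVersion("echosway")),
                  config_hash = hash, seed = config$seed)

  cohort <- run_stage("simulate", {
    spec <- config$cohort
    spec$seed <- derive_seed(config$seed, "cohort")
    generate_cohort(spec)
  })
  write_stamped_csv(as.data.frame(cohort),
                    file.path(config$output_dir, "cohort.csv"), hash)

  if (config$n_demo_images > 0) {
    results$texture <- run_stage("texture", {
      demo <- lapply(seq_len(config$n_demo_images), function(i) {
        lapply(c(young = "young", old = "old"), function(g) {
          ph <- if (g == "young") image_phenotype()
          else image_phenotype(mean_intensity = 56, heterogeneity_scale = 14,
                               muscle_thickness_px = 138)
          gen <- generate_us_image(
            ph, seed = derive_seed(config$seed, paste0("img_", g, "_", i)))
          feats <- haralick_features(
            compute_glcm(gen$image, gen$glcm_roi, config$glcm))
          thick <- measure_thickness(gen$landmarks, gen$image$pixel_spacing)
          c(list(group = g, EI = compute_ei(gen$image, gen$ei_roi)),
            thick, feats)
        })
      })
      rows <- do.call(rbind, lapply(unlist(demo, recursive = FALSE),
                                    function(r) as.data.frame(r)))
      write_stamped_csv(rows,
                        file.path(config$output_dir, "texture_demo.csv"), hash)
      rows
    })
  }

  if (config$n_demo_recordings > 0) {
    results$posture <- run_stage("posture", {
      rows <- do.call(rbind, lapply(seq_len(config$n_demo_recordings),
                                    function(i) {
        sp <- sway_spec(duration = config$demo_duration_s,
                        band = config$filter_band,
                        seed = derive_seed(config$seed, paste0("fp_", i)))
        rec <- generate_forceplate_recording(
          sp, subject_id = sprintf("demo%02d", i))
        cop <- bandpass_cop(compute_cop(rec), config$filter_band[1],
                            config$filter_band[2])
        s <- sway_summary(cop, height_m = 1.70)
        s$target_sd_ap <- sp$target_sd_ap
        s
      }))
      write_stamped_csv(rows,
                        file.path(config$output_dir, "sway_demo.csv"), hash)
      rows
    })
  }

  results$group_table <- run_stage("group_tables", {
    us_vars <- config$cohort$us_params$variable
    young <- cohort[cohort$group == "young", ]
    old <- cohort[cohort$group == "old", ]
    tab <- do.call(rbind, lapply(us_vars, function(v) {
      tt <- ttest_raw(young[[v]], old[[v]], variable = v)
      data.frame(variable = v,
                 mean_young = mean(young[[v]]), sd_young = sd(young[[v]]),
                 mean_old = mean(old[[v]]), sd_old = sd(old[[v]]),
                 t = tt$t, df = tt$df, p = tt$p, cohens_d = tt$cohens_d,
                 method = tt$method, stringsAsFactors = FALSE)
    }))
    write_stamped_csv(tab, file.path(config$output_dir, "group_table.csv"),
                      hash)
    tab
  })

  results$roc <- run_stage("classify", {
    us_vars <- config$cohort$us_params$variable
    aucs <- data.frame(
      parameter = us_vars,
      auc = vapply(us_vars, function(v) classify_parameter(cohort, v)$auc,
                   numeric(1)),
      orientation = vapply(us_vars, parameter_orientation, numeric(1)),
      stringsAsFactors = FALSE)
    prs <- combn(us_vars, 2)
    comp <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
      a <- prs[1, i]; b <- prs[2, i]
      cp <- compare_auc_paired(cohort[[a]], cohort[[b]], cohort$group,
                               parameter_orientation(a),
                               parameter_orientation(b),
                               positive_class = "old")
      data.frame(parameter_a = a, parameter_b = b, auc_a = cp$auc1,
                 auc_b = cp$auc2, z = cp$z, p = cp$p,
                 stringsAsFactors = FALSE)
    }))
    write_stamped_csv(aucs, file.path(config$output_dir, "roc_auc.csv"), hash)
    write_stamped_csv(comp,
                      file.path(config$output_dir, "roc_comparisons.csv"),
                      hash)
    list(auc = aucs, comparisons = comp)
  })

  results$anova <- run_stage("posture_anova", {
    long <- cohort_sway_long(cohort)
    an <- anova_condition_by_age(long)
    write_stamped_csv(an$effects,
                      file.path(config$output_dir, "anova_effects.csv"), hash)
    write_stamped_csv(an$posthoc,
                      file.path(config$output_dir, "anova_posthoc.csv"), hash)
    list(effects = an$effects, posthoc = an$posthoc)
  })

  results$cca <- run_stage("associate", {
    lapply(setNames(config$groups, config$groups), function(g) {
      sub <- cohort[cohort$group == g, ]
      X <- as.matrix(sub[, config$cca_vars])
      Y <- as.matrix(sub[, grep("^sdCOP_", names(sub))]) / (sub$height_cm / 100)
      res <- rcca_analysis(X, Y, ages = sub$age,
                           winsor_sd = config$winsor_sd,
                           grid = config$lambda_grid,
                           n_perm = config$n_perm,
                           seed = derive_seed(config$seed, paste0("cca_", g)))
      list(group = g, r = res$r, perm_p = res$perm_p,
           lambda_x = res$lambda_x, lambda_y = res$lambda_y,
           wx = as.list(res$wx), wy = as.list(res$wy),
           pooled_r = res$pooled$pearson_r, pooled_p = res$pooled$p,
           pooled_label = res$pooled$label)
    })
  })

  jsonlite::write_json(results, file.path(config$output_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(results)
}

#' Long-format sway table of a cohort
#'
#' One row per subject x condition with the height-normalized sdCOP_AP
#' (mm of sway per m of height), the layout the condition-by-age ANOVA runs
#' on.
#'
#' @param cohort a `cohort_table`.
#' @return Data frame with `subject_id`, `group`, `condition`,
#'   `sdCOP_AP_norm`.
#' @export
cohort_sway_long <- function(cohort) {
  conds <- sub("^sdCOP_", "", grep("^sdCOP_", names(cohort), value = TRUE))
  do.call(rbind, lapply(conds, function(cn) {
    data.frame(subject_id = cohort$subject_id, group = cohort$group,
               condition = cn,
               sdCOP_AP_norm = cohort[[paste0("sdCOP_", cn)]] /
                 (cohort$height_cm / 100),
               stringsAsFactors = FALSE)
  }))
}
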