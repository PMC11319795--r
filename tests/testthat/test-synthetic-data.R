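test_that("cohort generation is deterministic and hits the marginal targets", {
  sp <- cohort_spec(seed = 42)
  c1 <- generate_cohort(sp)
  c2 <- generate_cohort(sp)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 66)
  expect_setequal(unique(c1$group), c("young", "old"))

  # group means within 3 SE of the published echo-intensity marginals
  ei_y <- c1$EI[c1$group == "young"]; ei_o <- c1$EI[c1$group == "old"]
  expect_lt(abs(mean(ei_y) - 32.3), 3 * 7.1 / sqrt(32))
  expect_lt(abs(mean(ei_o) - 56.0), 3 * 9.2 / sqrt(34))
  # ages stay inside the recruitment ranges
  expect_true(all(c1$age[c1$group == "young"] >= 19 &
                    c1$age[c1$group == "young"] <= 31))
  expect_true(all(c1$age[c1$group == "old"] >= 65 &
                    c1$age[c1$group == "old"] <= 85))
})

test_that("sample covariance of the US block approaches the request as n grows", {
  target <- 0.3  # default exchangeable correlation on the age-aligned scale
  dist_for_n <- function(n, seed) {
    co <- generate_cohort(cohort_spec(n_young = n, n_old = 2, seed = seed))
    # normal-marginal variables carry the copula correlation exactly
    vars <- c("MT", "EI", "SAT", "Contrast", "IDM", "Entropy")
    dirs <- us_group_summaries("VL")
    sgn <- dirs$direction[match(vars, dirs$variable)]
    z <- sweep(scale(as.matrix(co[co$group == "young", vars])), 2, sgn, `*`)
    R <- matrix(target, length(vars), length(vars)); diag(R) <- 1
    sqrt(sum((cor(z) - R)^2))
  }
  d_small <- mean(sapply(1:5, function(s) dist_for_n(40, s)))
  d_large <- mean(sapply(1:5, function(s) dist_for_n(2000, s)))
  expect_lt(d_large, d_small / 2)
})

test_that("planted muscle-sway coupling is recovered and the null stays null", {
  pool_r <- function(co, g) {
    sub <- co[co$group == g, ]
    dirs <- us_group_summaries("VL")
    vars <- c("EI", "MT", "ASM", "IDM", "Entropy")
    sgn <- -dirs$direction[match(vars, dirs$variable)]  # muscle-quality signs
    zs <- sweep(scale(as.matrix(sub[, vars])), 2, sgn, `*`)
    cor(rowMeans(zs), rowMeans(scale(sub[, grep("^sdCOP_", names(sub))])))
  }
  # rho = 0 in both groups: independence by construction
  big <- generate_cohort(cohort_spec(n_young = 10000, n_old = 2,
                                     coupling_rho = c(young = 0, old = 0),
                                     seed = 5))
  expect_lt(abs(pool_r(big, "young")), 0.05)
  # rho = 0.5: mean sample correlation across 200 seeds within +/- 0.05
  rs <- vapply(1:200, function(s) {
    pool_r(generate_cohort(cohort_spec(
      coupling_rho = c(young = 0.5, old = 0), seed = s)), "young")
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.5), 0.05)
})

test_that("invalid cohort specifications are rejected with a named matrix", {
  bad <- matrix(0.9, 8, 8); diag(bad) <- 1; bad[1, 2] <- -0.9
  expect_error(cohort_spec(us_correlation = bad), "us_correlation")
  expect_error(cohort_spec(coupling_rho = c(young = 1.2, old = 0)),
               "coupling_rho")
  expect_error(cohort_spec(n_young = 1), "group sizes")
})

test_that("synthetic images carry their ground truth", {
  ph <- image_phenotype()
  gen <- generate_us_image(ph, seed = 3)
  gen2 <- generate_us_image(ph, seed = 3)
  expect_identical(gen$image$pixels, gen2$image$pixels)

  # thickness round-trips exactly through the landmarks
  th <- measure_thickness(gen$landmarks, ph$pixel_spacing)
  expect_equal(th$MT_cm, ph$muscle_thickness_px * ph$pixel_spacing)
  expect_equal(th$SAT_cm, ph$sat_thickness_px * ph$pixel_spacing)

  # realized muscle mean within +/- 2 gray levels of the phenotype
  expect_lt(abs(as.numeric(compute_ei(gen$image, gen$ei_roi)) -
                  ph$mean_intensity), 2)

  expect_error(image_phenotype(muscle_thickness_px = 1000), "exceed")
})

test_that("heterogeneity drives the texture features in the expected directions", {
  flat <- image_phenotype(heterogeneity_scale = 0)
  rough <- image_phenotype(heterogeneity_scale = 40)
  n_seeds <- 12
  feats <- function(ph) {
    rows <- lapply(seq_len(n_seeds), function(s) {
      g <- generate_us_image(ph, seed = s)
      haralick_features(compute_glcm(g$image, g$glcm_roi))
    })
    colMeans(do.call(rbind, lapply(rows, function(f) {
      unlist(f[c("ASM", "Contrast", "IDM", "Entropy")])
    })))
  }
  f0 <- feats(flat); f40 <- feats(rough)
  expect_gt(f0[["ASM"]], f40[["ASM"]])
  expect_gt(f0[["IDM"]], f40[["IDM"]])
  expect_lt(f0[["Contrast"]], f40[["Contrast"]])
  expect_lt(f0[["Entropy"]], f40[["Entropy"]])
})

test_that("young-like vs old-like phenotypes reproduce the published effect directions", {
  young_ph <- image_phenotype()  # mean 32, low clutter
  old_ph <- image_phenotype(mean_intensity = 56, heterogeneity_scale = 14,
                            muscle_thickness_px = 138)
  n_seeds <- 25
  ok_entropy <- 0; ok_asm <- 0
  for (s in seq_len(n_seeds)) {
    gy <- generate_us_image(young_ph, seed = s)
    go <- generate_us_image(old_ph, seed = s)
    fy <- haralick_features(compute_glcm(gy$image, gy$glcm_roi))
    fo <- haralick_features(compute_glcm(go$image, go$glcm_roi))
    ok_entropy <- ok_entropy + (fo$Entropy > fy$Entropy)
    ok_asm <- ok_asm + (fo$ASM < fy$ASM)
  }
  expect_gte(ok_entropy / n_seeds, 0.95)
  expect_gte(ok_asm / n_seeds, 0.95)
})

test_that("image and annotations survive a PNG + JSON round trip", {
  gen <- generate_us_image(image_phenotype(image_size = c(300, 200),
                                           muscle_thickness_px = 120),
                           seed = 9)
  png_f <- tempfile(fileext = ".png"); json_f <- tempfile(fileext = ".json")
  write_us_image(gen, png_f, json_f)
  back <- read_us_image(png_f, json_f)
  expect_identical(back$image$pixels, gen$image$pixels)
  expect_equal(back$landmarks$deep_boundary_depth,
               gen$landmarks$deep_boundary_depth)
  expect_equal(back$ei_roi$vertices, gen$ei_roi$vertices,
               ignore_attr = TRUE)
  expect_equal(as.numeric(compute_ei(back$image, back$ei_roi)),
               as.numeric(compute_ei(gen$image, gen$ei_roi)))
  unlink(c(png_f, json_f))
})

test_that("force-plate recordings encode the latent COP exactly", {
  sp <- sway_spec(target_sd_ap = 5, target_sd_ml = 3, duration = 30,
                  seed = 2)
  rec <- generate_forceplate_recording(sp)
  rec2 <- generate_forceplate_recording(sp)
  expect_identical(rec$Mx, rec2$Mx)
  lat <- attr(rec, "latent")
  expect_equal(sd(lat$cop_ap), 5)
  expect_equal(sd(lat$cop_ml), 3)
  cop <- compute_cop(rec)
  expect_equal(cop$cop_ap, lat$cop_ap, tolerance = 1e-12)
  expect_equal(cop$cop_ml, lat$cop_ml, tolerance = 1e-12)

  # zero target gives a constant COP; scaling the target scales the COP
  z <- generate_forceplate_recording(sway_spec(target_sd_ap = 0,
                                               duration = 30, seed = 2))
  expect_equal(sd(attr(z, "latent")$cop_ap), 0)
  d <- generate_forceplate_recording(sway_spec(target_sd_ap = 10,
                                               duration = 30, seed = 2))
  expect_equal(attr(d, "latent")$cop_ap, 2 * lat$cop_ap, tolerance = 1e-10)

  expect_error(sway_spec(target_sd_ap = -1), "target SDs")
  expect_error(sway_spec(band = c(0.1, 600), fs = 1000), "band")
})
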