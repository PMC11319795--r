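# shared fixtures built in code

# brute-force GLCM by explicit double loop over pixel pairs, the independent
# oracle for the vectorized implementation
glcm_bruteforce <- function(pixels, levels, distance, angle) {
  off <- switch(as.character(angle),
                "0" = c(0, distance), "90" = c(-distance, 0),
                "180" = c(0, -distance), "270" = c(distance, 0))
  counts <- matrix(0, levels, levels)
  nr <- nrow(pixels); nc <- ncol(pixels)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        i <- pixels[r, c] + 1; j <- pixels[r2, c2] + 1
        counts[i, j] <- counts[i, j] + 1
      }
    }
  }
  counts / sum(counts)
}

random_small_image <- function(seed, max_side = 8, max_levels = 4) {
  set.seed(seed)
  nr <- sample(2:max_side, 1); nc <- sample(2:max_side, 1)
  lv <- sample(2:max_levels, 1)
  list(pixels = matrix(sample(0:(lv - 1), nr * nc, replace = TRUE), nr, nc),
       levels = lv)
}

# unfiltered cop_series wrapper for direct signal injection
make_cop <- function(x, fs = 1000, ml = NULL) {
  structure(list(cop_ap = x, cop_ml = if (is.null(ml)) 0 * x else ml,
                 fs = fs, filtered = FALSE, band = NULL,
                 condition = "EOhard", subject_id = "S01"),
            class = "cop_series")
}

# preprocessed young/old blocks from a synthetic cohort
cohort_blocks <- function(seed, group, rho_young = 0.5, rho_old = 0) {
  co <- generate_cohort(cohort_spec(
    coupling_rho = c(young = rho_young, old = rho_old), seed = seed))
  sub <- co[co$group == group, ]
  list(
    X = preprocess_block(sub[, c("EI", "MT", "ASM", "IDM", "Entropy")],
                         sub$age),
    Y = preprocess_block(sub[, grep("^sdCOP_", names(sub))] /
                           (sub$height_cm / 100), sub$age)
  )
}
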