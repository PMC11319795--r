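#' Force-plate recording
#'
#' Raw force-plate signals: three forces (N) and three moments (N m) about
#' the plate-surface origin, sampled at `fs` Hz. Axis convention: x = medio-
#' lateral (ML), y = anterior-posterior (AP), z = vertical.
#'
#' @param fs sampling rate, Hz (> 20 so the 0.1-10 Hz band fits).
#' @param Fx,Fy,Fz,Mx,My,Mz equal-length numeric channels.
#' @param condition one of `"EOhard"`, `"EChard"`, `"EOfoam"`, `"ECfoam"`.
#' @param subject_id subject label.
#' @return A `force_plate_recording` object.
#' @export
force_plate_recording <- function(fs, Fx, Fy, Fz, Mx, My, Mz,
                                  condition = "EOhard",
                                  subject_id = "S01") {
  n <- length(Fz)
  chans <- list(Fx = Fx, Fy = Fy, Fz = Fz, Mx = Mx, My = My, Mz = Mz)
  if (!all(lengths(chans) == n)) {
    stopf("force_plate_recording: channels must have equal length")
  }
  if (!is.numeric(fs) || fs <= 20) {
    stopf("force_plate_recording: fs must be > 20 Hz")
  }
  if (!condition %in% c("EOhard", "EChard", "EOfoam", "ECfoam")) {
    stopf("force_plate_recording: unknown condition '%s'", condition)
  }
  structure(c(list(fs = fs, t = seq_len(n) / fs), chans,
              list(condition = condition, subject_id = subject_id)),
            class = "force_plate_recording")
}

#' @export
print.force_plate_recording <- function(x, ...) {
  cat(sprintf("<force_plate_recording> %s/%s: %.1f s at %g Hz\n",
              x$subject_id, x$condition, length(x$Fz) / x$fs, x$fs))
  invisible(x)
}

#' Centre of pressure from force-plate signals
#'
#' COP about the plate-surface origin, from the raw moments and the vertical
#' force: `COP_AP = Mx / Fz`, `COP_ML = -My / Fz`, converted to mm. Requires
#' a plausible continuous stance (`|Fz| > 50 N` throughout).
#'
#' @param rec a [force_plate_recording()].
#' @return A `cop_series` object: `cop_ap` and `cop_ml` in mm, `fs`, and a
#'   `filtered` flag (FALSE).
#' @export
compute_cop <- function(rec) {
  stopifnot(inherits(rec, "force_plate_recording"))
  bad <- which(abs(rec$Fz) <= 50)
  if (length(bad) > 0) {
    stopf("compute_cop: |Fz| <= 50 N at %d samples (first few: %s)",
          length(bad), paste(head(bad, 5), collapse = ", "))
  }
  structure(list(cop_ap = 1000 * rec$Mx / rec$Fz,
                 cop_ml = -1000 * rec$My / rec$Fz,
                 fs = rec$fs, filtered = FALSE, band = NULL,
                 condition = rec$condition, subject_id = rec$subject_id),
            class = "cop_series")
}

#' @export
print.cop_series <- function(x, ...) {
  cat(sprintf("<cop_series> %d samples at %g Hz, %s\n", length(x$cop_ap),
              x$fs,
              if (x$filtered) sprintf("filtered %g-%g Hz", x$band[1], x$band[2])
              else "unfiltered"))
  invisible(x)
}

# Butterworth biquad (second-order section) at corner f0 and quality Q,
# bilinear-transformed with frequency prewarping (RBJ cookbook form)
butter_biquad <- function(f0, fs, type, Q) {
  w0 <- 2 * pi * f0 / fs
  cw <- cos(w0)
  alpha <- sin(w0) / (2 * Q)
  if (type == "high") {
    b <- c((1 + cw) / 2, -(1 + cw), (1 + cw) / 2)
  } else {
    b <- c((1 - cw) / 2, (1 - cw), (1 - cw) / 2)
  }
  a <- c(1 + alpha, -2 * cw, 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# 4th-order Butterworth as two cascaded biquads at the Butterworth pole
# quality factors; cascading second-order sections keeps the 0.1 Hz corner
# (normalized frequency 2e-4) numerically well conditioned, where a single
# 4th- or 8th-order transfer function has a pole cluster at z = 1 whose
# rounding noise floor is orders of magnitude higher
butter4_sos <- function(f0, fs, type) {
  q <- 1 / (2 * sin(pi / 8 * c(1, 3)))   # 1.3066, 0.5412
  lapply(q, function(qq) butter_biquad(f0, fs, type, qq))
}

apply_sos <- function(sections, v) {
  for (s in sections) {
    v <- as.numeric(signal::filter(signal::Arma(b = s$b, a = s$a), v))
  }
  v
}

# zero-phase 4th-order Butterworth band-pass: high-pass then low-pass, each
# run forward and backward over an odd-reflection-padded copy; the mean is
# removed first so a pure offset maps to exactly zero
zero_phase_bandpass <- function(x, fs, low, high) {
  n <- length(x)
  pad <- min(n - 1L, as.integer(3 * fs))
  if (n < 3 * pad || n < 64) {
    stopf("band-pass: series of %d samples is shorter than 3x the filter warm-up (%d)",
          n, pad)
  }
  hp <- butter4_sos(low, fs, "high")
  lp <- butter4_sos(high, fs, "low")
  x <- x - mean(x)
  run <- function(sections, v) {
    m <- length(v)
    vp <- c(2 * v[1] - v[(pad + 1):2], v, 2 * v[m] - v[(m - 1):(m - pad)])
    y <- apply_sos(sections, vp)
    y <- rev(apply_sos(sections, rev(y)))
    y[(pad + 1):(pad + m)]
  }
  run(lp, run(hp, x))
}

#' Band-pass filter a COP series
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass, the
#' dominant posturography convention; the DC component is removed.
#'
#' @param cop a `cop_series` from [compute_cop()].
#' @param low,high band edges in Hz, `0 < low < high < fs/2`.
#' @return The filtered `cop_series`, flagged with its band.
#' @export
bandpass_cop <- function(cop, low = 0.1, high = 10) {
  stopifnot(inherits(cop, "cop_series"))
  if (!(0 < low && low < high && high < cop$fs / 2)) {
    stopf("bandpass_cop: need 0 < low < high < fs/2 (got %g, %g at fs = %g)",
          low, high, cop$fs)
  }
  cop$cop_ap <- zero_phase_bandpass(cop$cop_ap, cop$fs, low, high)
  cop$cop_ml <- zero_phase_bandpass(cop$cop_ml, cop$fs, low, high)
  cop$filtered <- TRUE
  cop$band <- c(low, high)
  cop
}

#' Sway summary of a filtered COP series
#'
#' Postural stability quantified as the sample standard deviation (n - 1
#' denominator) of the filtered COP per axis, in mm, and normalized by body
#' height (mm of sway per m of height). Low sdCOP indicates good stability.
#' Refuses unfiltered input: an un-removed DC offset would silently inflate
#' the SD.
#'
#' @param cop a filtered `cop_series`.
#' @param height_m body height in m.
#' @return A `sway_summary` object (also a one-row data frame) with
#'   `sdCOP_AP`, `sdCOP_ML` (mm), `sdCOP_AP_norm`, `sdCOP_ML_norm` (mm/m),
#'   `height_m`, `condition`, `subject_id`.
#' @export
sway_summary <- function(cop, height_m) {
  stopifnot(inherits(cop, "cop_series"))
  if (!isTRUE(cop$filtered)) {
    stopf("sway_summary: COP series must be band-pass filtered first")
  }
  if (!is.numeric(height_m) || height_m <= 0) {
    stopf("sway_summary: height must be > 0")
  }
  sd_ap <- sd(cop$cop_ap); sd_ml <- sd(cop$cop_ml)
  out <- data.frame(subject_id = cop$subject_id, condition = cop$condition,
                    sdCOP_AP = sd_ap, sdCOP_ML = sd_ml,
                    sdCOP_AP_norm = sd_ap / height_m,
                    sdCOP_ML_norm = sd_ml / height_m,
                    height_m = height_m, stringsAsFactors = FALSE)
  class(out) <- c("sway_summary", "data.frame")
  out
}

#' Average sway summaries over repeated blocks
#'
#' Per-subject, per-condition mean of the sway statistics across the repeated
#' measurement blocks, taken before any group statistics; averaging is
#' order-invariant.
#'
#' @param summaries data frame of row-bound [sway_summary()] results.
#' @return Data frame with one row per subject x condition.
#' @export
average_blocks <- function(summaries) {
  stopifnot(all(c("subject_id", "condition", "sdCOP_AP") %in% names(summaries)))
  num_cols <- c("sdCOP_AP", "sdCOP_ML", "sdCOP_AP_norm", "sdCOP_ML_norm",
                "height_m")
  num_cols <- intersect(num_cols, names(summaries))
  agg <- aggregate(summaries[num_cols],
                   by = list(subject_id = summaries$subject_id,
                             condition = summaries$condition),
                   FUN = mean)
  agg[order(agg$subject_id, agg$condition), , drop = FALSE]
}

#' Read a force-plate CSV
#'
#' Expects columns `time_s, Fx, Fy, Fz, Mx, My, Mz`; the sampling rate is
#' inferred from `time_s`.
#'
#' @param path CSV file (leading `#` comment lines allowed).
#' @param condition,subject_id labels attached to the recording.
#' @return A [force_plate_recording()].
#' @export
read_forceplate_csv <- function(path, condition = "EOhard",
                                subject_id = "S01") {
  d <- read.csv(path, comment.char = "#")
  need <- c("time_s", "Fx", "Fy", "Fz", "Mx", "My", "Mz")
  if (!all(need %in% names(d))) {
    stopf("read_forceplate_csv: %s must have columns %s", path,
          paste(need, collapse = ", "))
  }
  fs <- 1 / median(diff(d$time_s))
  force_plate_recording(fs, d$Fx, d$Fy, d$Fz, d$Mx, d$My, d$Mz,
                        condition = condition, subject_id = subject_id)
}

#' Write a force-plate recording as CSV
#'
#' @param rec a [force_plate_recording()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_forceplate_csv <- function(rec, path) {
  d <- data.frame(time_s = rec$t, Fx = rec$Fx, Fy = rec$Fy, Fz = rec$Fz,
                  Mx = rec$Mx, My = rec$My, Mz = rec$Mz)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
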