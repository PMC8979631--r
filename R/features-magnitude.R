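# Magnitude domain: 84 characteristics — 7 measures (RMS, SD, max,
# min, range, jerk RMS, jerk ratio) x 4 axes (VT, ML, AP, resultant)
# x 3 segmentation levels (step, stride, pass), each averaged across
# that level's segments.

magnitude_measure_names <- function()
  c("rms", "sd", "max", "min", "range", "jerk_rms", "jerk_ratio")

magnitude_feature_names <- function() {
  grid <- expand.grid(measure = magnitude_measure_names(),
                      axis = c("vt", "ml", "ap", "res"),
                      level = c("step", "stride", "pass"),
                      stringsAsFactors = FALSE)
  paste0("mag_", grid$measure, "_", grid$axis, "_", grid$level)
}

#' Magnitude measures of one signal segment
#'
#' RMS is computed on the mean-removed samples; max/min/range likewise.
#' Jerk is the central-difference time derivative of acceleration
#' (one-sided at the ends); the jerk ratio is the dimensionless
#' smoothness measure `jerk RMS * duration / RMS` (missing when
#' RMS = 0).
#'
#' @param x Numeric segment (acceleration, m/s^2); for the resultant
#'   axis pass the norm signal with `center = FALSE`.
#' @param fs Sampling frequency (Hz).
#' @param center Remove the segment mean before RMS/max/min (default
#'   `TRUE`; the resultant norm is already built from mean-removed
#'   axes).
#' @return Named vector of the 7 measures, or all-`NA` for segments
#'   shorter than 5 samples.
#' @export
magnitude_measures <- function(x, fs, center = TRUE) {
  nm <- magnitude_measure_names()
  out <- stats::setNames(rep(NA_real_, 7), nm)
  if (length(x) < 5) {
    message("segment shorter than 5 samples: magnitude measures missing")
    return(out)
  }
  x0 <- if (center) x - mean(x) else x
  dt <- 1 / fs
  n <- length(x)
  jerk <- c(x[2] - x[1],
            (x[3:n] - x[1:(n - 2)]) / 2,
            x[n] - x[n - 1]) / dt
  rms <- sqrt(mean(x0^2))
  jerk_rms <- sqrt(mean(jerk^2))
  out["rms"] <- rms
  out["sd"] <- stats::sd(x)
  out["max"] <- max(x0)
  out["min"] <- min(x0)
  out["range"] <- max(x0) - min(x0)
  out["jerk_rms"] <- jerk_rms
  out["jerk_ratio"] <- if (rms > 0) jerk_rms * (n * dt) / rms else NA_real_
  out
}

#' Magnitude feature vector (84 characteristics)
#'
#' Applies [magnitude_measures()] per axis to every step, stride and
#' pass segment and averages within each level.  The resultant axis is
#' the Euclidean norm of the mean-removed three-axis signal of the
#' segment, so that `RMS_res^2 = RMS_vt^2 + RMS_ml^2 + RMS_ap^2` holds
#' per segment.
#'
#' @param rec A preprocessed `gait_recording`.
#' @param ev A `gait_events` object.
#' @return Named numeric vector of length 84 (prefix `mag_`).
#' @export
magnitude_vector <- function(rec, ev) {
  nm <- magnitude_feature_names()
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  fs <- rec$fs
  for (level in c("step", "stride", "pass")) {
    segs <- segment(rec, ev, level)
    if (!nrow(segs)) next
    acc <- array(NA_real_, c(nrow(segs), 7, 4),
                 dimnames = list(NULL, magnitude_measure_names(),
                                 c("vt", "ml", "ap", "res")))
    for (i in seq_len(nrow(segs))) {
      block <- segment_samples(rec, segs$start_idx[i], segs$end_idx[i])
      if (nrow(block) < 5) next
      ctr <- sweep(block, 2, colMeans(block))
      for (a in c("vt", "ml", "ap"))
        acc[i, , a] <- magnitude_measures(ctr[, a], fs, center = FALSE)
      acc[i, , "res"] <- magnitude_measures(sqrt(rowSums(ctr^2)), fs,
                                            center = FALSE)
    }
    for (a in c("vt", "ml", "ap", "res")) {
      m <- acc[, , a, drop = FALSE]
      dim(m) <- dim(m)[1:2]
      v <- colMeans(m, na.rm = TRUE)
      out[paste0("mag_", magnitude_measure_names(), "_", a, "_", level)] <- v
    }
  }
  out
}
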