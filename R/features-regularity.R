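# Regularity domain: 20 characteristics from the unbiased
# autocorrelation — step regularity (Ad1), stride regularity (Ad2),
# their ratio (step/stride symmetry) and the combined-axis gait
# symmetry index (GSI).

regularity_feature_names <- function() {
  axes4 <- c("vt", "ml", "ap", "res")
  c(paste0("reg_step_", axes4, "_bout"),
    paste0("reg_stride_", axes4, "_bout"),
    paste0("reg_step_", axes4, "_pass"),
    paste0("reg_stride_", axes4, "_pass"),
    paste0("reg_symmetry_", c("vt", "ml"), "_bout"),
    paste0("reg_gsi_", c("bout", "pass")))
}

#' Step and stride regularity from the unbiased autocorrelation
#'
#' Ad1 (step regularity) is the maximum of the normalized unbiased
#' autocorrelation within +/- 20% of the mean step lag; Ad2 (stride
#' regularity) the maximum within +/- 20% of the mean stride lag;
#' symmetry is Ad1 / Ad2.  Values near 1 indicate highly repeatable
#' steps/strides.
#'
#' @param x Numeric signal.
#' @param mean_step_time,mean_stride_time Mean step and stride
#'   durations (s).
#' @param fs Sampling frequency (Hz).
#' @return Named vector `ad1`, `ad2`, `symmetry` (missing when a
#'   search window does not fit inside the usable lag range).
#' @export
step_stride_regularity <- function(x, mean_step_time, mean_stride_time,
                                   fs) {
  max_lag <- floor(length(x) / 2)
  lag_step <- mean_step_time * fs
  lag_stride <- mean_stride_time * fs
  out <- c(ad1 = NA_real_, ad2 = NA_real_, symmetry = NA_real_)
  if (ceiling(1.2 * lag_stride) > max_lag || floor(0.8 * lag_step) < 1)
    return(out)
  a <- unbiased_autocorrelation(x, max_lag)
  win <- function(lag) {
    lo <- max(1, floor(0.8 * lag)); hi <- min(max_lag, ceiling(1.2 * lag))
    max(a[(lo:hi) + 1])
  }
  out["ad1"] <- win(lag_step)
  out["ad2"] <- win(lag_stride)
  out["symmetry"] <- out["ad1"] / out["ad2"]
  out
}

#' Gait symmetry index
#'
#' Combines the three per-axis normalized (unbiased) autocorrelations
#' at the step lag into `GSI = C_step / sqrt(3)` with `C_step` the
#' Euclidean norm of the per-axis coefficients, so perfectly symmetric
#' periodic gait scores 1.  The step lag is located as the maximum of
#' `C(m)` within +/- 20% of the nominal step lag.
#'
#' @param samples T x 3 matrix (columns vt, ml, ap), preprocessed.
#' @param mean_step_time Mean step duration (s).
#' @param fs Sampling frequency (Hz).
#' @return Scalar in \[0, 1\].
#' @export
gait_symmetry_index <- function(samples, mean_step_time, fs) {
  n <- nrow(samples)
  lag_step <- mean_step_time * fs
  max_lag <- min(n - 1, ceiling(1.2 * lag_step))
  if (floor(0.8 * lag_step) < 1 || max_lag <= floor(0.8 * lag_step))
    return(NA_real_)
  ac <- sapply(c("vt", "ml", "ap"), function(a)
    unbiased_autocorrelation(samples[, a], max_lag))
  lo <- max(1, floor(0.8 * lag_step)); hi <- max_lag
  cmb <- sqrt(rowSums(ac[(lo:hi) + 1, , drop = FALSE]^2))
  min(max(cmb) / sqrt(3), 1)
}

#' Regularity feature vector (20 characteristics)
#'
#' @param rec A preprocessed `gait_recording`.
#' @param ev A `gait_events` object.
#' @return Named numeric vector of length 20 (prefix `reg_`).
#' @export
regularity_vector <- function(rec, ev) {
  nm <- regularity_feature_names()
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  fs <- rec$fs
  tp <- temporal_params(ev)
  mst <- mean(tp$steps$step_time, na.rm = TRUE)
  mstr <- mean(tp$strides$stride_time, na.rm = TRUE)
  axes4 <- c("vt", "ml", "ap", "res")
  sig_bout <- axis_signals(rec$samples)
  for (a in axes4) {
    r <- step_stride_regularity(sig_bout[[a]], mst, mstr, fs)
    out[paste0("reg_step_", a, "_bout")] <- r["ad1"]
    out[paste0("reg_stride_", a, "_bout")] <- r["ad2"]
  }
  out["reg_symmetry_vt_bout"] <-
    out["reg_step_vt_bout"] / out["reg_stride_vt_bout"]
  out["reg_symmetry_ml_bout"] <-
    out["reg_step_ml_bout"] / out["reg_stride_ml_bout"]
  pass_segs <- segment(rec, ev, "pass")
  acc <- matrix(NA_real_, nrow(pass_segs), 2 * length(axes4),
                dimnames = list(NULL, c(paste0("step_", axes4),
                                        paste0("stride_", axes4))))
  gsi_p <- numeric(nrow(pass_segs))
  for (i in seq_len(nrow(pass_segs))) {
    seg <- segment_samples(rec, pass_segs$start_idx[i], pass_segs$end_idx[i])
    sig <- axis_signals(seg)
    for (a in axes4) {
      r <- step_stride_regularity(sig[[a]], mst, mstr, fs)
      acc[i, paste0("step_", a)] <- r["ad1"]
      acc[i, paste0("stride_", a)] <- r["ad2"]
    }
    gsi_p[i] <- gait_symmetry_index(seg, mst, fs)
  }
  for (a in axes4) {
    out[paste0("reg_step_", a, "_pass")] <-
      mean(acc[, paste0("step_", a)], na.rm = TRUE)
    out[paste0("reg_stride_", a, "_pass")] <-
      mean(acc[, paste0("stride_", a)], na.rm = TRUE)
  }
  out["reg_gsi_bout"] <- gait_symmetry_index(rec$samples, mst, fs)
  out["reg_gsi_pass"] <- mean(gsi_p, na.rm = TRUE)
  out
}
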