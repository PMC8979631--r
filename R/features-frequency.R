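# Frequency domain: 56 characteristics from the Welch power spectral
# density (dominant-peak geometry and total power), the harmonic ratio
# and the index of harmonicity.  Peak features are computed on the
# whole bout and averaged across passes; harmonic ratio and index of
# harmonicity at pass and stride level.

frequency_feature_names <- function() {
  axes4 <- c("vt", "ml", "ap", "res")
  peak <- c("freq", "amp", "width", "slope", "range")
  c(as.vector(outer(peak, axes4, function(m, a)
      paste0("frq_peak_", m, "_", a, "_bout"))),
    as.vector(outer(peak, axes4, function(m, a)
      paste0("frq_peak_", m, "_", a, "_pass"))),
    paste0("frq_hr_", c("vt", "ml", "ap"), "_pass"),
    paste0("frq_hr_", c("vt", "ml", "ap"), "_stride"),
    paste0("frq_ih_", c("vt", "ml", "ap"), "_pass"),
    paste0("frq_ih_", c("vt", "ml", "ap"), "_stride"),
    paste0("frq_total_power_", axes4))
}

#' Dominant-peak features of the power spectral density
#'
#' Estimates the Welch PSD (Hann window, 3 s segments, 50% overlap,
#' linear detrend) and characterizes the dominant peak in the locomotor
#' band 0.3-5 Hz: its frequency and amplitude, the half-power width,
#' the rising slope from the left half-power bound, and the local range
#' (peak minus minimum PSD within +/- 0.5 Hz).
#'
#' @param x Numeric signal (>= 3 s recommended).
#' @param fs Sampling frequency (Hz).
#' @param band Search band in Hz.
#' @return Named vector `freq`, `amp`, `width`, `slope`, `range`
#'   (all `NA` for an all-zero signal).
#' @export
psd_peak_features <- function(x, fs, band = c(0.3, 5)) {
  out <- c(freq = NA_real_, amp = NA_real_, width = NA_real_,
           slope = NA_real_, range = NA_real_)
  if (all(abs(x - mean(x)) < 1e-12)) {
    message("all-zero signal: PSD peak features missing")
    return(out)
  }
  w <- welch_psd(x, fs)
  sel <- which(w$freq >= band[1] & w$freq <= band[2])
  psd <- w$psd[sel]; freq <- w$freq[sel]
  df <- freq[2] - freq[1]
  ipk <- which.max(psd)
  # parabolic refinement of the peak vertex through the three top bins
  fpk <- freq[ipk]; amp <- psd[ipk]
  if (ipk > 1 && ipk < length(psd)) {
    y1 <- psd[ipk - 1]; y2 <- psd[ipk]; y3 <- psd[ipk + 1]
    den <- y1 - 2 * y2 + y3
    if (den < 0) {
      d <- 0.5 * (y1 - y3) / den
      fpk <- freq[ipk] + d * df
      amp <- y2 - 0.25 * (y1 - y3) * d
    }
  }
  half <- amp / 2
  # half-power bounds, interpolated linearly between bins
  il <- ipk
  while (il > 1 && psd[il - 1] >= half) il <- il - 1
  f_left <- if (il > 1)
    freq[il] - df * (psd[il] - half) / (psd[il] - psd[il - 1])
  else freq[1]
  ir <- ipk
  while (ir < length(psd) && psd[ir + 1] >= half) ir <- ir + 1
  f_right <- if (ir < length(psd))
    freq[ir] + df * (psd[ir] - half) / (psd[ir] - psd[ir + 1])
  else freq[length(freq)]
  width <- max(f_right - f_left, 1e-6)
  slope <- if (fpk > f_left) (amp - half) / (fpk - f_left) else amp / df
  nb <- which(abs(freq - fpk) <= 0.5)
  out[] <- c(fpk, amp, width, slope, amp - min(psd[nb]))
  out
}

#' Harmonic ratio of a gait acceleration segment
#'
#' Finite Fourier amplitudes are taken at harmonics 1..20 of the stride
#' frequency.  For the step-periodic axes (VT, AP) the ratio is the sum
#' of even-harmonic amplitudes over the sum of odd ones; for ML (stride
#' periodic) the ratio is inverted.  A higher ratio means smoother,
#' more rhythmic gait.
#'
#' @param segment Numeric acceleration segment spanning an integer
#'   number of strides.
#' @param axis `"vt"`, `"ml"` or `"ap"`.
#' @param stride_frequency Stride frequency (Hz), e.g. from the mean
#'   stride time.
#' @param fs Sampling frequency (Hz).
#' @param n_harmonics Number of stride harmonics (default 20).
#' @param cap Upper cap for the ratio (default 1e6).
#' @return Non-negative scalar.
#' @export
harmonic_ratio <- function(segment, axis, stride_frequency, fs,
                           n_harmonics = 20, cap = 1e6) {
  axis <- match.arg(axis, c("vt", "ml", "ap"))
  nmax <- floor((fs / 2) / stride_frequency)
  if (nmax < n_harmonics) {
    message("only ", nmax, " resolvable stride harmonics; using ",
            2 * floor(nmax / 2))
    n_harmonics <- 2 * floor(nmax / 2)
  }
  h <- seq_len(n_harmonics)
  amps <- fourier_amplitude(segment, fs, h * stride_frequency)
  hr_from_amplitudes(amps, axis, cap)
}

# even/odd amplitude ratio from stride-harmonic amplitudes 1..H
hr_from_amplitudes <- function(amps, axis, cap = 1e6) {
  h <- seq_along(amps)
  even <- sum(amps[h %% 2 == 0]); odd <- sum(amps[h %% 2 == 1])
  r <- if (axis == "ml") odd / even else even / odd
  if (!is.finite(r) || r > cap) cap else r
}

# index of harmonicity from stride-harmonic amplitudes 1..H: power at
# the fundamental (stride harmonic 1 for ML, 2 for VT/AP) over the
# cumulative power of its first six harmonics
ih_from_amplitudes <- function(amps, axis) {
  idx <- if (axis == "ml") 1:6 else 2 * (1:6)
  idx <- idx[idx <= length(amps)]
  pw <- amps[idx]^2
  tot <- sum(pw)
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  pw[1] / tot
}

#' Index of harmonicity
#'
#' Power at the fundamental frequency divided by the cumulative power
#' of the first six harmonics of that fundamental; 1 for a perfectly
#' harmonic (single-tone) signal.  The fundamental is the stride
#' frequency for ML and the step frequency (twice the stride frequency)
#' for VT and AP.
#'
#' @inheritParams harmonic_ratio
#' @return Scalar in \[0, 1\], `NA` if the cumulative power is zero.
#' @export
index_of_harmonicity <- function(segment, axis, stride_frequency, fs) {
  axis <- match.arg(axis, c("vt", "ml", "ap"))
  f0 <- if (axis == "ml") stride_frequency else 2 * stride_frequency
  k <- 1:6
  usable <- k * f0 < fs / 2
  amps <- fourier_amplitude(segment, fs, k[usable] * f0)
  pw <- amps^2
  tot <- sum(pw)
  if (tot <= 0) return(NA_real_)
  pw[1] / tot
}

#' Frequency-domain feature vector (56 characteristics)
#'
#' @param rec A preprocessed `gait_recording`.
#' @param ev A `gait_events` object.
#' @return Named numeric vector of length 56 (prefix `frq_`).
#' @export
frequency_vector <- function(rec, ev) {
  nm <- frequency_feature_names()
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  fs <- rec$fs
  tp <- temporal_params(ev)
  stride_freq <- 1 / mean(tp$strides$stride_time, na.rm = TRUE)
  axes4 <- c("vt", "ml", "ap", "res")
  sig_bout <- axis_signals(rec$samples)
  pass_segs <- segment(rec, ev, "pass")
  stride_segs <- segment(rec, ev, "stride")

  # dominant-peak features: whole bout
  for (a in axes4) {
    pf <- psd_peak_features(sig_bout[[a]], fs)
    out[paste0("frq_peak_", names(pf), "_", a, "_bout")] <- pf
  }
  # dominant-peak features: averaged across passes
  for (a in axes4) {
    mat <- sapply(seq_len(nrow(pass_segs)), function(i) {
      seg <- segment_samples(rec, pass_segs$start_idx[i], pass_segs$end_idx[i])
      psd_peak_features(axis_signals(seg)[[a]], fs)
    })
    pf <- rowMeans(mat, na.rm = TRUE)
    out[paste0("frq_peak_", names(pf), "_", a, "_pass")] <- pf
  }
  # harmonic ratio and index of harmonicity at pass and stride level;
  # both derive from one set of stride-harmonic Fourier amplitudes
  hr_ih <- function(seg_df) {
    acc <- array(NA_real_, c(nrow(seg_df), 3, 2),
                 dimnames = list(NULL, c("vt", "ml", "ap"), c("hr", "ih")))
    for (i in seq_len(nrow(seg_df))) {
      block <- segment_samples(rec, seg_df$start_idx[i], seg_df$end_idx[i])
      f0 <- if (seg_df$level[1] == "stride")
        fs / (seg_df$end_idx[i] - seg_df$start_idx[i]) else stride_freq
      for (a in c("vt", "ml", "ap")) {
        amps <- fourier_amplitude(block[, a], fs, (1:20) * f0)
        acc[i, a, "hr"] <- hr_from_amplitudes(amps, a)
        acc[i, a, "ih"] <- ih_from_amplitudes(amps, a)
      }
    }
    acc
  }
  hp <- hr_ih(pass_segs); hs <- hr_ih(stride_segs)
  for (a in c("vt", "ml", "ap")) {
    out[paste0("frq_hr_", a, "_pass")] <- mean(hp[, a, "hr"], na.rm = TRUE)
    out[paste0("frq_hr_", a, "_stride")] <- mean(hs[, a, "hr"], na.rm = TRUE)
    out[paste0("frq_ih_", a, "_pass")] <- mean(hp[, a, "ih"], na.rm = TRUE)
    out[paste0("frq_ih_", a, "_stride")] <- mean(hs[, a, "ih"], na.rm = TRUE)
  }
  # total power per axis = integral of the Welch PSD
  for (a in axes4) {
    w <- welch_psd(sig_bout[[a]], fs)
    out[paste0("frq_total_power_", a)] <- trapz_int(w$freq, w$psd)
  }
  out
}

# per-axis signals incl. the resultant (norm of the mean-removed axes)
axis_signals <- function(samples) {
  ctr <- sweep(samples, 2, colMeans(samples))
  list(vt = ctr[, "vt"], ml = ctr[, "ml"], ap = ctr[, "ap"],
       res = sqrt(rowSums(ctr^2)))
}
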