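# Preprocessing and event-based segmentation of lumbar recordings.
#
# All feature extractors operate on preprocessed recordings: tilt is
# corrected so the mean acceleration vector is purely vertical, the
# gravity constant is removed from VT, and a 4th-order zero-phase
# low-pass Butterworth at 20 Hz suppresses out-of-band noise.
# Sample indices follow the half-open 0-based convention [start, end).

#' Preprocess a raw lumbar recording
#'
#' Applies, in order: (i) tilt correction, rotating the signal so the
#' mean acceleration vector over the recording points along VT;
#' (ii) removal of the gravity constant (the mean vector magnitude) from
#' VT; (iii) a 4th-order zero-phase low-pass Butterworth filter with a
#' 20 Hz cut-off on all axes.  The input is not modified.
#'
#' @param rec A `gait_recording`.
#' @param lowpass_hz Low-pass cut-off (Hz).
#' @return A new `gait_recording` with attribute `preprocessed = TRUE`.
#' @export
preprocess <- function(rec, lowpass_hz = 20) {
  stopifnot(inherits(rec, "gait_recording"))
  if (rec$fs < 50) stop("sampling frequency must be >= 50 Hz")
  if (rec$duration < 1) stop("recording shorter than 1 s")
  x <- rec$samples
  m <- colMeans(x)
  gmag <- sqrt(sum(m^2))
  # tilt-correct and de-gravitate only when the mean vector is
  # gravity-like; an already-corrected signal has a near-zero mean and
  # must not be rotated onto an arbitrary axis
  if (gmag > 4) {
    target <- c(1, 0, 0)
    u <- m / gmag
    axis <- c(u[2] * target[3] - u[3] * target[2],
              u[3] * target[1] - u[1] * target[3],
              u[1] * target[2] - u[2] * target[1])
    sin_a <- sqrt(sum(axis^2))
    cos_a <- sum(u * target)
    if (sin_a > 1e-12) {
      R <- rotation_matrix(axis / sin_a, atan2(sin_a, cos_a))
      x <- x %*% t(R)
    } else if (cos_a < 0) {
      x <- x %*% diag(c(-1, -1, 1))    # antiparallel: flip VT and ML
    }
    x[, 1] <- x[, 1] - gmag
  }
  bf <- signal::butter(4, lowpass_hz / (rec$fs / 2), type = "low")
  for (j in 1:3) x[, j] <- signal::filtfilt(bf, x[, j])
  colnames(x) <- c("vt", "ml", "ap")
  out <- rec
  out$samples <- x
  attr(out, "preprocessed") <- TRUE
  out
}

# map event times (s) to 0-based sample indices by rounding
time_to_index <- function(t, fs) as.integer(round(t * fs))

#' Segment a recording into passes, strides or steps
#'
#' Slices a recording into half-open 0-based sample intervals
#' `[start_idx, end_idx)` from heel-strike annotations.  A step runs
#' from a heel strike to the next contralateral heel strike; a stride to
#' the next ipsilateral heel strike.  Only events inside annotated
#' passes are used; passes with fewer than `min_heel_strikes` heel
#' strikes are dropped with a warning.
#'
#' @param rec A `gait_recording`.
#' @param ev A `gait_events` object.
#' @param level `"pass"`, `"stride"` or `"step"`.
#' @param min_heel_strikes Minimum heel strikes a pass must contain
#'   (default 4, the weakest rule yielding one stride per foot).
#' @return A data frame with columns `level`, `start_idx`, `end_idx`,
#'   `foot` (`"L"`, `"R"` or `NA` for passes) and `pass` (1-based pass
#'   number).
#' @export
segment <- function(rec, ev, level = c("pass", "stride", "step"),
                    min_heel_strikes = 4) {
  level <- match.arg(level)
  stopifnot(inherits(rec, "gait_recording"), inherits(ev, "gait_events"))
  fs <- rec$fs
  n <- nrow(rec$samples)
  all_t <- c(ev$heel_strikes$time, ev$toe_offs$time,
             ev$passes$start, ev$passes$end)
  bad <- all_t[all_t < 0 | time_to_index(all_t, fs) > n]
  if (length(bad))
    stop("events outside recording at t = ",
         paste(sprintf("%.3f", utils::head(bad, 5)), collapse = ", "), " s")

  out <- list()
  for (p in seq_len(nrow(ev$passes))) {
    p0 <- ev$passes$start[p]; p1 <- ev$passes$end[p]
    in_pass <- ev$heel_strikes$time >= p0 - 1e-9 &
      ev$heel_strikes$time <= p1 + 1e-9
    hs <- ev$heel_strikes[in_pass, , drop = FALSE]
    hs <- hs[order(hs$time), , drop = FALSE]
    if (nrow(hs) < min_heel_strikes) {
      warning(sprintf("pass %d has %d heel strikes (< %d): dropped",
                      p, nrow(hs), min_heel_strikes))
      next
    }
    idx <- time_to_index(hs$time, fs)
    if (level == "pass") {
      out[[length(out) + 1]] <- data.frame(
        level = "pass", start_idx = idx[1], end_idx = idx[length(idx)],
        foot = NA_character_, pass = p, stringsAsFactors = FALSE)
    } else if (level == "step") {
      k <- seq_len(nrow(hs) - 1)
      out[[length(out) + 1]] <- data.frame(
        level = "step", start_idx = idx[k], end_idx = idx[k + 1],
        foot = hs$foot[k], pass = p, stringsAsFactors = FALSE)
    } else {
      # stride: heel strike to next ipsilateral heel strike
      rows <- list()
      for (k in seq_len(nrow(hs) - 1)) {
        j <- which(hs$foot[(k + 1):nrow(hs)] == hs$foot[k])
        if (!length(j)) next
        j <- k + j[1]
        rows[[length(rows) + 1]] <- data.frame(
          level = "stride", start_idx = idx[k], end_idx = idx[j],
          foot = hs$foot[k], pass = p, stringsAsFactors = FALSE)
      }
      if (length(rows)) out[[length(out) + 1]] <- do.call(rbind, rows)
    }
  }
  if (!length(out))
    return(data.frame(level = character(), start_idx = integer(),
                      end_idx = integer(), foot = character(),
                      pass = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[res$end_idx > res$start_idx, , drop = FALSE]
}

# extract the sample block of a 0-based half-open segment
segment_samples <- function(rec, start_idx, end_idx) {
  rec$samples[(start_idx + 1):end_idx, , drop = FALSE]
}

#' Export segments to CSV
#'
#' @param segments Data frame from [segment()].
#' @param subject_id Subject identifier added as a column.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, subject_id, path) {
  out <- cbind(subject_id = subject_id, segments)
  data.table::fwrite(out, path)
  invisible(path)
}
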