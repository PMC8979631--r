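# Spatiotemporal domain: 25 characteristics built from gait-event
# timings plus inverted-pendulum step lengths from the vertical
# acceleration.  Variability (SD) features pool both feet; asymmetry is
# |mean(left) - mean(right)|; CVs are 100 * SD / mean.

spatiotemporal_feature_names <- function() {
  base5 <- c("step_time", "stance_time", "swing_time", "step_length",
             "step_velocity")
  c(paste0("st_", base5, "_mean"),
    paste0("st_", base5, "_sd"),
    paste0("st_", c("step_time", "stance_time", "swing_time",
                    "step_length"), "_asym"),
    "st_cadence",
    paste0("st_", c("stride_time", "stride_length", "stride_velocity"),
           "_mean"),
    paste0("st_", c("stride_time", "stride_length"), "_sd"),
    paste0("st_", c("step_time", "step_length", "step_velocity",
                    "stride_time", "stride_length"), "_cv"))
}

#' Per-step and per-stride timing table from gait events
#'
#' Step time is the interval between consecutive (alternating-foot)
#' heel strikes within a pass; stride time the interval between
#' ipsilateral heel strikes; stance time runs from a heel strike to the
#' next ipsilateral toe-off and swing time is stride minus stance.
#' Intervals crossing pass boundaries are excluded.
#'
#' @param ev A `gait_events` object.
#' @return List with data frames `steps` (`time`, `foot`, `pass`,
#'   `step_time`) and `strides` (`time`, `foot`, `pass`, `stride_time`,
#'   `stance_time`, `swing_time`; stance/swing are `NA` when the
#'   toe-off is missing).
#' @export
temporal_params <- function(ev) {
  stopifnot(inherits(ev, "gait_events"))
  if (nrow(ev$heel_strikes) < 2)
    stop("need at least two heel strikes")
  steps <- list(); strides <- list()
  for (p in seq_len(nrow(ev$passes))) {
    p0 <- ev$passes$start[p]; p1 <- ev$passes$end[p]
    hs <- ev$heel_strikes[ev$heel_strikes$time >= p0 - 1e-9 &
                            ev$heel_strikes$time <= p1 + 1e-9, ]
    hs <- hs[order(hs$time), ]
    if (nrow(hs) < 2) next
    k <- seq_len(nrow(hs) - 1)
    steps[[p]] <- data.frame(
      time = hs$time[k], foot = hs$foot[k], pass = p,
      step_time = diff(hs$time))
    to <- ev$toe_offs[ev$toe_offs$time >= p0 - 1e-9 &
                        ev$toe_offs$time <= p1 + 1e-9, ]
    rows <- list()
    for (k in seq_len(nrow(hs) - 1)) {
      j <- which(hs$foot[(k + 1):nrow(hs)] == hs$foot[k])
      if (!length(j)) next
      j <- k + j[1]
      stride_time <- hs$time[j] - hs$time[k]
      cand <- to$time[to$foot == hs$foot[k] & to$time > hs$time[k] &
                        to$time < hs$time[j]]
      stance <- if (length(cand)) cand[1] - hs$time[k] else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        time = hs$time[k], foot = hs$foot[k], pass = p,
        stride_time = stride_time, stance_time = stance,
        swing_time = stride_time - stance)
    }
    if (length(rows)) strides[[p]] <- do.call(rbind, rows)
  }
  steps <- if (length(steps)) do.call(rbind, steps) else
    data.frame(time = numeric(), foot = character(), pass = integer(),
               step_time = numeric())
  strides <- if (length(strides)) do.call(rbind, strides) else
    data.frame(time = numeric(), foot = character(), pass = integer(),
               stride_time = numeric(), stance_time = numeric(),
               swing_time = numeric())
  if (anyNA(strides$stance_time))
    message(sum(is.na(strides$stance_time)),
            " stride(s) without toe-off: stance/swing set to missing")
  list(steps = steps, strides = strides)
}

#' Inverted-pendulum step length from vertical acceleration
#'
#' Double-integrates the (preprocessed, gravity-free) vertical
#' acceleration of one step, removing integration drift with a 0.1 Hz
#' 4th-order zero-phase high-pass after each integration (linear
#' detrending on segments too short to filter), and converts the
#' peak-to-peak vertical excursion `h` of the sensor to a step length
#' via the inverted-pendulum chord `L = 2 * sqrt(2 * l * h - h^2)` with
#' `l` the sensor height.  The empirical 1.25 correction factor of the
#' walkway-calibrated variant is available but off by default.
#'
#' @param vt_segment Vertical acceleration of one step (m/s^2).
#' @param sensor_height Pendulum length `l` in metres.
#' @param fs Sampling frequency (Hz).
#' @param correction Multiplicative calibration factor (default 1).
#' @return Step length in metres, or `NA` (with a message) when the
#'   recovered excursion is not smaller than `l`.
#' @export
step_length_pendulum <- function(vt_segment, sensor_height, fs,
                                 correction = 1) {
  if (!length(vt_segment)) stop("empty segment")
  if (sensor_height <= 0) stop("sensor_height must be positive")
  disp <- integrate_twice(vt_segment, fs)
  h <- max(disp) - min(disp)
  pendulum_length(h, sensor_height, correction)
}

integrate_twice <- function(a, fs) {
  v <- highpass_or_detrend(cumtrapz_int(a, 1 / fs), fs)
  highpass_or_detrend(cumtrapz_int(v, 1 / fs), fs)
}

pendulum_length <- function(h, l, correction = 1) {
  if (is.na(h) || h >= l) {
    message("vertical excursion >= sensor height: step length missing")
    return(NA_real_)
  }
  correction * 2 * sqrt(2 * l * h - h^2)
}

#' Spatiotemporal feature vector (25 characteristics)
#'
#' Means, variabilities (pooled SDs), left/right asymmetries,
#' cadence, stride measures and coefficients of variation of the
#' event-derived gait timings and pendulum step lengths.
#'
#' @param rec A preprocessed `gait_recording`.
#' @param ev A `gait_events` object.
#' @param sensor_height Sensor height above ground (m).
#' @param correction Pendulum calibration factor (default 1).
#' @return Named numeric vector of length 25 (prefix `st_`), or an
#'   all-`NA` vector flagged with attribute `usable = FALSE` when fewer
#'   than two strides per foot are available.
#' @export
spatiotemporal_vector <- function(rec, ev, sensor_height,
                                  correction = 1) {
  nm <- spatiotemporal_feature_names()
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  tp <- temporal_params(ev)
  nL <- sum(tp$strides$foot == "L"); nR <- sum(tp$strides$foot == "R")
  if (nL < 2 || nR < 2) {
    attr(out, "usable") <- FALSE
    return(out)
  }
  fs <- rec$fs
  # per-step lengths from the pendulum model: integrate the vertical
  # displacement within each (turn-free) pass, then take per-step
  # excursions; windows are padded slightly so boundary extrema of the
  # displacement cycle are not clipped by sample rounding
  step_segs <- segment(rec, ev, "step")
  pass_segs <- segment(rec, ev, "pass")
  step_len <- rep(NA_real_, nrow(step_segs))
  for (i in seq_len(nrow(pass_segs))) {
    vt <- rec$samples[(pass_segs$start_idx[i] + 1):pass_segs$end_idx[i], "vt"]
    disp <- integrate_twice(vt, fs)
    for (k in which(step_segs$pass == pass_segs$pass[i])) {
      pad <- max(1L, round(0.05 * (step_segs$end_idx[k] - step_segs$start_idx[k])))
      lo <- max(1L, step_segs$start_idx[k] + 1L - pad - pass_segs$start_idx[i])
      hi <- min(length(disp), step_segs$end_idx[k] + pad - pass_segs$start_idx[i])
      h <- max(disp[lo:hi]) - min(disp[lo:hi])
      if (h < sensor_height)
        step_len[k] <- correction * 2 * sqrt(2 * sensor_height * h - h^2)
    }
  }
  # timings come from the exact event times; the sample-rounded
  # segment windows serve only to slice the displacement signal
  stopifnot(nrow(tp$steps) == nrow(step_segs))
  step_time <- tp$steps$step_time
  step_foot <- tp$steps$foot
  step_vel <- step_len / step_time

  # stride length = sum of its two component (adjacent, same-pass) steps
  stride_time <- tp$strides$stride_time
  stride_len <- rep(NA_real_, nrow(tp$strides))
  for (p in unique(tp$steps$pass)) {
    sidx <- which(tp$steps$pass == p)
    ridx <- which(tp$strides$pass == p)
    for (j in seq_along(ridx)) {
      if (j + 1 <= length(sidx))
        stride_len[ridx[j]] <- step_len[sidx[j]] + step_len[sidx[j + 1]]
    }
  }
  stride_vel <- stride_len / stride_time

  st <- tp$strides
  m <- function(v) mean(v, na.rm = TRUE)
  s <- function(v) stats::sd(v, na.rm = TRUE)
  asym <- function(v, foot) abs(m(v[foot == "L"]) - m(v[foot == "R"]))
  cv <- function(v) 100 * s(v) / m(v)

  out["st_step_time_mean"] <- m(step_time)
  out["st_stance_time_mean"] <- m(st$stance_time)
  out["st_swing_time_mean"] <- m(st$swing_time)
  out["st_step_length_mean"] <- m(step_len)
  out["st_step_velocity_mean"] <- m(step_vel)
  out["st_step_time_sd"] <- s(step_time)
  out["st_stance_time_sd"] <- s(st$stance_time)
  out["st_swing_time_sd"] <- s(st$swing_time)
  out["st_step_length_sd"] <- s(step_len)
  out["st_step_velocity_sd"] <- s(step_vel)
  out["st_step_time_asym"] <- asym(step_time, step_foot)
  out["st_stance_time_asym"] <- asym(st$stance_time, st$foot)
  out["st_swing_time_asym"] <- asym(st$swing_time, st$foot)
  out["st_step_length_asym"] <- asym(step_len, step_foot)
  out["st_cadence"] <- 60 / m(step_time)
  out["st_stride_time_mean"] <- m(stride_time)
  out["st_stride_length_mean"] <- m(stride_len)
  out["st_stride_velocity_mean"] <- m(stride_vel)
  out["st_stride_time_sd"] <- s(stride_time)
  out["st_stride_length_sd"] <- s(stride_len)
  out["st_step_time_cv"] <- cv(step_time)
  out["st_step_length_cv"] <- cv(step_len)
  out["st_step_velocity_cv"] <- cv(step_vel)
  out["st_stride_time_cv"] <- cv(stride_time)
  out["st_stride_length_cv"] <- cv(stride_len)
  attr(out, "usable") <- TRUE
  out
}
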