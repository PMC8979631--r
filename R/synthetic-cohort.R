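# Synthetic lumbar-accelerometry cohort generator.
#
# One "subject" is a ~2-minute walk over an oval circuit with repeated
# straight passes over an instrumented mat; the straight passes carry
# gait-event annotations (heel strikes, toe offs) and everything between
# passes is a turn, never analysed.  The gait signal itself is a jittered
# harmonic series on the stride cycle: VT and AP carry even stride
# harmonics (step-frequency dominated), ML carries odd stride harmonics,
# so the generated data has exactly the periodicity/symmetry/harmonic
# structure the downstream feature battery measures, with known ground
# truth.

GRAVITY <- 9.80665

#' Parameters of one synthetic walking subject
#'
#' Bundles the gait-model parameters used by [generate_subject()].  The
#' signal model is a per-axis harmonic series on the stride cycle with
#' per-step timing jitter, per-step amplitude jitter, left/right
#' asymmetry scaling and additive white sensor noise; constant gravity is
#' added to the vertical (VT) axis.
#'
#' @param group `"CL"` (control) or `"PD"`.
#' @param stride_frequency Stride (full gait cycle) frequency in Hz; must
#'   lie in (0.5, 1.5).  Step frequency is twice this.
#' @param step_length Nominal step length in metres; drives the dominant
#'   VT harmonic amplitude through the inverted-pendulum relation.
#' @param sensor_height Height of the lumbar sensor above ground in
#'   metres (the inverted-pendulum leg length).  `NULL` derives it as
#'   0.53 x body height from the sampled demographics.
#' @param axis_amplitudes Named list with numeric vectors `vt`, `ml`,
#'   `ap` of harmonic amplitudes (m/s^2, >= 4 per axis).  VT/AP entries
#'   are amplitudes of even stride harmonics (2, 4, 6, ...), ML entries
#'   of odd stride harmonics (1, 3, 5, ...).  `NULL` derives defaults
#'   from `step_length` and `sensor_height`.
#' @param step_time_jitter_sd SD of per-step duration jitter (s).
#' @param amplitude_jitter_cv Coefficient of variation of the per-step
#'   amplitude scaling (unitless).
#' @param noise_sd SD of additive white sensor noise (m/s^2).
#' @param asymmetry_factor Left/right amplitude asymmetry in \[0, 1\];
#'   0 is perfectly symmetric gait.  Left steps are scaled by
#'   `1 - asymmetry_factor / 2`, right steps by `1 + asymmetry_factor / 2`.
#' @param tilt_deg Static sensor tilt about a horizontal axis (degrees);
#'   the preprocessing stage is expected to undo it.
#' @param n_passes Number of straight mat passes (>= 2).
#' @param steps_per_pass Number of steps (heel-strike intervals) per
#'   pass; must be even so every pass starts on the left foot.
#' @param duration Optional target recording duration (s).  When given it
#'   overrides `n_passes` with as many passes as fit; an error names the
#'   minimum duration if fewer than two passes fit.
#' @param fs Sampling frequency in Hz (default 100, emulating a lumbar
#'   inertial sensor with a +/- 8 g range).
#' @param seed Integer seed; fixes the subject completely.
#'
#' @return An object of class `subject_params` (a named list).
#' @export
subject_params <- function(group = c("CL", "PD"),
                           stride_frequency = 0.92,
                           step_length = 0.66,
                           sensor_height = NULL,
                           axis_amplitudes = NULL,
                           step_time_jitter_sd = 0.012,
                           amplitude_jitter_cv = 0.05,
                           noise_sd = 0.15,
                           asymmetry_factor = 0.04,
                           tilt_deg = 0,
                           n_passes = 6,
                           steps_per_pass = 8,
                           duration = NULL,
                           fs = 100,
                           seed = 1L) {
  group <- match.arg(group)
  if (!(stride_frequency > 0.5 && stride_frequency < 1.5))
    stop("stride_frequency must lie in (0.5, 1.5) Hz, got ", stride_frequency)
  if (step_length <= 0) stop("step_length must be positive")
  if (!is.null(sensor_height) && sensor_height <= 0)
    stop("sensor_height must be positive")
  if (!is.null(axis_amplitudes)) {
    stopifnot(all(c("vt", "ml", "ap") %in% names(axis_amplitudes)))
    for (ax in c("vt", "ml", "ap")) {
      a <- axis_amplitudes[[ax]]
      if (length(a) < 4 || any(a < 0))
        stop("axis_amplitudes$", ax, " needs >= 4 non-negative harmonics")
    }
  }
  if (step_time_jitter_sd < 0 || noise_sd < 0 || amplitude_jitter_cv < 0)
    stop("jitter and noise SDs must be non-negative")
  if (asymmetry_factor < 0 || asymmetry_factor > 1)
    stop("asymmetry_factor must lie in [0, 1]")
  if (steps_per_pass %% 2 != 0 || steps_per_pass < 4)
    stop("steps_per_pass must be an even number >= 4")
  if (is.null(duration) && n_passes < 2)
    stop("n_passes must be >= 2")
  structure(list(
    group = group, stride_frequency = stride_frequency,
    step_length = step_length, sensor_height = sensor_height,
    axis_amplitudes = axis_amplitudes,
    step_time_jitter_sd = step_time_jitter_sd,
    amplitude_jitter_cv = amplitude_jitter_cv,
    noise_sd = noise_sd, asymmetry_factor = asymmetry_factor,
    tilt_deg = tilt_deg, n_passes = n_passes,
    steps_per_pass = steps_per_pass, duration = duration,
    fs = fs, seed = as.integer(seed)
  ), class = "subject_params")
}

# default harmonic amplitudes: the first (step-frequency) VT harmonic is
# set so that double integration yields the vertical excursion h that the
# inverted-pendulum formula maps back to step_length.
default_axis_amplitudes <- function(step_length, sensor_height,
                                    stride_frequency) {
  l <- sensor_height
  h <- l - sqrt(l^2 - step_length^2 / 4)
  f_step <- 2 * stride_frequency
  a1 <- h * (2 * pi * f_step)^2 / 2
  list(
    vt = a1 * c(1, 0.22, 0.09, 0.04),
    ml = a1 * 0.45 * c(1, 0.30, 0.12, 0.05),
    ap = a1 * 0.55 * c(1, 0.25, 0.10, 0.04)
  )
}

sample_demographics <- function(group) {
  rtruncnorm1 <- function(mean, sd, lo, hi) {
    for (i in 1:50) {
      x <- stats::rnorm(1, mean, sd)
      if (x >= lo && x <= hi) return(x)
    }
    min(max(mean, lo), hi)
  }
  if (group == "PD") {
    age <- rtruncnorm1(69, 10, 45, 92)
    sex <- if (stats::runif(1) < 0.65) "M" else "F"
    height <- rtruncnorm1(1.67, 0.09, 1.45, 2.00)
    weight <- rtruncnorm1(75, 13, 42, 130)
    moca <- round(rtruncnorm1(25.2, 3.3, 10, 30))
  } else {
    age <- rtruncnorm1(70, 7, 45, 92)
    sex <- if (stats::runif(1) < 0.5) "M" else "F"
    height <- rtruncnorm1(1.70, 0.09, 1.45, 2.00)
    weight <- rtruncnorm1(79, 12, 42, 130)
    moca <- round(rtruncnorm1(27.4, 2.0, 10, 30))
  }
  list(age = age, sex = sex, height = height, weight = weight,
       bmi = weight / height^2, moca = as.integer(moca))
}

# rotation matrix about unit axis u by angle theta (Rodrigues)
rotation_matrix <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Generate one synthetic walking subject
#'
#' Produces a tri-axial lower-back acceleration recording with
#' ground-truth gait events, pass annotations and sampled demographics.
#' See [subject_params()] for the signal model.
#'
#' @param params A [subject_params()] object.
#' @param subject_id Identifier string stored in the recording.
#'
#' @return A list of class `gait_subject` with elements `recording`
#'   (class `gait_recording`: `subject_id`, `fs`, `duration`, `samples`
#'   as a T x 3 matrix with columns `vt`, `ml`, `ap` in m/s^2),
#'   `events` (class `gait_events`: data frames `heel_strikes`,
#'   `toe_offs` with columns `time`, `foot`, and `passes` with `start`,
#'   `end`), `demographics`, and `truth` (per-step ground-truth table
#'   with durations, feet, amplitude scales and step lengths).
#' @export
generate_subject <- function(params, subject_id = "S001") {
  stopifnot(inherits(params, "subject_params"))
  set.seed(params$seed)
  fs <- params$fs
  f0 <- params$stride_frequency
  step_period <- 1 / (2 * f0)

  demo <- sample_demographics(params$group)
  sensor_height <- if (is.null(params$sensor_height))
    0.53 * demo$height else params$sensor_height
  amps <- if (is.null(params$axis_amplitudes))
    default_axis_amplitudes(params$step_length, sensor_height, f0)
  else params$axis_amplitudes

  n_passes <- params$n_passes
  if (!is.null(params$duration)) {
    pass_dur <- params$steps_per_pass * step_period
    unit <- pass_dur + 2.0           # nominal pass + turn
    n_passes <- floor((params$duration - 1 + 2.0) / unit)
    if (n_passes < 2)
      stop(sprintf(
        "duration %.1f s too short for >= 2 passes; need at least %.1f s",
        params$duration, 1 + 2 * unit - 2.0))
  }

  # --- event skeleton -----------------------------------------------------
  lead <- 0.5
  cursor <- lead
  steps <- list()           # per-step bookkeeping
  passes <- matrix(NA_real_, n_passes, 2)
  turn_spans <- list()
  for (p in seq_len(n_passes)) {
    passes[p, 1] <- cursor
    for (k in seq_len(params$steps_per_pass)) {
      d <- step_period + stats::rnorm(1, 0, params$step_time_jitter_sd)
      d <- min(max(d, 0.5 * step_period), 1.5 * step_period)
      foot <- if (k %% 2 == 1) "L" else "R"
      sc <- (1 + stats::rnorm(1, 0, params$amplitude_jitter_cv)) *
        (1 + (if (foot == "L") -0.5 else 0.5) * params$asymmetry_factor)
      sc <- max(sc, 0.05)
      steps[[length(steps) + 1]] <- list(
        start = cursor, dur = d, foot = foot, scale = sc, pass = p,
        phase0 = (k - 1) * pi)
      cursor <- cursor + d
    }
    passes[p, 2] <- cursor
    if (p < n_passes) {
      td <- stats::runif(1, 1.5, 2.5)
      turn_spans[[p]] <- c(cursor, cursor + td)
      cursor <- cursor + td
    }
  }
  total_dur <- cursor + 0.5
  n <- floor(total_dur * fs)
  t <- (seq_len(n) - 1) / fs

  vt <- numeric(n); ml <- numeric(n); ap <- numeric(n)

  # --- gait signal inside passes -----------------------------------------
  h_vt <- seq_along(amps$vt) * 2        # even stride harmonics
  h_ap <- seq_along(amps$ap) * 2
  h_ml <- seq_along(amps$ml) * 2 - 1    # odd stride harmonics
  for (s in steps) {
    idx <- which(t >= s$start & t < s$start + s$dur)
    if (!length(idx)) next
    theta <- s$phase0 + pi * (t[idx] - s$start) / s$dur
    vt[idx] <- s$scale * colSums(amps$vt * t(outer(theta, h_vt, function(th, h) cos(h * th))))
    ap[idx] <- s$scale * colSums(amps$ap * t(outer(theta, h_ap, function(th, h) cos(h * th + pi / 4))))
    ml[idx] <- s$scale * colSums(amps$ml * t(outer(theta, h_ml, function(th, h) cos(h * th))))
  }

  # --- gentle oscillation during turns and lead-in/out -------------------
  in_pass <- rep(FALSE, n)
  for (p in seq_len(n_passes))
    in_pass[t >= passes[p, 1] & t < passes[p, 2]] <- TRUE
  idx <- which(!in_pass)
  if (length(idx)) {
    a1 <- amps$vt[1]
    w <- 2 * pi * 0.8 * (2 * f0)
    vt[idx] <- 0.30 * a1 * sin(w * t[idx])
    ml[idx] <- 0.40 * a1 * sin(0.5 * w * t[idx] + 1)
    ap[idx] <- 0.30 * a1 * sin(w * t[idx] + 2)
  }

  # noise + gravity
  vt <- vt + stats::rnorm(n, 0, params$noise_sd) + GRAVITY
  ml <- ml + stats::rnorm(n, 0, params$noise_sd)
  ap <- ap + stats::rnorm(n, 0, params$noise_sd)
  samples <- cbind(vt = vt, ml = ml, ap = ap)

  if (params$tilt_deg != 0) {
    phi <- stats::runif(1, 0, 2 * pi)   # tilt about a random horizontal axis
    R <- rotation_matrix(c(0, cos(phi), sin(phi)), params$tilt_deg * pi / 180)
    samples <- samples %*% t(R)
    colnames(samples) <- c("vt", "ml", "ap")
  }
  lim <- 8 * GRAVITY
  samples[samples > lim] <- lim
  samples[samples < -lim] <- -lim

  # --- events -------------------------------------------------------------
  step_start <- vapply(steps, `[[`, 0, "start")
  step_dur <- vapply(steps, `[[`, 0, "dur")
  step_foot <- vapply(steps, `[[`, "", "foot")
  step_pass <- vapply(steps, `[[`, 0, "pass")
  step_scale <- vapply(steps, `[[`, 0, "scale")

  hs_time <- c(); hs_foot <- c()
  to_time <- c(); to_foot <- c()
  for (p in seq_len(n_passes)) {
    i <- which(step_pass == p)
    hs_time <- c(hs_time, step_start[i], passes[p, 2])
    closing <- if (step_foot[i[length(i)]] == "L") "R" else "L"
    hs_foot <- c(hs_foot, step_foot[i], closing)
    # toe-off of the striking foot ~60% of its stride after heel strike
    for (k in i) {
      stride <- if ((k + 1) %in% i)
        step_dur[k] + step_dur[k + 1]
      else 2 * step_period
      tt <- step_start[k] + 0.6 * stride
      if (tt < passes[p, 2]) {
        to_time <- c(to_time, tt)
        to_foot <- c(to_foot, step_foot[k])
      }
    }
  }
  ord <- order(hs_time)
  events <- structure(list(
    heel_strikes = data.frame(time = hs_time[ord], foot = hs_foot[ord],
                              stringsAsFactors = FALSE),
    toe_offs = data.frame(time = to_time[order(to_time)],
                          foot = to_foot[order(to_time)],
                          stringsAsFactors = FALSE),
    passes = data.frame(start = passes[, 1], end = passes[, 2])
  ), class = "gait_events")

  # ground truth: per-step instantaneous vertical excursion and pendulum length
  h_k <- 2 * amps$vt[1] * step_scale / (2 * pi / step_dur)^2
  len_k <- ifelse(h_k < sensor_height,
                  2 * sqrt(2 * sensor_height * h_k - h_k^2), NA_real_)
  truth <- data.frame(
    start = step_start, duration = step_dur, foot = step_foot,
    pass = step_pass, scale = step_scale, h = h_k, step_length = len_k,
    stringsAsFactors = FALSE)

  recording <- structure(list(
    subject_id = subject_id, fs = fs, duration = n / fs,
    samples = samples), class = "gait_recording")

  demo <- c(list(subject_id = subject_id, group = params$group), demo)
  structure(list(recording = recording, events = events,
                 demographics = demo, truth = truth,
                 sensor_height = sensor_height,
                 axis_amplitudes = amps, params = params),
            class = "gait_subject")
}

#' @export
print.gait_recording <- function(x, ...) {
  cat(sprintf("<gait_recording> %s: %.1f s @ %g Hz (%d samples, VT/ML/AP)\n",
              x$subject_id, x$duration, x$fs, nrow(x$samples)))
  invisible(x)
}

#' @export
print.gait_subject <- function(x, ...) {
  cat(sprintf(
    "<gait_subject> %s [%s]: %.1f s, %d passes, %d heel strikes\n",
    x$recording$subject_id, x$demographics$group, x$recording$duration,
    nrow(x$events$passes), nrow(x$events$heel_strikes)))
  invisible(x)
}

#' Cohort-level simulation configuration
#'
#' Group-level parameter distributions and effect sizes for
#' [simulate_cohort()].  Control (CL) subjects are drawn from the listed
#' means/SDs; PD subjects are shifted by `effect * effect_scale` CL
#' standard deviations on each parameter.  `effect_scale = 0` yields a
#' null cohort with fully exchangeable groups (identical walking
#' protocol in both groups).
#'
#' @param n_pd,n_cl Group sizes (default 81 PD, 61 CL).
#' @param effect_scale Multiplier on all group effects; 1 = planted
#'   effects on, 0 = null cohort.
#' @param means,sds Named CL-group means and SDs for `stride_frequency`,
#'   `step_length`, `step_time_jitter_sd`, `amplitude_scale`,
#'   `amplitude_jitter_cv`, `asymmetry_factor`.
#' @param effects Signed PD shifts in CL-SD units (negative = lower in
#'   PD): defaults plant lower mediolateral/anteroposterior trunk
#'   amplitudes, shorter steps (which lowers vertical dynamics through
#'   the pendulum relation), higher timing and amplitude jitter and
#'   higher asymmetry in PD, with cadence preserved.
#' @param pd_passes,cl_passes Mat passes per group (PD walk slower, so
#'   fewer passes fit the two-minute bout); under `effect_scale = 0`
#'   both groups use `cl_passes`.
#' @param steps_per_pass Steps per pass (even).
#' @param noise_sd In-band motor-noise SD (m/s^2) at the control-mean
#'   step length; per subject it scales with the squared relative step
#'   length (signal-dependent motor noise).
#' @param tilt_sd_deg Static sensor tilt drawn per subject from
#'   N(0, `tilt_sd_deg`) degrees.
#' @param fs Sampling frequency (Hz).
#'
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_pd = 81, n_cl = 61, effect_scale = 1,
                          means = c(stride_frequency = 0.92,
                                    step_length = 0.66,
                                    step_time_jitter_sd = 0.012,
                                    amplitude_scale = 1.0,
                                    amplitude_jitter_cv = 0.05,
                                    asymmetry_factor = 0.04),
                          sds = c(stride_frequency = 0.045,
                                  step_length = 0.05,
                                  step_time_jitter_sd = 0.003,
                                  amplitude_scale = 0.09,
                                  amplitude_jitter_cv = 0.01,
                                  asymmetry_factor = 0.02),
                          effects = c(stride_frequency = 0,
                                      step_length = -0.5,
                                      step_time_jitter_sd = 1.5,
                                      amplitude_scale = -1.5,
                                      amplitude_jitter_cv = 0.8,
                                      asymmetry_factor = 0.8),
                          pd_passes = 5, cl_passes = 6,
                          steps_per_pass = 8,
                          noise_sd = 0.15,
                          tilt_sd_deg = 2, fs = 100) {
  if (n_pd <= 0 || n_cl <= 0) stop("group sizes must be positive")
  keys <- c("stride_frequency", "step_length", "step_time_jitter_sd",
            "amplitude_scale", "amplitude_jitter_cv", "asymmetry_factor")
  stopifnot(all(keys %in% names(means)), all(keys %in% names(sds)),
            all(keys %in% names(effects)))
  structure(list(
    n_pd = n_pd, n_cl = n_cl, effect_scale = effect_scale,
    means = means[keys], sds = sds[keys], effects = effects[keys],
    pd_passes = pd_passes, cl_passes = cl_passes,
    steps_per_pass = steps_per_pass, noise_sd = noise_sd,
    tilt_sd_deg = tilt_sd_deg, fs = fs), class = "cohort_config")
}

rdraw <- function(n, mean, sd, lo, hi) pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)

#' Simulate a full synthetic cohort
#'
#' Draws per-subject gait parameters from the group distributions in a
#' [cohort_config()] and generates every subject with
#' [generate_subject()].  All randomness derives from `seed`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer master seed.
#' @param params_only Return only the per-subject gait parameter draws
#'   and group labels, without synthesizing any signal (fast; useful
#'   for calibration studies of the sampling layer).
#' @return Object of class `gait_cohort`: list with `subjects` (list of
#'   `gait_subject`), `demographics` (data frame), `config`, `seed`.
#'   With `params_only = TRUE`, a list with `draws` and `group`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L,
                            params_only = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  n <- config$n_pd + config$n_cl
  groups <- c(rep("PD", config$n_pd), rep("CL", config$n_cl))
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n)
  m <- config$means; s <- config$sds
  eff <- config$effects * config$effect_scale
  subjects <- vector("list", n)
  ids <- sprintf("%s%03d", ifelse(groups == "PD", "PD", "CL"),
                 c(seq_len(config$n_pd), seq_len(config$n_cl)))
  # per-subject parameter draws (group mean + effect shift for PD)
  draws <- sapply(names(m), function(k) {
    mu <- ifelse(groups == "PD", m[[k]] + eff[[k]] * s[[k]], m[[k]])
    stats::rnorm(n, mu, s[[k]])
  })
  draws[, "stride_frequency"] <- pmin(pmax(draws[, "stride_frequency"], 0.55), 1.45)
  draws[, "step_length"] <- pmin(pmax(draws[, "step_length"], 0.25), 1.0)
  draws[, "step_time_jitter_sd"] <- pmax(draws[, "step_time_jitter_sd"], 0.001)
  draws[, "amplitude_scale"] <- pmax(draws[, "amplitude_scale"], 0.3)
  draws[, "amplitude_jitter_cv"] <- pmax(draws[, "amplitude_jitter_cv"], 0.005)
  draws[, "asymmetry_factor"] <- pmin(pmax(draws[, "asymmetry_factor"], 0), 1)
  if (params_only) return(list(draws = draws, group = groups))
  tilts <- stats::rnorm(n, 0, config$tilt_sd_deg)
  null_cohort <- config$effect_scale == 0
  for (i in seq_len(n)) {
    p <- subject_params(
      group = groups[i],
      stride_frequency = draws[i, "stride_frequency"],
      step_length = draws[i, "step_length"],
      step_time_jitter_sd = draws[i, "step_time_jitter_sd"],
      amplitude_jitter_cv = draws[i, "amplitude_jitter_cv"],
      # signal-dependent motor noise: scales with the vigor of the
      # vertical movement (~ squared relative step length)
      noise_sd = config$noise_sd *
        (draws[i, "step_length"] / config$means[["step_length"]])^2,
      asymmetry_factor = draws[i, "asymmetry_factor"],
      tilt_deg = tilts[i],
      n_passes = if (groups[i] == "PD" && !null_cohort)
        config$pd_passes else config$cl_passes,
      steps_per_pass = config$steps_per_pass,
      fs = config$fs,
      seed = subject_seeds[i])
    subj <- generate_subject(p, subject_id = ids[i])
    # global amplitude multiplier applied post hoc: scale the dynamic
    # (gravity-removed) part of the signal and the ground truth with it
    a <- draws[i, "amplitude_scale"]
    if (abs(a - 1) > 1e-12) {
      subj <- scale_subject_amplitude(subj, a)
    }
    subjects[[i]] <- subj
  }
  demo <- do.call(rbind, lapply(subjects, function(s)
    as.data.frame(s$demographics, stringsAsFactors = FALSE)))
  structure(list(subjects = subjects, demographics = demo,
                 config = config, seed = seed), class = "gait_cohort")
}

# multiply the dynamic trunk-control (ML/AP) part of the signal by `a`
# (gravity untouched); vertical dynamics follow step length through the
# pendulum relation and are left alone, so the ground truth stands
scale_subject_amplitude <- function(subj, a) {
  g <- colMeans(subj$recording$samples)   # gravity direction (incl. tilt)
  sc <- sweep(subj$recording$samples, 2, g)
  sc[, c("ml", "ap")] <- sc[, c("ml", "ap")] * a
  subj$recording$samples <- sweep(sc, 2, g, `+`)
  subj
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %d subjects (%d PD, %d CL), seed %d\n",
              length(x$subjects), sum(x$demographics$group == "PD"),
              sum(x$demographics$group == "CL"), x$seed))
  invisible(x)
}

#' Write a cohort to disk as plain CSV files
#'
#' Layout: per subject `<id>_accel.csv` (time_s, vt, ml, ap),
#' `<id>_events.csv` (time_s, event_type HS/TO, foot L/R),
#' `<id>_passes.csv` (start_s, end_s); cohort-level `demographics.csv`
#' and `manifest.json` (config echo plus seeds).
#'
#' @param cohort A `gait_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gait_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    id <- s$recording$subject_id
    fs <- s$recording$fs
    acc <- data.table::data.table(
      time_s = round((seq_len(nrow(s$recording$samples)) - 1) / fs, 6),
      vt = s$recording$samples[, "vt"],
      ml = s$recording$samples[, "ml"],
      ap = s$recording$samples[, "ap"])
    data.table::fwrite(acc, file.path(dir, paste0(id, "_accel.csv")))
    ev <- rbind(
      data.frame(time_s = s$events$heel_strikes$time, event_type = "HS",
                 foot = s$events$heel_strikes$foot),
      data.frame(time_s = s$events$toe_offs$time, event_type = "TO",
                 foot = s$events$toe_offs$foot))
    ev <- ev[order(ev$time_s), ]
    data.table::fwrite(ev, file.path(dir, paste0(id, "_events.csv")))
    data.table::fwrite(
      data.frame(start_s = s$events$passes$start, end_s = s$events$passes$end),
      file.path(dir, paste0(id, "_passes.csv")))
  }
  demo <- cohort$demographics
  names(demo) <- c("subject_id", "group", "age", "sex", "height_m",
                   "weight_kg", "bmi", "moca")
  data.table::fwrite(demo, file.path(dir, "demographics.csv"))
  manifest <- list(
    seed = cohort$seed,
    n_pd = cohort$config$n_pd, n_cl = cohort$config$n_cl,
    effect_scale = cohort$config$effect_scale,
    fs = cohort$config$fs,
    subject_ids = vapply(cohort$subjects,
                         function(s) s$recording$subject_id, ""),
    sensor_heights = vapply(cohort$subjects,
                            function(s) s$sensor_height, 0),
    config = unclass(cohort$config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort previously written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A `gait_cohort`-like object with `subjects` (each holding a
#'   `gait_recording`, `gait_events`, demographics and sensor height)
#'   and `demographics`.
#' @export
read_cohort <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  demo <- as.data.frame(data.table::fread(file.path(dir, "demographics.csv")))
  subjects <- vector("list", nrow(demo))
  for (i in seq_len(nrow(demo))) {
    id <- demo$subject_id[i]
    acc <- data.table::fread(file.path(dir, paste0(id, "_accel.csv")))
    ev <- as.data.frame(data.table::fread(file.path(dir, paste0(id, "_events.csv"))))
    ps <- as.data.frame(data.table::fread(file.path(dir, paste0(id, "_passes.csv"))))
    samples <- as.matrix(acc[, c("vt", "ml", "ap")])
    fs <- man$fs %||% 100
    recording <- structure(list(
      subject_id = id, fs = fs, duration = nrow(samples) / fs,
      samples = samples), class = "gait_recording")
    hs <- ev[ev$event_type == "HS", ]
    to <- ev[ev$event_type == "TO", ]
    events <- structure(list(
      heel_strikes = data.frame(time = hs$time_s, foot = hs$foot),
      toe_offs = data.frame(time = to$time_s, foot = to$foot),
      passes = data.frame(start = ps$start_s, end = ps$end_s)
    ), class = "gait_events")
    sh <- if (!is.null(man$sensor_heights)) man$sensor_heights[i] else
      0.53 * demo$height_m[i]
    subjects[[i]] <- structure(list(
      recording = recording, events = events,
      demographics = list(subject_id = id, group = demo$group[i],
                          age = demo$age[i], sex = demo$sex[i],
                          height = demo$height_m[i], weight = demo$weight_kg[i],
                          bmi = demo$bmi[i], moca = demo$moca[i]),
      truth = NULL, sensor_height = sh), class = "gait_subject")
  }
  names(demo) <- c("subject_id", "group", "age", "sex", "height",
                   "weight", "bmi", "moca")
  structure(list(subjects = subjects, demographics = demo,
                 config = man$config, seed = man$seed),
            class = "gait_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
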