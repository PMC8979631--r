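test_that("subject generation is deterministic and validates inputs", {
  a <- generate_subject(subject_params(seed = 7))
  b <- generate_subject(subject_params(seed = 7))
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$events, b$events)

  expect_error(subject_params(stride_frequency = 1.6), "stride_frequency")
  expect_error(subject_params(asymmetry_factor = 1.2), "asymmetry_factor")
  expect_error(subject_params(noise_sd = -1), "non-negative")
  expect_error(subject_params(steps_per_pass = 7), "even")
  expect_error(subject_params(n_passes = 1), "n_passes")
  expect_error(
    generate_subject(subject_params(duration = 5)),
    "too short.*minimum|minimum|need at least")
})

test_that("noise/jitter/asymmetry-free gait is perfectly regular", {
  s <- clean_subject(seed = 3)
  rec <- preprocess(s$recording)
  tp <- temporal_params(s$events)
  blk <- pass_block(rec, s$events)
  r <- step_stride_regularity(blk[, "vt"] - mean(blk[, "vt"]),
                              mean(tp$steps$step_time),
                              mean(tp$strides$stride_time), rec$fs)
  expect_equal(unname(r["ad1"]), 1, tolerance = 0.01)
  expect_equal(unname(r["ad2"]), 1, tolerance = 0.01)
})

test_that("dominant spectral peak sits at the step frequency", {
  # independent oracle: raw FFT periodogram of the generated VT signal
  s <- generate_subject(subject_params(
    seed = 5, stride_frequency = 1.0, step_time_jitter_sd = 0,
    noise_sd = 0.05, tilt_deg = 0))
  vt <- s$recording$samples[, "vt"]
  vt <- vt - mean(vt)
  n <- length(vt)
  spec <- Mod(stats::fft(vt)[1:(n %/% 2)])^2
  freq <- (0:(n %/% 2 - 1)) * s$recording$fs / n
  sel <- freq > 0.3 & freq < 5
  expect_equal(freq[sel][which.max(spec[sel])], 2.0, tolerance = 0.05)
})

test_that("event annotations are consistent with the recording", {
  s <- default_subject(seed = 11)
  ev <- s$events
  expect_true(all(ev$passes$start >= 0))
  expect_true(all(ev$passes$end <= s$recording$duration))
  expect_true(all(diff(ev$heel_strikes$time) > 0))
  # step times reconstructed from heel strikes match the ground truth
  for (p in seq_len(nrow(ev$passes))) {
    hs <- ev$heel_strikes$time[
      ev$heel_strikes$time >= ev$passes$start[p] - 1e-9 &
        ev$heel_strikes$time <= ev$passes$end[p] + 1e-9]
    truth <- s$truth$duration[s$truth$pass == p]
    expect_equal(diff(hs), truth, tolerance = 1 / s$recording$fs)
    expect_gte(length(hs), 4)
    # feet alternate within the pass
    feet <- ev$heel_strikes$foot[
      ev$heel_strikes$time >= ev$passes$start[p] - 1e-9 &
        ev$heel_strikes$time <= ev$passes$end[p] + 1e-9]
    expect_true(all(feet[-1] != feet[-length(feet)]))
  }
})

test_that("VT dynamic RMS scales linearly with a global amplitude multiplier", {
  base <- subject_params(seed = 13, noise_sd = 0, tilt_deg = 0)
  s1 <- generate_subject(base)
  amps2 <- lapply(s1$axis_amplitudes, function(a) 2 * a)
  p2 <- subject_params(seed = 13, noise_sd = 0, tilt_deg = 0,
                       axis_amplitudes = amps2)
  s2 <- generate_subject(p2)
  rms <- function(s) {
    vt <- s$recording$samples[, "vt"]
    sqrt(mean((vt - mean(vt))^2))
  }
  expect_equal(rms(s2) / rms(s1), 2, tolerance = 0.02)
})

test_that("stride regularity degrades monotonically with timing jitter", {
  jitters <- c(0.004, 0.015, 0.035)
  ad2_mean <- sapply(jitters, function(j) {
    mean(sapply(1:20, function(sd0) {
      s <- generate_subject(subject_params(
        seed = sd0, step_time_jitter_sd = j, tilt_deg = 0))
      rec <- preprocess(s$recording)
      tp <- temporal_params(s$events)
      blk <- pass_block(rec, s$events)
      step_stride_regularity(
        blk[, "vt"] - mean(blk[, "vt"]),
        mean(tp$steps$step_time), mean(tp$strides$stride_time),
        rec$fs)["ad2"]
    }))
  })
  expect_true(all(diff(ad2_mean) < 0))
})

test_that("cohort simulation respects group sizes, seeds and the null", {
  expect_error(cohort_config(n_pd = 0), "positive")
  co <- simulate_cohort(cohort_config(n_pd = 3, n_cl = 2), seed = 4)
  expect_length(co$subjects, 5)
  expect_equal(sum(co$demographics$group == "PD"), 3)
  co2 <- simulate_cohort(cohort_config(n_pd = 3, n_cl = 2), seed = 4)
  expect_identical(co$subjects[[1]]$recording$samples,
                   co2$subjects[[1]]$recording$samples)
  expect_identical(co$demographics, co2$demographics)

  # null cohort: both groups share the walking protocol
  cn <- simulate_cohort(cohort_config(n_pd = 2, n_cl = 2,
                                      effect_scale = 0), seed = 1)
  expect_equal(nrow(cn$subjects[[1]]$events$passes),
               nrow(cn$subjects[[3]]$events$passes))
})

test_that("null cohorts show chance-level group differences in step velocity", {
  # Monte-Carlo over replicate null cohorts at the parameter level:
  # the two-sample t-test on mean step velocity should reject at ~5%
  cfg <- cohort_config(n_pd = 15, n_cl = 15, effect_scale = 0)
  pvals <- sapply(1:200, function(sd0) {
    d <- simulate_cohort(cfg, seed = sd0, params_only = TRUE)
    vel <- d$draws[, "step_length"] * 2 * d$draws[, "stride_frequency"]
    stats::t.test(vel[d$group == "PD"], vel[d$group == "CL"])$p.value
  })
  expect_gt(mean(pvals < 0.05), 0.01)
  expect_lt(mean(pvals < 0.05), 0.12)
})
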