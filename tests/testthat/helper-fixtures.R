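# Shared fixtures, all generated in code.

# a deterministic, noise/jitter/asymmetry-free subject: perfectly
# periodic gait, useful wherever exact regularity/symmetry is expected
clean_subject <- function(seed = 1, stride_frequency = 0.92, ...) {
  generate_subject(subject_params(
    seed = seed, stride_frequency = stride_frequency,
    step_time_jitter_sd = 0, amplitude_jitter_cv = 0, noise_sd = 0,
    asymmetry_factor = 0, tilt_deg = 0, ...))
}

default_subject <- function(seed = 1, ...) {
  generate_subject(subject_params(seed = seed, ...))
}

# a small cohort plus its feature matrix, built once per test run
small_cohort_cache <- new.env(parent = emptyenv())
small_cohort <- function() {
  if (is.null(small_cohort_cache$cohort)) {
    small_cohort_cache$cohort <-
      simulate_cohort(cohort_config(n_pd = 10, n_cl = 10), seed = 99)
    small_cohort_cache$features <-
      extract_features(small_cohort_cache$cohort, lyap_n_ref = 80)
  }
  list(cohort = small_cohort_cache$cohort,
       features = small_cohort_cache$features)
}

make_recording <- function(samples, fs = 100, id = "T001") {
  colnames(samples) <- c("vt", "ml", "ap")
  structure(list(subject_id = id, fs = fs,
                 duration = nrow(samples) / fs, samples = samples),
            class = "gait_recording")
}

make_events <- function(hs_time, hs_foot, passes,
                        to_time = numeric(), to_foot = character()) {
  structure(list(
    heel_strikes = data.frame(time = hs_time, foot = hs_foot,
                              stringsAsFactors = FALSE),
    toe_offs = data.frame(time = to_time, foot = to_foot,
                          stringsAsFactors = FALSE),
    passes = data.frame(start = passes[, 1], end = passes[, 2])
  ), class = "gait_events")
}

sine_wave <- function(freq, dur, fs = 100, amp = 1, phase = 0)
  amp * sin(2 * pi * freq * (seq_len(round(dur * fs)) - 1) / fs + phase)

# samples of the i-th straight-walk pass of a (preprocessed) recording
pass_block <- function(rec, ev, i = 1) {
  ps <- segment(rec, ev, "pass")
  rec$samples[(ps$start_idx[i] + 1):ps$end_idx[i], , drop = FALSE]
}
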