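test_that("temporal parameters follow the event definitions", {
  ev <- make_events(c(0.0, 0.55, 1.10), c("L", "R", "L"),
                    matrix(c(0.0, 1.10), 1),
                    to_time = 0.70, to_foot = "L")
  tp <- temporal_params(ev)
  expect_equal(tp$steps$step_time, c(0.55, 0.55))
  l <- tp$strides[tp$strides$foot == "L", ]
  expect_equal(l$stride_time, 1.10)
  expect_equal(l$stance_time, 0.70)
  expect_equal(l$swing_time, 0.40)

  single <- make_events(1.0, "L", matrix(c(1.0, 1.0), 1))
  expect_error(temporal_params(single), "two heel strikes")
})

test_that("step-time variability is below one sample for jitter-free gait", {
  s <- clean_subject(seed = 6)
  tp <- temporal_params(s$events)
  expect_lt(stats::sd(tp$steps$step_time), 1 / s$recording$fs)
})

test_that("inverted-pendulum step length matches the closed form", {
  # a(t) = A sin(2 pi f t) integrates to displacement amplitude
  # A / (2 pi f)^2, hence excursion h = 2 A / (2 pi f)^2
  fs <- 100; f <- 1.84; l <- 1.0
  h_target <- 0.02
  A <- h_target * (2 * pi * f)^2 / 2
  n <- round(15 / f * fs)                # fifteen whole periods
  x <- A * sin(2 * pi * f * (0:n) / fs)
  L <- step_length_pendulum(x, sensor_height = l, fs = fs)
  expect_equal(L, 2 * sqrt(2 * l * h_target - h_target^2),
               tolerance = 0.1 * 0.39799)
  expect_equal(2 * sqrt(2 * 1 * 0.02 - 0.02^2), 0.39799,
               tolerance = 1e-4)

  # zero signal: zero excursion, zero length
  expect_equal(step_length_pendulum(numeric(200), 1, fs), 0)
  expect_error(step_length_pendulum(numeric(0), 1, fs), "empty")
  # excursion >= sensor height is unphysical
  big <- 200 * sin(2 * pi * 1 * (0:800) / 100)
  expect_message(val <- step_length_pendulum(big, 0.05, 100), "missing")
  expect_true(is.na(val))
})

test_that("the spatiotemporal vector has 25 coherent characteristics", {
  s <- clean_subject(seed = 8)
  rec <- preprocess(s$recording)
  fv <- spatiotemporal_vector(rec, s$events, s$sensor_height)
  expect_length(fv, 25)
  reg <- feature_registry()
  expect_identical(names(fv), reg$name[reg$domain == "spatiotemporal"])
  # symmetric, jitter-free gait: asymmetries vanish
  asyms <- fv[grep("_asym$", names(fv))]
  means <- fv[c("st_step_time_mean", "st_stance_time_mean",
                "st_swing_time_mean", "st_step_length_mean")]
  expect_true(all(asyms < 1e-3 * abs(means)))
  # cadence identity
  expect_equal(unname(fv["st_cadence"]), 60 / fv[["st_step_time_mean"]],
               tolerance = 1e-6)
  # stance + swing = stride, per stride with complete events
  tp <- temporal_params(s$events)
  ok <- !is.na(tp$strides$stance_time)
  expect_equal(tp$strides$stance_time[ok] + tp$strides$swing_time[ok],
               tp$strides$stride_time[ok], tolerance = 1e-9)
})

test_that("step time and length are recovered across synthetic subjects", {
  err_t <- err_l <- numeric(20)
  for (sd0 in 1:20) {
    s <- default_subject(seed = sd0)
    rec <- preprocess(s$recording)
    fv <- spatiotemporal_vector(rec, s$events, s$sensor_height)
    err_t[sd0] <- abs(fv[["st_step_time_mean"]] - mean(s$truth$duration))
    err_l[sd0] <- abs(fv[["st_step_length_mean"]] -
                        mean(s$truth$step_length)) /
      mean(s$truth$step_length)
  }
  expect_lt(mean(err_t), 1 / 100)
  expect_lt(mean(err_l), 0.15)
})

test_that("time-based CV features ignore the signal amplitude", {
  s <- default_subject(seed = 21, noise_sd = 0)
  rec <- preprocess(s$recording)
  fv1 <- spatiotemporal_vector(rec, s$events, s$sensor_height)
  rec2 <- rec
  rec2$samples <- rec2$samples * 3
  fv2 <- spatiotemporal_vector(rec2, s$events, s$sensor_height)
  expect_equal(fv1[["st_step_time_cv"]], fv2[["st_step_time_cv"]])
  expect_equal(fv1[["st_stride_time_cv"]], fv2[["st_stride_time_cv"]])
  expect_equal(fv1[["st_cadence"]], fv2[["st_cadence"]])
})
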