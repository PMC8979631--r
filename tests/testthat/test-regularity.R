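test_that("unbiased autocorrelation matches the brute-force definition", {
  brute <- function(x, max_lag) {
    x <- x - mean(x)
    n <- length(x)
    a <- sapply(0:max_lag, function(m)
      sum(x[1:(n - m)] * x[(1 + m):n]) / (n - m))
    a / a[1]
  }
  for (sd0 in 1:5) {
    set.seed(sd0)
    x <- rnorm(200)
    expect_equal(unbiased_autocorrelation(x, 100), brute(x, 100),
                 tolerance = 1e-10)
  }
  set.seed(1)
  expect_equal(unbiased_autocorrelation(rnorm(100), 50)[1], 1)
  expect_error(unbiased_autocorrelation(rep(2, 100), 50), "constant")
  expect_error(unbiased_autocorrelation(rnorm(100), 60), "max_lag")
})

test_that("periodic signals have unit autocorrelation at their period", {
  x <- rep(sin(2 * pi * (0:49) / 50) + 0.3 * sin(4 * pi * (0:49) / 50), 20)
  a <- unbiased_autocorrelation(x, 300)
  expect_equal(a[51], 1, tolerance = 0.01)   # lag 50 = one period
})

test_that("step/stride regularity separate symmetric from asymmetric gait", {
  s <- clean_subject(seed = 10)
  rec <- preprocess(s$recording)
  tp <- temporal_params(s$events)
  blk <- pass_block(rec, s$events)
  r <- step_stride_regularity(
    blk[, "vt"] - mean(blk[, "vt"]),
    mean(tp$steps$step_time), mean(tp$strides$stride_time), rec$fs)
  expect_equal(unname(r["ad1"]), 1, tolerance = 0.02)
  expect_equal(unname(r["symmetry"]), 1, tolerance = 0.02)

  # strong left/right asymmetry: steps unlike, strides alike (VT)
  d <- sapply(1:20, function(sd0) {
    s2 <- generate_subject(subject_params(
      seed = sd0, asymmetry_factor = 0.5, noise_sd = 0.05,
      tilt_deg = 0))
    rec2 <- preprocess(s2$recording)
    tp2 <- temporal_params(s2$events)
    blk2 <- pass_block(rec2, s2$events)
    r2 <- step_stride_regularity(
      blk2[, "vt"] - mean(blk2[, "vt"]),
      mean(tp2$steps$step_time), mean(tp2$strides$stride_time), rec2$fs)
    r2[["ad2"]] - r2[["ad1"]]
  })
  expect_gt(mean(d > 0), 0.9)
})

test_that("white noise shows no spurious regularity", {
  set.seed(42)
  vals <- replicate(20, {
    r <- step_stride_regularity(rnorm(2000), 0.5, 1.0, 100)
    max(abs(r[c("ad1", "ad2")]))
  })
  expect_gt(mean(vals < 0.2), 0.95)
})

test_that("regularity features are invariant to positive rescaling", {
  s <- default_subject(seed = 12)
  rec <- preprocess(s$recording)
  fv1 <- regularity_vector(rec, s$events)
  rec2 <- rec; rec2$samples <- rec2$samples * 7.3
  fv2 <- regularity_vector(rec2, s$events)
  expect_equal(fv1, fv2, tolerance = 1e-12)
})

test_that("the gait symmetry index scores symmetric gait near one", {
  s <- clean_subject(seed = 14)
  rec <- preprocess(s$recording)
  tp <- temporal_params(s$events)
  gsi <- gait_symmetry_index(pass_block(rec, s$events),
                             mean(tp$steps$step_time), rec$fs)
  expect_equal(gsi, 1, tolerance = 0.02)

  # identical periodic signal on all three axes: coefficients (1,1,1)
  x <- rep(sin(2 * pi * (0:49) / 50), 20)
  gsi3 <- gait_symmetry_index(cbind(vt = x, ml = x, ap = x), 0.5, 100)
  expect_equal(gsi3, 1, tolerance = 0.01)

  # monotone degradation with asymmetry (5 levels x 10 seeds)
  levels <- c(0, 0.15, 0.3, 0.5, 0.7)
  m <- sapply(levels, function(a) {
    mean(sapply(1:10, function(sd0) {
      s2 <- generate_subject(subject_params(
        seed = sd0, asymmetry_factor = a, noise_sd = 0.05, tilt_deg = 0))
      rec2 <- preprocess(s2$recording)
      tp2 <- temporal_params(s2$events)
      gait_symmetry_index(pass_block(rec2, s2$events),
                          mean(tp2$steps$step_time), rec2$fs)
    }))
  })
  expect_true(all(diff(m) < 0))
})

test_that("the regularity vector has 20 characteristics in registry order", {
  s <- default_subject(seed = 15)
  fv <- regularity_vector(preprocess(s$recording), s$events)
  expect_length(fv, 20)
  reg <- feature_registry()
  expect_identical(names(fv), reg$name[reg$domain == "regularity"])
})
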