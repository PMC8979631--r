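# Monte-Carlo even-odd (ray casting) point-in-polygon area oracle
mc_polygon_area <- function(poly, n = 20000, seed = 1) {
  set.seed(seed)
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  px <- runif(n, xr[1], xr[2]); py <- runif(n, yr[1], yr[2])
  np <- nrow(poly)
  inside <- logical(n)
  j <- np
  for (i in seq_len(np)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    hit <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, hit)
    j <- i
  }
  mean(inside) * diff(xr) * diff(yr)
}

test_that("orbit geometry matches closed forms on circles and ellipses", {
  th <- seq(0, 2 * pi, length.out = 2001)[-1]
  circle <- cbind(cos(th), sin(th))
  g <- orbit_geometry(circle)
  expect_equal(g$area, pi, tolerance = 0.001 * pi)
  ellipse <- cbind(3 * cos(th), 1.2 * sin(th))
  ge <- orbit_geometry(ellipse)
  expect_equal(ge$area, pi * 3 * 1.2, tolerance = 0.001 * pi * 3.6)
  expect_lt(ge$long_asym, 1e-6)
  expect_lt(ge$short_asym, 1e-6)
})

test_that("shoelace area agrees with a Monte-Carlo point-in-polygon oracle", {
  th <- seq(0, 2 * pi, length.out = 400)[-1]
  # convex, slightly squashed orbit
  poly <- cbind(2 * cos(th) + 0.3 * cos(2 * th), sin(th))
  g <- orbit_geometry(poly)
  expect_equal(g$area, mc_polygon_area(poly, n = 2e5), tolerance = 0.01 * g$area)
})

test_that("half-orbit asymmetries are invariant to similarity transforms", {
  th <- seq(0, 2 * pi, length.out = 501)[-1]
  blob <- cbind(2 * cos(th) + 0.4 * cos(2 * th),
                sin(th) + 0.2 * sin(3 * th))
  g0 <- orbit_geometry(blob)
  set.seed(3)
  for (i in 1:5) {
    ang <- runif(1, 0, 2 * pi); sc <- runif(1, 0.2, 5)
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
    moved <- sweep(blob %*% R * sc, 2, runif(2, -3, 3), `+`)
    g1 <- orbit_geometry(moved)
    expect_equal(g1$long_asym, g0$long_asym, tolerance = 1e-6)
    expect_equal(g1$short_asym, g0$short_asym, tolerance = 1e-6)
    expect_equal(g1$area, g0$area * sc^2, tolerance = 1e-6 * g0$area * sc^2)
  }
})

test_that("phase-plot asymmetry grows with left/right gait asymmetry", {
  asym_of <- function(a, sd0) {
    s <- generate_subject(subject_params(
      seed = sd0, asymmetry_factor = a, noise_sd = 0.05, tilt_deg = 0))
    rec <- preprocess(s$recording)
    strides <- segment(rec, s$events, "stride")
    vt <- rec$samples[, "vt"]
    phase_plot_features(vt - mean(vt), strides, rec$fs)[["long_half_asym"]]
  }
  lo <- mean(sapply(1:20, function(i) asym_of(0, i)))
  hi <- mean(sapply(1:20, function(i) asym_of(0.5, i)))
  expect_gt(hi, lo)
})

test_that("a pure sinusoid has a vanishing Lyapunov exponent", {
  x <- sin(2 * pi * 1.84 * (0:5999) / 100)
  lam <- lyapunov_rosenstein(x, 100, theiler_s = 1.09,
                             fit_window_s = 0.54)
  expect_lt(abs(lam), 0.1)   # ~5% of the jittered-gait scale (~2 1/s)
})

test_that("timing jitter raises the gait Lyapunov exponent", {
  lam_of <- function(j, sd0) {
    s <- generate_subject(subject_params(
      seed = sd0, step_time_jitter_sd = j, tilt_deg = 0))
    rec <- preprocess(s$recording)
    vt <- rec$samples[, "vt"]
    lyapunov_rosenstein(vt - mean(vt), rec$fs, theiler_s = 1.09,
                        fit_window_s = 0.54, n_ref = 120)
  }
  lo <- mean(sapply(1:20, function(i) lam_of(0.004, i)))
  hi <- mean(sapply(1:20, function(i) lam_of(0.03, i)))
  expect_gt(hi, lo)
})

test_that("the complexity vector has 25 characteristics in registry order", {
  s <- default_subject(seed = 23)
  fv <- complexity_vector(preprocess(s$recording), s$events, n_ref = 100)
  expect_length(fv, 25)
  reg <- feature_registry()
  expect_identical(names(fv), reg$name[reg$domain == "complexity"])
  asym <- fv[grep("half_asym", names(fv))]
  expect_true(all(asym >= 0 & asym <= 1))
})
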