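make_xy <- function(n = 30, p = 5, effect = 1.5, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("PD", "CL"), length.out = n), levels = c("PD", "CL"))
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  x[y == "PD", 1] <- x[y == "PD", 1] + effect
  list(x = x, y = y)
}

test_that("single-predictor PLS equals univariate least squares", {
  d <- make_xy(n = 24, p = 1)
  fit <- plsda(d$x, d$y, ncomp = 1)
  Y0 <- cbind(PD = as.numeric(d$y == "PD"), CL = as.numeric(d$y == "CL"))
  ols <- stats::lm(Y0 ~ d$x)
  expect_equal(unname(fitted(fit)), unname(fitted(ols)), tolerance = 1e-10)
})

test_that("full-rank PLS converges to ordinary least squares", {
  d <- make_xy(n = 20, p = 5)
  fit <- plsda(d$x, d$y, ncomp = 5)
  Y0 <- cbind(PD = as.numeric(d$y == "PD"), CL = as.numeric(d$y == "CL"))
  ols <- stats::lm(Y0 ~ d$x)
  expect_equal(unname(fitted(fit)), unname(fitted(ols)), tolerance = 1e-8)
})

test_that("NIPALS invariants hold: unit weights, orthogonal scores", {
  d <- make_xy(n = 40, p = 12, seed = 3)
  fit <- plsda(d$x, d$y, ncomp = 4)
  expect_equal(unname(colSums(fit$weights^2)), rep(1, 4), tolerance = 1e-10)
  g <- crossprod(fit$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  # R2 curves nondecreasing and within [0, 1]
  expect_true(all(diff(fit$r2x) >= -1e-12))
  expect_true(all(diff(fit$r2y) >= -1e-12))
  expect_true(all(fit$r2x >= 0 & fit$r2x <= 1 + 1e-12))
})

test_that("prediction reproduces training behavior and guards inputs", {
  d <- make_xy(n = 30, p = 6, seed = 4)
  fit <- plsda(d$x, d$y, ncomp = 3)
  pr <- predict(fit, d$x, type = "score")
  expect_equal(unname(pr), unname(fitted(fit)), tolerance = 1e-10)
  # duplicated row predicts identically
  expect_equal(predict(fit, d$x[c(3, 3), ], type = "score")[1, ],
               predict(fit, d$x[c(3, 3), ], type = "score")[2, ])
  # a row at the training means predicts the class proportions
  mrow <- matrix(colMeans(d$x), 1, dimnames = list(NULL, colnames(d$x)))
  expect_equal(unname(predict(fit, mrow, type = "score")[1, ]),
               as.numeric(table(d$y)[fit$levels]) / length(d$y),
               tolerance = 1e-8)
  # column mismatch errors, listing the difference
  bad <- d$x[, 1:4]
  expect_error(predict(fit, bad), "column mismatch.*f5")
  # zero-variance column errors by name
  xz <- d$x; xz[, 2] <- 1
  expect_error(plsda(xz, d$y), "zero-variance.*f2")
  expect_error(plsda(d$x, d$y, ncomp = 40), "ncomp")
})

test_that("VIP normalization and single-predictor identities hold", {
  d <- make_xy(n = 30, p = 8, seed = 5)
  fit <- plsda(d$x, d$y, ncomp = 3)
  v <- vip(fit)
  for (a in seq_len(3))
    expect_equal(sum(v[[paste0("vip_comp", a)]]^2), 8, tolerance = 1e-8)
  d1 <- make_xy(n = 24, p = 1)
  expect_equal(vip(plsda(d1$x, d1$y, ncomp = 1))$vip_avg, 1)
})

test_that("VIP ranks planted features above noise features", {
  pooled_planted <- c(); pooled_noise <- c()
  for (sd0 in 1:5) {
    set.seed(sd0)
    n <- 60; p <- 30
    y <- factor(rep(c("PD", "CL"), each = n / 2), levels = c("PD", "CL"))
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", 1:p)))
    x[y == "PD", 1:5] <- x[y == "PD", 1:5] + 1
    v <- vip(plsda(x, y, ncomp = 2))
    pooled_planted <- c(pooled_planted, v$vip_avg[1:5])
    pooled_noise <- c(pooled_noise, v$vip_avg[6:p])
  }
  w <- stats::wilcox.test(pooled_planted, pooled_noise,
                          alternative = "greater")
  expect_lt(w$p.value, 0.01)
})

test_that("cross-validated Q2 separates signal from noise", {
  # pure-noise labels: Q2 <= 0 for all components in >90% of runs
  allneg <- replicate(50, {
    set.seed(sample.int(1e6, 1))
    x <- matrix(rnorm(40 * 10), 40)
    y <- factor(rep(c("PD", "CL"), 20), levels = c("PD", "CL"))
    q <- plsda_cv(x[sample(40), ], y, ncomp_max = 3, folds = 5,
                  seed = sample.int(1e6, 1))
    all(q$Q2 <= 0)
  })
  expect_gt(mean(allneg), 0.9)

  # strongly separable groups: Q2 > 0.5 by two components
  d <- make_xy(n = 60, p = 10, effect = 3, seed = 6)
  q <- plsda_cv(d$x, d$y, ncomp_max = 3, folds = 7)
  expect_gt(q$Q2[2], 0.5)
  # R2Y nondecreasing, Q2 bounded by it
  expect_true(all(diff(q$R2Y) >= -1e-12))
  expect_true(all(q$Q2 <= q$R2Y + 1e-6))
})

test_that("component selection follows the Q2 plateau rule", {
  q <- data.frame(component = 1:4, Q2 = c(0.40, 0.55, 0.56, 0.56),
                  R2X = 1:4 / 4, R2Y = 1:4 / 4)
  expect_equal(select_components(q), 2)
  q2 <- data.frame(component = 1:3, Q2 = c(0.2, 0.4, 0.6),
                   R2X = 1:3 / 3, R2Y = 1:3 / 3)
  expect_equal(select_components(q2), 3)
})

test_that("imputation and stratification guards work", {
  d <- make_xy(n = 30, p = 6, seed = 7)
  xna <- d$x; xna[c(2, 9), 3] <- NA
  expect_message(fit <- plsda(xna, d$y, ncomp = 2), "imputing")
  expect_false(anyNA(fitted(fit)))
  expect_error(plsda_cv(d$x, d$y, folds = 1), "folds")
})

test_that("scores agree with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  d <- make_xy(n = 30, p = 8, seed = 8)
  fit <- plsda(d$x, d$y, ncomp = 2)
  Y0 <- cbind(PD = as.numeric(d$y == "PD"), CL = as.numeric(d$y == "CL"))
  ref <- mixOmics::pls(d$x, Y0, ncomp = 2, mode = "regression",
                       scale = TRUE)
  for (a in 1:2) {
    r <- abs(stats::cor(fit$scores[, a], ref$variates$X[, a]))
    expect_gt(r, 1 - 1e-8)
  }
})
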