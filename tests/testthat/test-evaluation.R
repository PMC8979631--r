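test_that("trapezoidal AUC equals the Mann-Whitney statistic, ties included", {
  mw_auc <- function(scores, labels) {
    pos <- labels == "PD"
    r <- rank(scores)
    (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
      (sum(pos) * sum(!pos))
  }
  for (sd0 in 1:10) {
    set.seed(sd0)
    labels <- sample(c("PD", "CL"), 60, replace = TRUE, prob = c(0.6, 0.4))
    scores <- sample(1:8, 60, replace = TRUE)   # heavy ties
    expect_equal(roc_auc(scores, labels), mw_auc(scores, labels),
                 tolerance = 1e-12)
  }
  # perfect separation
  expect_equal(roc_auc(c(5, 6, 7, 1, 2), c("PD", "PD", "PD", "CL", "CL")), 1)
  expect_error(roc_auc(1:5, rep("PD", 5)), "both classes")
  # labels independent of scores: AUC near 1/2
  aucs <- replicate(50, {
    roc_auc(rnorm(80), sample(c("PD", "CL"), 80, replace = TRUE))
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.1)
})

test_that("group comparison matches the Welch closed form", {
  welch <- function(m1, s1, n1, m2, s2, n2) {
    t <- (m1 - m2) / sqrt(s1^2 / n1 + s2^2 / n2)
    df <- (s1^2 / n1 + s2^2 / n2)^2 /
      ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
    list(t = t, p = 2 * stats::pt(-abs(t), df))
  }
  set.seed(2)
  a <- rnorm(10, 1, 1); b <- rnorm(10, 0, 2)
  X <- matrix(c(a, b), ncol = 1, dimnames = list(NULL, "feat"))
  out <- group_compare(X, labels = rep(c("PD", "CL"), each = 10))
  ref <- welch(mean(a), sd(a), 10, mean(b), sd(b), 10)
  expect_equal(out$t, ref$t, tolerance = 1e-6)
  expect_equal(out$p, ref$p, tolerance = 1e-6)
  expect_equal(out$z, (mean(a) - mean(b)) / sd(b), tolerance = 1e-10)

  # identical groups: no effect
  X2 <- matrix(rep(rnorm(10), 2), ncol = 1,
               dimnames = list(NULL, "feat"))
  out2 <- group_compare(X2, labels = rep(c("PD", "CL"), each = 10))
  expect_equal(out2$t, 0, tolerance = 1e-12)
  expect_equal(out2$p, 1, tolerance = 1e-12)
  expect_equal(out2$z, 0, tolerance = 1e-12)

  # zero control SD: z missing
  X3 <- cbind(feat = c(rnorm(5), rep(1, 5)))
  expect_message(
    out3 <- group_compare(X3, labels = rep(c("PD", "CL"), each = 5)),
    "zero control SD")
  expect_true(is.na(out3$z))
})

test_that("a planted one-control-SD shift is recovered as z = 1", {
  zs <- sapply(1:20, function(sd0) {
    set.seed(sd0)
    X <- cbind(feat = c(rnorm(60, 1), rnorm(60, 0)))
    group_compare(X, labels = rep(c("PD", "CL"), each = 60))$z
  })
  expect_equal(mean(zs), 1, tolerance = 0.15)
})

test_that("battery subsets have the architecture's column counts", {
  sc <- small_cohort()
  bat <- run_battery(sc$features, sc$cohort$demographics, folds = 4)
  expect_equal(bat$n_features[bat$model == "spatiotemporal"], 25)
  expect_equal(bat$n_features[bat$model == "signal"], 56 + 20 + 84 + 25)
  expect_equal(bat$n_features[bat$model == "gait"], 210)
  expect_equal(bat$n_features[bat$model == "gait_dem"], 216)
  # confusion-matrix identities hold exactly
  n <- nrow(sc$features)
  expect_equal(bat$accuracy, 100 * (bat$tp + bat$tn) / n)
  expect_equal(bat$sensitivity, 100 * bat$tp / (bat$tp + bat$fn))
  expect_equal(bat$specificity, 100 * bat$tn / (bat$tn + bat$fp))
  expect_true(all(bat$auc >= 0 & bat$auc <= 100))
  expect_error(run_battery(sc$features, subsets = "everything"),
               "unknown subset")
})

test_that("the battery is deterministic for a fixed cohort and seed", {
  sc <- small_cohort()
  b1 <- run_battery(sc$features, sc$cohort$demographics,
                    subsets = c("spatiotemporal", "gait_dem"), folds = 4)
  b2 <- run_battery(sc$features, sc$cohort$demographics,
                    subsets = c("spatiotemporal", "gait_dem"), folds = 4)
  expect_identical(as.data.frame(b1), as.data.frame(b2))
})
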