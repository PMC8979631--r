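# Model battery, classification metrics, ROC/AUC and group statistics.

#' Trapezoidal ROC area under the curve
#'
#' AUC by the trapezoidal rule over all score thresholds; tied scores
#' contribute half, so the value equals the Mann-Whitney U statistic
#' divided by `n1 * n2`.
#'
#' @param scores Continuous classifier scores (higher = more positive).
#' @param labels Class labels.
#' @param positive Positive-class label (default `"PD"`).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels, positive = "PD") {
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("both classes must be present")
  roc <- roc_curve(scores, pos)
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

# ROC coordinates over all distinct thresholds (descending)
roc_curve <- function(scores, pos) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # group ties: cumulative counts at the end of every tie block
  block_end <- c(diff(s) != 0, TRUE)
  tp <- cumsum(p)[block_end]; fp <- cumsum(!p)[block_end]
  data.frame(threshold = c(Inf, s[block_end]),
             tpr = c(0, tp / sum(pos)), fpr = c(0, fp / sum(!pos)))
}

classification_metrics <- function(pred, truth, positive = "PD") {
  tp <- sum(pred == positive & truth == positive)
  tn <- sum(pred != positive & truth != positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  c(accuracy = 100 * (tp + tn) / length(truth),
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    tp = tp, tn = tn, fp = fp, fn = fn)
}

battery_subsets <- function() {
  list(
    spatiotemporal = "st",
    spatiotemporal_dem = c("st", "dem"),
    signal = c("frq", "reg", "mag", "cpx"),
    signal_dem = c("frq", "reg", "mag", "cpx", "dem"),
    gait = c("st", "frq", "reg", "mag", "cpx"),
    gait_dem = c("st", "frq", "reg", "mag", "cpx", "dem"))
}

subset_columns <- function(feature_names, domains) {
  pref <- sub("_.*", "", feature_names)
  feature_names[pref %in% domains]
}

#' Run the six-model PLS-DA classification battery
#'
#' Trains one PLS-DA model per feature subset: spatiotemporal alone
#' and with demographics, signal-based (frequency + regularity +
#' magnitude + complexity) alone and with demographics, and the full
#' gait battery alone and with demographics.  For each subset the
#' number of components is chosen from the cross-validated Q2 curve,
#' out-of-fold predictions are pooled over a stratified k-fold split,
#' and accuracy, sensitivity, specificity (PD positive) and the
#' trapezoidal AUC of the pooled PD score are reported.  A held-out
#' split mode (`holdout > 0`) is also available.
#'
#' @param features Data frame from [extract_features()] (columns
#'   `subject_id`, `group` and the 210 gait features).
#' @param demographics Data frame with `subject_id`, `age`, `sex`,
#'   `height`, `weight`, `bmi`, `moca`.
#' @param subsets Character vector of subset names (default all six).
#' @param ncomp_max,folds,seed Passed to [plsda_cv()] and the pooled
#'   CV predictions.
#' @param holdout Fraction held out for testing instead of pooled CV
#'   (0 = pooled cross-validation, the default).
#' @return Data frame of class `battery_report`: one row per model with
#'   columns `model`, `n_features`, `ncomp`, `accuracy`, `sensitivity`,
#'   `specificity`, `auc`, `tp`, `tn`, `fp`, `fn`; per-model ROC
#'   coordinates in `attr(, "roc")` and pooled scores in
#'   `attr(, "scores")`.
#' @export
run_battery <- function(features, demographics = NULL,
                        subsets = names(battery_subsets()),
                        ncomp_max = 6, folds = 7, seed = 20200214,
                        holdout = 0) {
  defs <- battery_subsets()
  unknown <- setdiff(subsets, names(defs))
  if (length(unknown))
    stop("unknown subset name(s): ", paste(unknown, collapse = ", "))
  y <- factor(features$group, levels = c("PD", "CL"))
  X_full <- design_matrix(features, demographics)
  rows <- list(); rocs <- list(); score_list <- list()
  for (nm in subsets) {
    cols <- subset_columns(colnames(X_full), defs[[nm]])
    X <- X_full[, cols, drop = FALSE]
    quality <- plsda_cv(X, y, ncomp_max = ncomp_max, folds = folds,
                        seed = seed)
    astar <- select_components(quality)
    if (holdout > 0) {
      set.seed(seed)
      te <- unlist(lapply(levels(y), function(lv) {
        w <- which(y == lv); sample(w, max(1, round(holdout * length(w))))
      }))
      fit <- plsda(X[-te, , drop = FALSE], y[-te], ncomp = astar)
      pr <- predict(fit, X[te, , drop = FALSE], type = "both")
      truth <- y[te]; cls <- pr$class; sc <- pr$score[, "PD"]
    } else {
      idx <- stratified_folds(y, folds, seed)
      cls <- factor(rep(NA_character_, length(y)), levels = levels(y))
      sc <- numeric(length(y))
      for (f in seq_len(folds)) {
        tr <- idx != f
        fit <- plsda(X[tr, , drop = FALSE], y[tr], ncomp = astar)
        pr <- predict(fit, X[!tr, , drop = FALSE], type = "both")
        cls[!tr] <- pr$class
        sc[!tr] <- pr$score[, "PD"]
      }
      truth <- y
    }
    met <- classification_metrics(cls, truth)
    auc <- roc_auc(sc, truth)
    rows[[nm]] <- data.frame(
      model = nm, n_features = ncol(X), ncomp = astar,
      accuracy = met[["accuracy"]], sensitivity = met[["sensitivity"]],
      specificity = met[["specificity"]], auc = 100 * auc,
      tp = met[["tp"]], tn = met[["tn"]], fp = met[["fp"]],
      fn = met[["fn"]], stringsAsFactors = FALSE)
    rocs[[nm]] <- roc_curve(sc, truth == "PD")
    score_list[[nm]] <- data.frame(subject_id = features$subject_id[
      if (holdout > 0) te else seq_along(y)],
      truth = truth, score_pd = sc, predicted = cls)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "roc") <- rocs
  attr(out, "scores") <- score_list
  class(out) <- c("battery_report", "data.frame")
  out
}

#' @export
print.battery_report <- function(x, ...) {
  cat("PLS-DA classification battery (PD positive):\n")
  print.data.frame(x[, c("model", "n_features", "ncomp", "accuracy",
                         "sensitivity", "specificity", "auc")],
                   row.names = FALSE, digits = 4)
  invisible(x)
}

#' Per-feature group comparison (PD vs CL)
#'
#' Welch two-sample t-test per feature, group means and SDs, and the
#' z-score of the PD mean relative to the control distribution,
#' `z = (mean_PD - mean_CL) / SD_CL`.  Optionally a Benjamini-Hochberg
#' adjusted p-value column, and a Pearson correlation matrix among a
#' chosen feature subset (e.g. the VIP-selected ones).
#'
#' @param features Feature data frame (with `group` column) or numeric
#'   matrix.
#' @param labels Group labels if `features` is a matrix.
#' @param adjust Add BH-adjusted p-values (default `FALSE`).
#' @param cor_features Character vector of feature names for the
#'   correlation matrix (attribute `correlation` of the result).
#' @return Data frame with one row per feature: `feature`, `mean_pd`,
#'   `sd_pd`, `mean_cl`, `sd_cl`, `t`, `p`, `z`.
#' @export
group_compare <- function(features, labels = NULL, adjust = FALSE,
                          cor_features = NULL) {
  if (is.data.frame(features) && "group" %in% names(features)) {
    labels <- features$group
    X <- as.matrix(features[, !(names(features) %in%
                                  c("subject_id", "group")), drop = FALSE])
  } else {
    X <- as.matrix(features)
  }
  pd <- labels == "PD"; cl <- labels == "CL"
  if (sum(pd) < 2 || sum(cl) < 2) stop("need >= 2 subjects per group")
  res <- lapply(colnames(X), function(j) {
    a <- X[pd, j]; b <- X[cl, j]
    m1 <- mean(a, na.rm = TRUE); m2 <- mean(b, na.rm = TRUE)
    s1 <- stats::sd(a, na.rm = TRUE); s2 <- stats::sd(b, na.rm = TRUE)
    tt <- tryCatch(stats::t.test(a, b), error = function(e) NULL)
    if (s2 < 1e-12) message("zero control SD for ", j, ": z-score missing")
    data.frame(feature = j, mean_pd = m1, sd_pd = s1, mean_cl = m2,
               sd_cl = s2,
               t = if (is.null(tt)) 0 else unname(tt$statistic),
               p = if (is.null(tt)) 1 else tt$p.value,
               z = if (s2 < 1e-12) NA_real_ else (m1 - m2) / s2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  if (!is.null(cor_features)) {
    sel <- intersect(cor_features, colnames(X))
    attr(out, "correlation") <- stats::cor(X[, sel, drop = FALSE],
                                           use = "pairwise.complete.obs")
  }
  out
}
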