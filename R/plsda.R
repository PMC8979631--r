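# Partial least squares discriminant analysis, written from scratch
# with the NIPALS algorithm.  The class matrix is one-hot coded
# (PD, CL) and column-centered; predictors are autoscaled (mean 0,
# SD 1).  Component quality is judged by cross-validated Q2 together
# with the cumulative explained variances R2X and R2Y, and variable
# importance by the VIP score.

#' Fit a PLS-DA model
#'
#' Fits partial least squares regression of a column-centered one-hot
#' class matrix on autoscaled predictors using the NIPALS algorithm,
#' for use as a two-class discriminant model.  For each component the
#' weight/score/loading set is extracted iteratively and the data
#' matrices deflated.
#'
#' @param x Numeric matrix or data frame of predictors (n x p).
#' @param y Factor (or character/logical coercible to one) with exactly
#'   two levels; `"PD"` is treated as the positive class when present.
#' @param ncomp Number of latent components to extract.
#' @param scale Autoscale columns of `x` (default `TRUE`).
#' @param tol Convergence tolerance on the relative change of the score
#'   vector (default 1e-10).
#' @param max_iter Maximum NIPALS iterations per component.
#'
#' @return An object of class `plsda`: a list with score matrix `scores`
#'   (T), predictor weights `weights` (W, unit columns), predictor
#'   loadings `loadings` (P), class loadings `yloadings` (Q, 2 x A),
#'   per-component explained response sum of squares `ssy`, explained
#'   variance curves `r2x`/`r2y` (cumulative), regression coefficients
#'   on the autoscaled scale, the centering/scaling vectors, imputation
#'   medians, and the class levels.
#'
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40 * 6), 40)
#' y <- factor(rep(c("PD", "CL"), each = 20))
#' x[y == "PD", 1] <- x[y == "PD", 1] + 2
#' fit <- plsda(x, y, ncomp = 2)
#' fit
#' head(predict(fit, x))
#' vip(fit)
#' @export
plsda <- function(x, y, ncomp = 2, scale = TRUE, tol = 1e-10,
                  max_iter = 500) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stop("y must have exactly two classes")
  lev <- levels(y)
  if ("PD" %in% lev) lev <- c("PD", setdiff(lev, "PD"))
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n) stop("x and y dimensions disagree")
  if (ncomp < 1 || ncomp > min(n - 1, p))
    stop("ncomp must lie in [1, min(n - 1, p)]")

  # median imputation (training medians kept for prediction)
  medians <- apply(x, 2, stats::median, na.rm = TRUE)
  na_cols <- colnames(x)[colSums(is.na(x)) > 0]
  if (length(na_cols)) {
    message("imputing training medians in ", length(na_cols),
            " column(s): ", paste(utils::head(na_cols, 5), collapse = ", "),
            if (length(na_cols) > 5) ", ..." else "")
    for (j in na_cols) x[is.na(x[, j]), j] <- medians[j]
  }
  x_center <- colMeans(x)
  x_scale <- if (scale) apply(x, 2, stats::sd) else rep(1, p)
  zero_var <- colnames(x)[x_scale < 1e-12]
  if (length(zero_var))
    stop("zero-variance column(s) in x: ",
         paste(utils::head(zero_var, 5), collapse = ", "))
  Xs <- sweep(sweep(x, 2, x_center), 2, x_scale, `/`)
  Y0 <- cbind(as.numeric(y == lev[1]), as.numeric(y == lev[2]))
  colnames(Y0) <- lev
  y_means <- colMeans(Y0)
  Ys <- sweep(Y0, 2, y_means)

  ssx_tot <- sum(Xs^2); ssy_tot <- sum(Ys^2)
  W <- matrix(0, p, ncomp, dimnames = list(colnames(x), NULL))
  P <- matrix(0, p, ncomp, dimnames = list(colnames(x), NULL))
  Q <- matrix(0, 2, ncomp, dimnames = list(lev, NULL))
  TT <- matrix(0, n, ncomp)
  ssy_comp <- numeric(ncomp)
  r2x <- r2y <- numeric(ncomp)
  Xa <- Xs; Ya <- Ys
  for (a in seq_len(ncomp)) {
    u <- Ya[, which.max(apply(Ya, 2, stats::var))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xa, u)
      w <- w / sqrt(sum(w^2))
      t <- Xa %*% w
      q <- crossprod(Ya, t) / sum(t^2)
      u <- Ya %*% q / sum(q^2)
      if (sqrt(sum((t - t_old)^2)) / sqrt(sum(t^2)) < tol) break
      t_old <- t
      if (it == max_iter)
        stop("NIPALS did not converge in ", max_iter,
             " iterations for component ", a)
    }
    pload <- crossprod(Xa, t) / sum(t^2)
    Xa <- Xa - t %*% t(pload)
    Ya <- Ya - t %*% t(q)
    W[, a] <- w; P[, a] <- pload; Q[, a] <- q; TT[, a] <- t
    ssy_comp[a] <- sum(q^2) * sum(t^2)
    r2x[a] <- 1 - sum(Xa^2) / ssx_tot
    r2y[a] <- 1 - sum(Ya^2) / ssy_tot
  }
  # regression coefficients on the autoscaled scale
  B <- W %*% solve(crossprod(P, W), t(Q))
  structure(list(
    scores = TT, weights = W, loadings = P, yloadings = Q,
    ssy = ssy_comp, r2x = r2x, r2y = r2y, coefficients = B,
    x_center = x_center, x_scale = x_scale, medians = medians,
    y_means = y_means, levels = lev, ncomp = ncomp, n = n, p = p,
    y = factor(as.character(y), levels = lev),
    terms_names = colnames(x)), class = "plsda")
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("PLS-DA model: %d observations, %d predictors, %d component(s)\n",
              x$n, x$p, x$ncomp))
  cat(sprintf("classes: %s (positive) vs %s\n", x$levels[1], x$levels[2]))
  cat("cumulative R2X:", paste(sprintf("%.3f", x$r2x), collapse = " "), "\n")
  cat("cumulative R2Y:", paste(sprintf("%.3f", x$r2y), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.plsda <- function(object, ...) {
  tab <- data.frame(component = seq_len(object$ncomp),
                    R2X_cum = object$r2x, R2Y_cum = object$r2y,
                    SSY_explained = object$ssy)
  v <- vip(object)
  res <- list(model = object, quality = tab,
              top_features = utils::head(v[order(-v$vip_avg), ], 10))
  class(res) <- "summary.plsda"
  res
}

#' @export
print.summary.plsda <- function(x, ...) {
  print(x$model)
  cat("\nPer-component quality:\n")
  print(x$quality, row.names = FALSE, digits = 4)
  cat("\nTop features by average VIP:\n")
  print(x$top_features[, c("feature", "vip_avg", "rank")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.plsda <- function(object, ...) object$coefficients

#' Predict classes or scores from a PLS-DA model
#'
#' New data are imputed with the training medians and autoscaled with
#' the training parameters; predictions are the two-column continuous
#' regression outputs (adding back the class-proportion intercepts)
#' and the class is the column argmax, ties going to the positive
#' class.
#'
#' @param object A `plsda` fit.
#' @param newdata Matrix/data frame with the training columns.
#' @param type `"class"` (default) for labels, `"score"` for the
#'   continuous two-column predictions, `"both"` for a list.
#' @param ... Unused.
#' @export
predict.plsda <- function(object, newdata,
                          type = c("class", "score", "both"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (is.null(colnames(x))) colnames(x) <- object$terms_names
  missing_cols <- setdiff(object$terms_names, colnames(x))
  extra <- setdiff(colnames(x), object$terms_names)
  if (length(missing_cols) || (length(extra) && ncol(x) != object$p))
    stop("column mismatch; missing: ",
         paste(utils::head(missing_cols, 5), collapse = ", "),
         "; unexpected: ", paste(utils::head(extra, 5), collapse = ", "))
  x <- x[, object$terms_names, drop = FALSE]
  for (j in seq_len(ncol(x)))
    x[is.na(x[, j]), j] <- object$medians[j]
  Xs <- sweep(sweep(x, 2, object$x_center), 2, object$x_scale, `/`)
  sc <- Xs %*% object$coefficients
  sc <- sweep(sc, 2, object$y_means, `+`)
  colnames(sc) <- object$levels
  cls <- factor(object$levels[max.col(sc, ties.method = "first")],
                levels = object$levels)
  switch(type, class = cls, score = sc, both = list(class = cls, score = sc))
}

#' @export
fitted.plsda <- function(object, ...) {
  sc <- object$scores %*% t(object$yloadings)
  sweep(sc, 2, object$y_means, `+`)
}

#' @export
residuals.plsda <- function(object, ...) {
  Y0 <- cbind(as.numeric(object$y == object$levels[1]),
              as.numeric(object$y == object$levels[2]))
  colnames(Y0) <- object$levels
  Y0 - fitted(object)
}

#' Score plot of a PLS-DA model
#'
#' @param x A `plsda` fit.
#' @param comps Two component indices to plot.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.plsda <- function(x, comps = c(1, 2), ...) {
  if (x$ncomp < 2) comps <- c(1, 1)
  cls <- x$y
  graphics::plot(x$scores[, comps[1]], x$scores[, comps[2]],
                 col = as.integer(cls) + 1, pch = as.integer(cls),
                 xlab = paste0("t", comps[1]), ylab = paste0("t", comps[2]),
                 main = "PLS-DA scores", ...)
  graphics::legend("topright", legend = x$levels, col = 2:3, pch = 1:2)
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' Cumulative VIP at each component
#' `VIP_j(a) = sqrt(p * sum_(b<=a) SSY_b w_jb^2 / sum_(b<=a) SSY_b)`
#' with `SSY_b` the response sum of squares explained by component `b`;
#' the mean of squared VIPs over features is 1 at every `a`.  Features
#' are ranked by the average VIP across the model's components.
#'
#' @param object A fitted model.
#' @param ... Method arguments.
#' @return For `plsda`: a data frame of class `vip_table` with columns
#'   `feature`, `vip_comp1..A` (cumulative VIP at each component),
#'   `vip_avg` and `rank` (1 = most important).
#' @export
vip <- function(object, ...) UseMethod("vip")

#' @rdname vip
#' @export
vip.plsda <- function(object, ...) {
  W <- object$weights
  ssy <- object$ssy
  p <- object$p
  vmat <- sapply(seq_len(object$ncomp), function(a) {
    wsq <- W[, 1:a, drop = FALSE]^2
    sqrt(p * as.numeric(wsq %*% ssy[1:a]) / sum(ssy[1:a]))
  })
  vmat <- matrix(vmat, nrow = p)
  colnames(vmat) <- paste0("vip_comp", seq_len(object$ncomp))
  avg <- rowMeans(vmat)
  out <- data.frame(feature = object$terms_names, vmat,
                    vip_avg = avg, rank = rank(-avg, ties.method = "first"),
                    stringsAsFactors = FALSE)
  class(out) <- c("vip_table", "data.frame")
  out
}

#' Cross-validated PLS-DA quality curves (Q2, R2X, R2Y)
#'
#' Q2 at `a` components is `1 - PRESS(a) / SS(Y)` with the prediction
#' error accumulated over stratified k-fold cross-validation (median
#' imputation and autoscaling refit inside every training fold);
#' R2X/R2Y are the cumulative explained variances of the full-data
#' fit.
#'
#' @param x Predictor matrix.
#' @param y Two-level factor.
#' @param ncomp_max Largest number of components to evaluate.
#' @param folds Number of stratified folds (default 7).
#' @param seed Seed for the fold assignment (default 20200214).
#' @return Data frame of class `plsda_quality` with columns
#'   `component`, `Q2`, `R2X`, `R2Y`.
#' @export
plsda_cv <- function(x, y, ncomp_max = 6, folds = 7, seed = 20200214) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (folds < 2) stop("folds must be >= 2")
  n <- nrow(x)
  idx <- stratified_folds(y, folds, seed)
  for (f in seq_len(folds)) {
    if (nlevels(droplevels(y[idx != f])) < 2 ||
        !length(which(idx == f)))
      stop("a fold lost one of the classes; reduce folds")
  }
  ncomp_max <- min(ncomp_max, ncol(x), n - max(table(idx)) - 1)
  lev <- levels(y)
  if ("PD" %in% lev) lev <- c("PD", setdiff(lev, "PD"))
  Y0 <- cbind(as.numeric(y == lev[1]), as.numeric(y == lev[2]))
  ssy <- sum(sweep(Y0, 2, colMeans(Y0))^2)
  press <- numeric(ncomp_max)
  for (f in seq_len(folds)) {
    tr <- idx != f; te <- !tr
    fit <- plsda(x[tr, , drop = FALSE], y[tr], ncomp = ncomp_max)
    # predictions at every truncated component count
    xte <- x[te, , drop = FALSE]
    for (j in seq_len(ncol(xte)))
      xte[is.na(xte[, j]), j] <- fit$medians[j]
    Xs <- sweep(sweep(xte, 2, fit$x_center), 2, fit$x_scale, `/`)
    for (a in seq_len(ncomp_max)) {
      Ba <- fit$weights[, 1:a, drop = FALSE] %*%
        solve(crossprod(fit$loadings[, 1:a, drop = FALSE],
                        fit$weights[, 1:a, drop = FALSE]),
              t(fit$yloadings[, 1:a, drop = FALSE]))
      pred <- sweep(Xs %*% Ba, 2, fit$y_means, `+`)
      obs <- cbind(as.numeric(y[te] == lev[1]), as.numeric(y[te] == lev[2]))
      press[a] <- press[a] + sum((obs - pred)^2)
    }
  }
  full <- plsda(x, y, ncomp = ncomp_max)
  out <- data.frame(component = seq_len(ncomp_max),
                    Q2 = 1 - press / ssy, R2X = full$r2x, R2Y = full$r2y)
  class(out) <- c("plsda_quality", "data.frame")
  out
}

stratified_folds <- function(y, folds, seed) {
  idx <- integer(length(y))
  set.seed(seed)
  for (lv in levels(y)) {
    w <- which(y == lv)
    idx[w] <- sample(rep(seq_len(folds), length.out = length(w)))
  }
  idx
}

#' Select the number of PLS-DA components
#'
#' The smallest `a` whose Q2 gain over the next component falls below
#' `delta` (default 0.01), capped at 10; if the curve keeps rising the
#' largest evaluated `a` is returned.
#'
#' @param quality A `plsda_quality` data frame from [plsda_cv()].
#' @param delta Minimal worthwhile Q2 improvement.
#' @param cap Hard upper bound on the selected number of components.
#' @return Integer number of components.
#' @export
select_components <- function(quality, delta = 0.01, cap = 10) {
  q <- quality$Q2
  amax <- length(q)
  for (a in seq_len(amax - 1))
    if (q[a + 1] - q[a] < delta + 1e-9) return(min(a, cap))
  min(amax, cap)
}

#' Serialize a PLS-DA model to a JSON + CSV bundle
#'
#' @param object A `plsda` fit.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_plsda <- function(object, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("weights", "loadings", "scores", "coefficients")) {
    m <- object[[nm]]
    data.table::fwrite(as.data.frame(m), file.path(dir, paste0(nm, ".csv")))
  }
  data.table::fwrite(vip(object), file.path(dir, "vip.csv"))
  meta <- list(ncomp = object$ncomp, levels = object$levels,
               r2x = object$r2x, r2y = object$r2y, ssy = object$ssy,
               y_means = object$y_means,
               x_center = as.list(object$x_center),
               x_scale = as.list(object$x_scale))
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
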