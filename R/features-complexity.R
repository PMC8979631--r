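# Complexity domain: 25 characteristics — phase-plot (acceleration vs
# jerk) orbit geometry per stride, and largest Lyapunov exponents by
# the Rosenstein algorithm (per axis, on the resultant, and on the
# joint three-axis state space).

complexity_feature_names <- function() {
  axes4 <- c("vt", "ml", "ap", "res")
  pp <- c("orbit_area_mean", "orbit_area_sd", "long_half_asym",
          "short_half_asym", "centroid_drift")
  c(as.vector(outer(pp, axes4, function(m, a) paste0("cpx_", m, "_", a))),
    paste0("cpx_lyap_", axes4), "cpx_lyap_joint")
}

#' Phase-plot orbit features of one axis
#'
#' For every stride the orbit is the closed curve of the z-normalized
#' acceleration against its z-normalized central-difference derivative
#' (jerk), both normalized over the whole bout.  Per stride the orbit
#' area is computed by the shoelace formula; the long/short half-orbit
#' area asymmetries split the orbit along its first/second principal
#' axis (through the orbit centroid) and compare the clipped areas
#' `|A+ - A-| / (A+ + A-)`; centroid drift is the RMS distance of the
#' per-stride orbit centroids from their mean.
#'
#' @param x Whole-bout axis signal.
#' @param strides Data frame of stride segments (from [segment()]),
#'   indices referring to `x`.
#' @param fs Sampling frequency (Hz).
#' @return Named vector `orbit_area_mean`, `orbit_area_sd`,
#'   `long_half_asym`, `short_half_asym`, `centroid_drift`.
#' @export
phase_plot_features <- function(x, strides, fs) {
  out <- c(orbit_area_mean = NA_real_, orbit_area_sd = NA_real_,
           long_half_asym = NA_real_, short_half_asym = NA_real_,
           centroid_drift = NA_real_)
  if (nrow(strides) < 5) return(out)
  n <- length(x)
  jerk <- c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1]) * fs
  xz <- (x - mean(x)) / stats::sd(x)
  jz <- (jerk - mean(jerk)) / stats::sd(jerk)
  g <- .orbit_stats(xz, jz, as.integer(strides$start_idx),
                    as.integer(strides$end_idx))
  ok <- !is.na(g$area)
  if (sum(ok) < 5) return(out)
  out["orbit_area_mean"] <- mean(g$area[ok])
  out["orbit_area_sd"] <- stats::sd(g$area[ok])
  out["long_half_asym"] <- mean(g$long_asym[ok], na.rm = TRUE)
  out["short_half_asym"] <- mean(g$short_asym[ok], na.rm = TRUE)
  cents <- cbind(g$cx[ok], g$cy[ok])
  cm <- colMeans(cents)
  out["centroid_drift"] <- sqrt(mean(rowSums(sweep(cents, 2, cm)^2)))
  out
}

#' Geometry of a single phase-plot orbit
#'
#' Shoelace area, half-orbit area asymmetries about the first and
#' second principal axes, and the centroid, for one closed
#' acceleration-jerk orbit.
#'
#' @param orb n x 2 matrix of orbit points in traversal order.
#' @return List with `area`, `long_asym`, `short_asym`, `centroid`,
#'   or `NULL` for a degenerate (zero-area) orbit.
#' @export
orbit_geometry <- function(orb) {
  orb <- as.matrix(orb)
  g <- .orbit_stats(orb[, 1], orb[, 2], 0L, nrow(orb))
  if (is.na(g$area[1])) return(NULL)
  list(area = g$area[1], long_asym = g$long_asym[1],
       short_asym = g$short_asym[1], centroid = c(g$cx[1], g$cy[1]))
}

#' Largest Lyapunov exponent (Rosenstein algorithm)
#'
#' Delay-embeds the signal (default dimension 5; delay from the first
#' minimum of the average mutual information, falling back to 10
#' samples), finds for a set of reference points the nearest neighbour
#' outside a Theiler window, and fits a least-squares line to the mean
#' log-divergence curve over the initial expansion window.  The slope
#' is returned per second.
#'
#' @param x Numeric vector, or a T x k matrix for a joint state space
#'   (each column is delay-embedded and the coordinates concatenated).
#' @param fs Sampling frequency (Hz).
#' @param embed_dim Total embedding dimension for a vector input; for a
#'   matrix input the per-column dimension is
#'   `max(2, ceiling(embed_dim / k))`.
#' @param delay Embedding delay in samples (`NULL` = automatic).
#' @param theiler_s Theiler exclusion window in seconds (use the mean
#'   stride time).
#' @param fit_window_s End of the divergence-fit window in seconds
#'   (use half the mean stride time for gait).
#' @param fit_skip_s Start of the fit window in seconds (default 0;
#'   set it past the initial neighbour-alignment transient when the
#'   log-divergence curve of the system has one, as for long smooth
#'   chaotic series).
#' @param n_ref Number of reference points (subsampled evenly).
#' @return Exponent in 1/s, or `NA` when too few neighbour pairs
#'   exist; exactly 0 when all nearest neighbours are machine-precision
#'   repeats (a perfectly periodic signal).
#' @export
lyapunov_rosenstein <- function(x, fs, embed_dim = 5, delay = NULL,
                                theiler_s = 1, fit_window_s = 0.5,
                                fit_skip_s = 0, n_ref = 250) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  k <- ncol(x)
  x <- scale(x)
  if (is.null(delay)) delay <- ami_delay(x[, 1], max_lag = min(fs, 50))
  m <- if (k == 1) embed_dim else max(2, ceiling(embed_dim / k))
  n <- nrow(x)
  n_states <- n - (m - 1) * delay
  if (n_states < 100) return(NA_real_)
  # embedded state matrix: n_states x (m * k)
  emb <- matrix(0, n_states, m * k)
  for (j in seq_len(k)) for (d in seq_len(m))
    emb[, (j - 1) * m + d] <- x[(1 + (d - 1) * delay):((d - 1) * delay + n_states), j]
  theiler <- max(1L, round(theiler_s * fs))
  kmax <- max(2L, round(fit_window_s * fs))
  usable <- n_states - kmax
  if (usable < 2 * theiler + 10) return(NA_real_)
  refs <- unique(round(seq(1, usable, length.out = min(n_ref, usable))))
  sq <- rowSums(emb^2)
  # nearest neighbours of all reference points in one BLAS call;
  # the per-row constant sq[i] is irrelevant to the argmin
  D2 <- sweep(-2 * tcrossprod(emb[refs, , drop = FALSE],
                              emb[seq_len(usable), , drop = FALSE]),
              2, sq[seq_len(usable)], `+`)
  for (ri in seq_along(refs)) {
    i <- refs[ri]
    D2[ri, max(1, i - theiler):min(usable, i + theiler)] <- Inf
  }
  nn <- max.col(-D2, ties.method = "first")
  d2min <- D2[cbind(seq_along(refs), nn)] + sq[refs]
  ok <- is.finite(d2min) & d2min > 1e-12
  if (sum(ok) < 5) {
    # nearest neighbours are numerically exact repeats: the signal is
    # periodic to machine precision and shows no divergence
    if (stats::median(d2min, na.rm = TRUE) < 1e-12) return(0)
    return(NA_real_)
  }
  ri <- refs[ok]; rj <- nn[ok]
  logd <- matrix(NA_real_, length(ri), kmax + 1)
  for (k in 0:kmax) {
    d2k <- rowSums((emb[ri + k, , drop = FALSE] -
                      emb[rj + k, , drop = FALSE])^2)
    logd[, k + 1] <- 0.5 * log(pmax(d2k, 1e-300))
  }
  curve <- colMeans(logd)
  if (!all(is.finite(curve))) return(NA_real_)
  tt <- (0:kmax) / fs
  sel <- tt >= fit_skip_s
  if (sum(sel) < 3) sel <- rep(TRUE, length(tt))
  unname(stats::coef(stats::lm.fit(cbind(1, tt[sel]), curve[sel]))[2])
}

# delay from the first local minimum of the average mutual information
ami_delay <- function(x, max_lag = 100, n_bins = 16, fallback = 10) {
  n <- length(x)
  max_lag <- min(max_lag, floor(n / 4))
  br <- stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1))
  br <- unique(br)
  if (length(br) < 3 || max_lag < 3) return(fallback)
  b <- cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
  nb <- length(br) - 1
  ami <- numeric(max_lag)
  for (lag in seq_len(max_lag)) {
    b1 <- b[1:(n - lag)]; b2 <- b[(lag + 1):n]
    tab <- tabulate(b1 + nb * (b2 - 1), nb * nb) / (n - lag)
    dim(tab) <- c(nb, nb)
    p1 <- rowSums(tab); p2 <- colSums(tab)
    nz <- tab > 0
    ami[lag] <- sum(tab[nz] * log(tab[nz] / outer(p1, p2)[nz]))
  }
  for (lag in 2:(max_lag - 1))
    if (ami[lag] < ami[lag - 1] && ami[lag] <= ami[lag + 1]) return(lag)
  fallback
}

#' Complexity feature vector (25 characteristics)
#'
#' Phase-plot orbit geometry per axis (20) plus largest Lyapunov
#' exponents per axis, on the resultant, and on the joint three-axis
#' state space (5).
#'
#' @param rec A preprocessed `gait_recording`.
#' @param ev A `gait_events` object.
#' @param n_ref Reference points for the Lyapunov estimator.
#' @return Named numeric vector of length 25 (prefix `cpx_`).
#' @export
complexity_vector <- function(rec, ev, n_ref = 200) {
  nm <- complexity_feature_names()
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  fs <- rec$fs
  tp <- temporal_params(ev)
  stride_t <- mean(tp$strides$stride_time, na.rm = TRUE)
  strides <- segment(rec, ev, "stride")
  sig <- axis_signals(rec$samples)
  for (a in c("vt", "ml", "ap", "res")) {
    pf <- phase_plot_features(sig[[a]], strides, fs)
    out[paste0("cpx_", names(pf), "_", a)] <- pf
    out[paste0("cpx_lyap_", a)] <- lyapunov_rosenstein(
      sig[[a]], fs, theiler_s = stride_t, fit_window_s = stride_t / 2,
      n_ref = n_ref)
  }
  out["cpx_lyap_joint"] <- lyapunov_rosenstein(
    cbind(sig$vt, sig$ml, sig$ap), fs, embed_dim = 6,
    theiler_s = stride_t, fit_window_s = stride_t / 2, n_ref = n_ref)
  out
}
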