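# Shared signal-processing primitives used across the feature domains.

trapz_int <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

cumtrapz_int <- function(y, dt) {
  n <- length(y)
  c(0, cumsum((y[-n] + y[-1]) / 2 * dt))
}

#' Welch power spectral density estimate
#'
#' Hann-windowed, linearly detrended, 50%-overlapping segment-averaged
#' periodogram, scaled as a one-sided density so that integrating over
#' frequency recovers the signal variance (Parseval).
#'
#' @param x Numeric signal.
#' @param fs Sampling frequency (Hz).
#' @param seg_sec Segment length in seconds (default 3); shrunk to the
#'   full signal when shorter.
#' @param overlap Fractional overlap between segments.
#' @return List with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, seg_sec = 3, overlap = 0.5) {
  n <- length(x)
  nseg <- min(n, round(seg_sec * fs))
  if (nseg < 8) stop("signal too short for a PSD estimate")
  step <- max(1, floor(nseg * (1 - overlap)))
  starts <- seq(1, n - nseg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  scale <- fs * sum(w^2)
  nf <- floor(nseg / 2) + 1
  acc <- numeric(nf)
  tt <- seq_len(nseg)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nseg - 1)]
    fit <- stats::lm.fit(cbind(1, tt), seg)       # linear detrend
    seg <- fit$residuals * w
    X <- stats::fft(seg)[seq_len(nf)]
    p <- (Mod(X)^2) / scale
    # one-sided: double all bins except DC (and Nyquist when nseg even)
    dbl <- rep(2, nf); dbl[1] <- 1
    if (nseg %% 2 == 0) dbl[nf] <- 1
    acc <- acc + p * dbl
  }
  list(freq = (seq_len(nf) - 1) * fs / nseg, psd = acc / length(starts))
}

# amplitude of the finite Fourier component of x at frequency f (Hz):
# 2/N |sum x exp(-i 2 pi f t)|
fourier_amplitude <- function(x, fs, f) {
  n <- length(x)
  t <- (seq_len(n) - 1) / fs
  x <- x - mean(x)
  E <- exp(outer(t, -2i * pi * f))
  as.numeric(2 / n * Mod(crossprod(x, E)))
}

#' Unbiased normalized autocorrelation
#'
#' Computes `A(m) = [1/(N - m)] * sum_i x_i x_(i+m)` on the mean-removed
#' signal, normalized by `A(0)` so that `A(0) = 1` exactly.  Lags are
#' restricted to at most half the signal length, where the unbiased
#' estimator is stable.
#'
#' @param x Numeric signal (non-constant).
#' @param max_lag Largest lag in samples (`<= length(x) / 2`).
#' @return Numeric vector of length `max_lag + 1` (lags `0..max_lag`).
#' @export
unbiased_autocorrelation <- function(x, max_lag) {
  n <- length(x)
  if (max_lag > n / 2) stop("max_lag must be <= length(x) / 2")
  x <- x - mean(x)
  if (all(abs(x) < 1e-300)) stop("constant signal: zero variance")
  # raw lagged sums via FFT (zero-padded linear correlation)
  nfft <- stats::nextn(2 * n, 2)
  X <- stats::fft(c(x, numeric(nfft - n)))
  s <- Re(stats::fft(Mod(X)^2, inverse = TRUE)) / nfft
  lags <- 0:max_lag
  a <- s[lags + 1] / (n - lags)
  a / a[1]
}

# zero-phase high-pass (4th-order Butterworth) with a linear-detrend
# fallback: the filter needs at least ~3 cutoff periods of data, below
# that its edge transients dominate the segment
highpass_or_detrend <- function(x, fs, cutoff_hz = 0.1) {
  n <- length(x)
  if (n > 3 * fs / cutoff_hz) {
    bf <- signal::butter(4, cutoff_hz / (fs / 2), type = "high")
    signal::filtfilt(bf, x)
  } else {
    tt <- seq_len(n)
    stats::lm.fit(cbind(1, tt), x)$residuals
  }
}

# shoelace area of a closed polygon given as an n x 2 matrix (absolute)
shoelace_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Sutherland-Hodgman clip of polygon xy against half-plane a %*% p >= b
clip_halfplane <- function(xy, a, b = 0) {
  n <- nrow(xy)
  d <- as.numeric(xy %*% a) - b
  j <- c(2:n, 1)
  keep <- d >= 0
  crossing <- xor(keep, keep[j])
  tt <- ifelse(crossing, d / (d - d[j]), 0)
  inter <- xy + tt * (xy[j, , drop = FALSE] - xy)
  # interleave original vertices (when inside) with edge intersections
  M <- matrix(0, 2 * n, 2)
  M[seq(1, 2 * n, 2), ] <- xy
  M[seq(2, 2 * n, 2), ] <- inter
  mask <- logical(2 * n)
  mask[seq(1, 2 * n, 2)] <- keep
  mask[seq(2, 2 * n, 2)] <- crossing
  M[mask, , drop = FALSE]
}
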