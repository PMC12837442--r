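#' Butterworth filter specification
#'
#' The event-detection chain uses a 4th-order 0.5 Hz high-pass (offset
#' removal) followed by a 4th-order 1.8 Hz low-pass (isolates the
#' fundamental acceleration/deceleration wave of gait); the integration
#' branch uses a 2nd-order 3.5 Hz low-pass. `order` is the design order of
#' the single-pass prototype; application is zero-phase (forward-backward),
#' so event times are not lag-shifted.
#'
#' @param kind `"highpass"` or `"lowpass"`.
#' @param order filter order (2 or 4).
#' @param cutoff_hz cutoff frequency in Hz.
#' @return list of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("highpass", "lowpass"), order, cutoff_hz) {
  kind <- match.arg(kind)
  if (!order %in% c(2L, 4L)) stop("order must be 2 or 4")
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0) stop("cutoff_hz must be positive")
  structure(list(kind = kind, order = as.integer(order), cutoff_hz = cutoff_hz),
            class = "filter_spec")
}

#' Zero-phase Butterworth filtering
#'
#' Designs a Butterworth filter from `spec` and applies it forward and
#' backward (zero phase). The signal is extended by reflective padding on
#' each side before filtering (at least 2 s, growing to several cutoff
#' periods for low cutoffs so start-up transients decay inside the pad),
#' then cropped back, so output length equals input length.
#'
#' @param x numeric signal.
#' @param spec a [filter_spec()].
#' @param fs sampling rate, Hz.
#' @return filtered signal, same length as `x`.
#' @export
butterworth_filter <- function(x, spec, fs) {
  stopifnot(inherits(spec, "filter_spec"))
  n <- length(x)
  if (n <= 3 * spec$order) stop("signal too short for the requested filter order")
  if (spec$cutoff_hz >= fs / 2) stop("cutoff at or above Nyquist frequency")
  bf <- signal::butter(spec$order, spec$cutoff_hz / (fs / 2),
                       type = switch(spec$kind, highpass = "high", lowpass = "low"))
  pad <- min(n - 1L, round(max(2 * fs, 8 * fs / spec$cutoff_hz)))
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- signal::filtfilt(bf, xp)
  y[(pad + 1):(pad + n)]
}

#' Analog Butterworth magnitude response
#'
#' \eqn{|H(f)| = 1/\sqrt{1 + (f/f_c)^{2k}}} for a single pass of an
#' order-k design; squared for the zero-phase (forward-backward)
#' application. Used as an independent oracle on attenuation.
#'
#' @param f frequency, Hz.
#' @param cutoff_hz cutoff, Hz.
#' @param order filter order.
#' @param kind `"lowpass"` or `"highpass"`.
#' @param zero_phase if `TRUE` return the two-pass magnitude.
#' @return magnitude gain(s) in (0, 1].
#' @export
butterworth_gain <- function(f, cutoff_hz, order, kind = c("lowpass", "highpass"),
                             zero_phase = FALSE) {
  kind <- match.arg(kind)
  ratio <- if (kind == "lowpass") f / cutoff_hz else cutoff_hz / f
  g <- 1 / sqrt(1 + ratio^(2 * order))
  if (zero_phase) g^2 else g
}

#' Locomotion frequency band (QC)
#'
#' Time-averaged spectral analysis of anteroposterior acceleration via a
#' continuous wavelet transform (complex Morlet), reporting where the
#' dominant locomotor power sits in 0.5-3 Hz. In steady adult gait the
#' fundamental falls in roughly 1.5-1.8 Hz. This is a quality-control
#' estimate only: the fixed 0.5/1.8 Hz detection cutoffs are not adapted
#' to it.
#'
#' @param acc_ap anteroposterior acceleration, m/s^2.
#' @param fs sampling rate, Hz.
#' @param f_range search range in Hz, default `c(0.5, 3)`.
#' @param n_freq number of frequency voices.
#' @param omega0 Morlet centre frequency parameter (frequency resolution
#'   grows with it); the default favours frequency over time resolution.
#' @return list of class `spectral_band`: `f_lo`, `f_hi`, `dominant_f` (Hz),
#'   `power` (per-frequency mean power), `freqs`, and `clear_peak` (FALSE,
#'   with a warning, when no frequency clearly dominates).
#' @export
locomotion_band <- function(acc_ap, fs, f_range = c(0.5, 3), n_freq = 48L,
                            omega0 = 8) {
  n <- length(acc_ap)
  if (n < 5 * fs) stop("signal too short: need at least 5 s for band estimation")
  x <- acc_ap - mean(acc_ap)
  freqs <- exp(seq(log(f_range[1]), log(f_range[2]), length.out = n_freq))
  nfft <- stats::nextn(2L * n, 2)
  X <- stats::fft(c(x, rep(0, nfft - n)))
  fgrid <- (0:(nfft - 1)) / nfft * fs
  pow <- vapply(freqs, function(f0) {
    s <- omega0 / (2 * pi * f0)               # wavelet scale, seconds
    # Morlet in the frequency domain: Gaussian around f0 (analytic, f>0)
    H <- exp(-2 * pi^2 * s^2 * (fgrid - f0)^2)
    H[fgrid > fs / 2] <- 0
    w <- stats::fft(X * H, inverse = TRUE) / nfft
    mean(Mod(w[seq_len(n)])^2)
  }, numeric(1))
  imax <- which.max(pow)
  dominant <- freqs[imax]
  # band: contiguous frequencies above half the peak power
  above <- pow >= 0.5 * pow[imax]
  lo <- imax; while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- imax; while (hi < n_freq && above[hi + 1]) hi <- hi + 1
  clear <- (pow[imax] / stats::median(pow)) > 20
  if (!clear) warning("no clear locomotor peak in ", f_range[1], "-",
                      f_range[2], " Hz")
  structure(list(f_lo = freqs[lo], f_hi = freqs[hi], dominant_f = dominant,
                 freqs = freqs, power = pow, clear_peak = clear),
            class = "spectral_band")
}

#' FFT-bin high-pass with phase realignment
#'
#' Removes the offset and low-frequency wander of the yaw series directly in
#' the frequency domain: all FFT bins with |f| below `cutoff_hz` (DC
#' included, conjugate partners handled symmetrically) are zeroed and the
#' signal reconstructed by inverse FFT. The output is then realigned to the
#' input by maximizing circular cross-correlation and applying the
#' corresponding circular shift. With `n_bins` the literal fixed-bin variant
#' (zero the first `n_bins` positive-frequency components regardless of
#' record length) is available.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param cutoff_hz cutoff frequency, Hz (default 0.25).
#' @param n_bins optional integer; if given, zero exactly this many
#'   positive-frequency bins (plus DC) instead of using `cutoff_hz`.
#' @return filtered signal, same length, zero mean.
#' @export
fft_bin_highpass <- function(x, fs, cutoff_hz = 0.25, n_bins = NULL) {
  n <- length(x)
  if (n < 4L) stop("signal too short for FFT filtering")
  if (is.null(n_bins)) {
    if (cutoff_hz >= fs / 2) stop("cutoff at or above Nyquist frequency")
    k <- ceiling(cutoff_hz * n / fs)   # positive-frequency bins below cutoff
  } else {
    k <- as.integer(n_bins)
  }
  X <- stats::fft(x)
  X[1] <- 0                            # DC
  if (k >= 1) {
    kk <- seq_len(min(k, floor((n - 1) / 2)))
    X[1 + kk] <- 0                     # positive frequencies
    X[n + 1 - kk] <- 0                 # conjugate partners
  }
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  # realign by circular cross-correlation (bins were zeroed in place, so the
  # optimum is the zero shift; kept for fidelity to the procedure)
  cc <- Re(stats::fft(stats::fft(x - mean(x)) * Conj(stats::fft(y)),
                      inverse = TRUE)) / n
  lag <- which.max(cc) - 1L
  if (lag != 0L) y <- c(y[(n - lag + 1):n], y[seq_len(n - lag)])
  y
}
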