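#' Gaussian transmit pulse spectrum
#'
#' Gaussian magnitude spectrum centred at `center_frequency` whose -6 dB
#' full width equals `fractional_bandwidth * center_frequency` (the usual
#' transducer bandwidth convention), with zero phase: focal delays carry all
#' timing. Peak normalized to 1.
#'
#' @param center_frequency Hz.
#' @param fractional_bandwidth -6 dB full width divided by the centre
#'   frequency, in `(0, 2)`.
#' @param freq_axis frequency bins, Hz, at which the spectrum is tabulated.
#' @return an object of class `pulse` with fields `center_frequency`,
#'   `fractional_bandwidth`, `spectrum` (complex), `freq_axis`, `sigma_f`.
#' @export
gaussian_pulse_spectrum <- function(center_frequency, fractional_bandwidth,
                                    freq_axis) {
  stopifnot(center_frequency > 0,
            fractional_bandwidth > 0, fractional_bandwidth < 2)
  sigma_f <- pulse_sigma_f(center_frequency, fractional_bandwidth)
  sp <- exp(-(freq_axis - center_frequency)^2 / (2 * sigma_f^2)) + 0i
  structure(list(center_frequency = center_frequency,
                 fractional_bandwidth = fractional_bandwidth,
                 spectrum = sp, freq_axis = freq_axis, sigma_f = sigma_f),
            class = "pulse")
}

#' @export
print.pulse <- function(x, ...) {
  cat(sprintf("Gaussian pulse: f0 = %.2f MHz, %.0f%% fractional bandwidth (-6 dB)\n",
              1e-6 * x$center_frequency, 100 * x$fractional_bandwidth))
  invisible(x)
}

# spectral standard deviation for a -6 dB full width of fbw * f0
pulse_sigma_f <- function(center_frequency, fractional_bandwidth) {
  fractional_bandwidth * center_frequency / (2 * sqrt(2 * log(2)))
}

#' Time-domain pulse waveform
#'
#' The Gaussian-modulated cosine whose spectrum (analysis convention
#' `exp(-2i*pi*f*t)`) matches [gaussian_pulse_spectrum]:
#' `s(t) = cos(2*pi*f0*t) * exp(-t^2 / (2*sigma_t^2))` with
#' `sigma_t = 1/(2*pi*sigma_f)`. The envelope peak is at `t = 0`.
#'
#' @param t times, seconds.
#' @param center_frequency Hz.
#' @param fractional_bandwidth as in [gaussian_pulse_spectrum].
#' @return numeric vector of pressures (arbitrary units, peak 1 at t = 0).
#' @export
pulse_waveform <- function(t, center_frequency, fractional_bandwidth) {
  sigma_t <- 1 / (2 * pi * pulse_sigma_f(center_frequency, fractional_bandwidth))
  cos(2 * pi * center_frequency * t) * exp(-t^2 / (2 * sigma_t^2))
}

# sampled waveform table for the reference simulator; covers the support
# down to ~1e-8 of the peak. `kind = "line"` applies the far-field 2-D
# line-source filter sqrt(f0/f) * exp(-1i*pi/4) (half time-integral with a
# -45 degree phase), the shape a cylindrically spreading wave carries.
# `derivative = TRUE` additionally applies the time-derivative filter
# 1i*f/f0 that relates radiated pressure to a piston source's surface
# waveform (equivalently, to a pressure distribution prescribed on the
# source surface).
pulse_table <- function(center_frequency, fractional_bandwidth,
                        dt = 1 / (32 * center_frequency),
                        kind = c("point", "line"), derivative = FALSE) {
  kind <- match.arg(kind)
  sigma_t <- 1 / (2 * pi * pulse_sigma_f(center_frequency, fractional_bandwidth))
  half <- 5 * sigma_t   # envelope truncated below 4e-6 of the peak
  if (kind == "point" && !derivative) {
    tt <- seq(-half, half, by = dt)
    return(list(t = tt, s = pulse_waveform(tt, center_frequency,
                                           fractional_bandwidth), dt = dt))
  }
  # synthesize via a dense one-sided spectrum
  n <- 2^ceiling(log2(4 * (2 * half / dt)))
  fs <- 1 / dt
  f <- fft_freqs(n, dt)
  pos <- f > 0
  P <- numeric(n) + 0i
  sigma_f <- pulse_sigma_f(center_frequency, fractional_bandwidth)
  P[pos] <- exp(-(f[pos] - center_frequency)^2 / (2 * sigma_f^2))
  if (kind == "line")
    P[pos] <- P[pos] * sqrt(center_frequency / f[pos]) * exp(-1i * pi / 4)
  if (derivative)
    P[pos] <- P[pos] * (1i * f[pos] / center_frequency)
  s_full <- 2 * Re(fft(P, inverse = TRUE)) / n
  # fft's inverse places t = 0 at the first sample; recentre on [-half, half]
  tt_all <- (seq_len(n) - 1) / fs
  tt_all[tt_all >= n / fs / 2] <- tt_all[tt_all >= n / fs / 2] - n / fs
  ord <- order(tt_all)
  selmask <- abs(tt_all[ord]) <= half
  s <- s_full[ord][selmask]
  list(t = tt_all[ord][selmask], s = s / max(abs(s)), dt = dt)
}

#' Analytic signal of real traces
#'
#' FFT-based analytic signal (negative frequencies zeroed, positive doubled)
#' of each column of `x`.
#'
#' @param x real vector or matrix (time along rows).
#' @return complex vector/matrix of the same shape.
#' @export
analytic_signal <- function(x) {
  v <- if (is.matrix(x)) x else matrix(x, ncol = 1L)
  n <- nrow(v)
  X <- mvfft(v)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  out <- mvfft(X * h, inverse = TRUE) / n
  if (is.matrix(x)) out else drop(out)
}

# one-sided band spectra of real traces: columns of x are traces sampled at
# fs starting at absolute time t0; returns spectra at the band's bin
# frequencies, phase-referenced to absolute time zero.
traces_to_band_spectra <- function(x, fs, t0, band_idx = NULL, freqs = NULL) {
  v <- if (is.matrix(x)) x else matrix(x, ncol = 1L)
  n <- nrow(v)
  f_all <- (seq_len(n) - 1) * fs / n
  if (is.null(band_idx)) band_idx <- which(f_all > 0 & f_all < fs / 2)
  X <- mvfft(v)[band_idx, , drop = FALSE]
  f <- f_all[band_idx]
  X * exp(-2i * pi * f * t0)
}

# inverse of traces_to_band_spectra: one-sided band spectra back to real
# traces of length n_t sampled at fs from absolute time t0.
band_spectra_to_traces <- function(X, band_idx, n_t, fs, t0 = 0) {
  v <- if (is.matrix(X)) X else matrix(X, ncol = 1L)
  f <- (band_idx - 1) * fs / n_t
  full <- matrix(0 + 0i, n_t, ncol(v))
  full[band_idx, ] <- v * exp(2i * pi * f * t0)
  out <- 2 * Re(mvfft(full, inverse = TRUE)) / n_t
  if (is.matrix(X)) out else drop(out)
}
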