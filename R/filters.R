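## Frequency filtering of whole runs. Filters are applied causally (single
## forward pass) by default, matching an online acquisition chain; a
## zero-phase forward-backward mode is available. Runs are filtered before
## epoching so the 1-s analysis windows carry no edge transients.

# apply an IIR filter (b, a) to every channel of a recording
.filter_rec <- function(rec, b, a, zero_phase) {
  filt <- signal::Arma(b = b, a = a)
  out <- t(apply(rec$samples, 1, function(x) {
    if (zero_phase) signal::filtfilt(filt, x) else signal::filter(filt, x)
  }))
  eeg_recording(out, rec$labels, rec$rate)
}

#' Design a second-order IIR notch (band-reject) filter
#'
#' Constrained biquad with unit gain at DC and Nyquist and a zero pair on the
#' unit circle at the notch frequency; `q` sets the -3 dB rejection
#' bandwidth `freq / q`.
#'
#' @param freq Notch centre frequency in Hz.
#' @param rate Sampling rate in Hz.
#' @param q Quality factor (dimensionless); default 35 gives a ~1.4 Hz
#'   band at 50 Hz, a standard mains-rejection design.
#' @return List with numerator `b` and denominator `a` coefficients.
#' @export
notch_coefficients <- function(freq, rate, q = 35) {
  stopifnot(freq > 0, rate > 0, q > 0)
  if (freq >= rate / 2) stop("notch frequency must be below the Nyquist rate")
  w0 <- 2 * pi * freq / rate
  beta <- tan(w0 / (2 * q))
  g <- 1 / (1 + beta)
  list(b = g * c(1, -2 * cos(w0), 1),
       a = c(1, -2 * g * cos(w0), 2 * g - 1))
}

#' Notch-filter a recording (mains interference rejection)
#'
#' Applies the biquad of [notch_coefficients()] to every channel, removing
#' narrow-band power-line interference while leaving the rest of the
#' spectrum essentially untouched.
#'
#' @param rec An `eeg_recording`.
#' @param freq Centre frequency in Hz (default 50, European mains).
#' @param q Quality factor, see [notch_coefficients()].
#' @param zero_phase Apply forward-backward for zero phase distortion
#'   (default `FALSE`: causal single pass).
#' @return Filtered `eeg_recording` of identical shape.
#' @export
notch_filter <- function(rec, freq = 50, q = 35, zero_phase = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"))
  co <- notch_coefficients(freq, rec$rate, q)
  .filter_rec(rec, co$b, co$a, zero_phase)
}

#' Butterworth band-pass filter a recording
#'
#' Digital Butterworth band-pass (bilinear transform) of the stated overall
#' order, applied to every channel. The default 5--40 Hz order-8 band keeps
#' the mu (8--12 Hz) and beta (13--30 Hz) rhythms while removing the DC
#' component, drift and high-frequency noise.
#'
#' @param rec An `eeg_recording`.
#' @param low,high Band edges in Hz, `0 < low < high < rate/2`.
#' @param order Overall filter order (even; default 8).
#' @param zero_phase Forward-backward filtering (default `FALSE`: causal).
#' @return Filtered `eeg_recording` of identical shape.
#' @export
bandpass_filter <- function(rec, low = 5, high = 40, order = 8,
                            zero_phase = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(low > 0 && low < high && high < rec$rate / 2)) {
    stop("invalid band: need 0 < low < high < rate/2")
  }
  if (order %% 2 != 0 || order < 2) {
    stop("band-pass order must be a positive even number")
  }
  bt <- signal::butter(order / 2, c(low, high) / (rec$rate / 2), type = "pass")
  .filter_rec(rec, bt$b, bt$a, zero_phase)
}

#' Standard preprocessing chain for one run
#'
#' Notch, band-pass, then surface Laplacian, in acquisition order: frequency
#' filters clean each channel, after which the spatial reference sharpens
#' local activity.
#'
#' @param rec An `eeg_recording`.
#' @param w An `erd_laplacian` matching the recording's channels.
#' @param config Processing settings, see [default_config()].
#' @return Preprocessed `eeg_recording`.
#' @export
preprocess_recording <- function(rec, w, config = default_config()) {
  rec <- notch_filter(rec, freq = config$notch_freq, q = config$notch_q,
                      zero_phase = config$zero_phase)
  rec <- bandpass_filter(rec, low = config$band[1], high = config$band[2],
                         order = config$filter_order,
                         zero_phase = config$zero_phase)
  apply_laplacian(rec, w)
}
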