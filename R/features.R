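## Band-power features: FFT of each 1-s epoch (256 samples at 256 Hz gives
## exactly 1-Hz bins), one-sided power spectrum, then per-channel sums over
## the mu (8-12 Hz) and split beta (13-24, 25-30 Hz) bands -> 48 features.

#' Frequency-band scheme for the band-sum features
#'
#' @param bands List of `c(low, high)` integer band edges in Hz, inclusive
#'   at 1-Hz resolution. Default: mu 8--12 Hz and the beta band split into
#'   13--24 Hz and 25--30 Hz.
#' @return A `band_scheme` object.
#' @export
band_scheme <- function(bands = list(c(8, 12), c(13, 24), c(25, 30))) {
  stopifnot(is.list(bands), length(bands) >= 1)
  edges <- do.call(rbind, lapply(bands, function(b) {
    stopifnot(length(b) == 2, b[1] <= b[2], b[1] > 0, b[2] < 128)
    as.numeric(b)
  }))
  if (nrow(edges) > 1) {
    o <- order(edges[, 1])
    edges <- edges[o, , drop = FALSE]
    if (any(edges[-1, 1] <= edges[-nrow(edges), 2])) {
      stop("bands must be disjoint")
    }
  }
  structure(list(edges = edges), class = "band_scheme")
}

# names like "8_12" for each band
.band_names <- function(scheme) {
  apply(scheme$edges, 1, function(b) paste0(b[1], "_", b[2]))
}

#' One-sided power spectrum of a 1-s epoch
#'
#' Plain (untapered) FFT of each channel with power normalization
#' `P(f) = |X(f)|^2 / N^2`, doubling all bins except DC and Nyquist, so that
#' the spectrum sums to the mean squared amplitude (Parseval). With 256
#' samples at 256 Hz the bins fall exactly on integer frequencies 0..128 Hz.
#'
#' @param epoch Channels x samples numeric matrix (one second of signal).
#' @param rate Sampling rate in Hz; must equal the number of samples so the
#'   resolution is exactly 1 Hz.
#' @param taper Optional Hann taper before the FFT (default `FALSE`).
#' @return Channels x (N/2 + 1) matrix of power at 0..rate/2 Hz; columns
#'   named by frequency.
#' @export
power_spectrum <- function(epoch, rate = 256, taper = FALSE) {
  epoch <- as.matrix(epoch)
  n <- ncol(epoch)
  if (n != rate) {
    stop("epoch must contain exactly one second of signal (", rate,
         " samples), got ", n)
  }
  if (taper) {
    w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
    w <- w / sqrt(mean(w^2))  # preserve broadband power
    epoch <- sweep(epoch, 2, w, `*`)
  }
  X <- t(apply(epoch, 1, stats::fft))
  if (nrow(epoch) == 1) X <- matrix(X, nrow = 1)
  p <- Mod(X[, 1:(n / 2 + 1), drop = FALSE])^2 / n^2
  p[, 2:(n / 2)] <- 2 * p[, 2:(n / 2), drop = FALSE]
  colnames(p) <- 0:(n / 2)
  rownames(p) <- rownames(epoch)
  p
}

#' Sum a power spectrum into band features
#'
#' For each channel and each band of the scheme, sums the power at the
#' integer frequencies from the low to the high edge inclusive. On the
#' 16-channel montage with the default three bands this yields the
#' 48-dimensional feature vector.
#'
#' @param spectrum Channels x frequencies power matrix from
#'   [power_spectrum()] (columns named by frequency in Hz).
#' @param scheme A [band_scheme()].
#' @return Named numeric vector, channel-major then band
#'   (e.g. `Cz_8_12, Cz_13_24, Cz_25_30, ...`).
#' @export
band_features <- function(spectrum, scheme = band_scheme()) {
  stopifnot(inherits(scheme, "band_scheme"))
  freqs <- as.numeric(colnames(spectrum))
  if (max(scheme$edges) > max(freqs) || min(scheme$edges) < min(freqs)) {
    stop("band outside spectrum support")
  }
  chans <- rownames(spectrum)
  if (is.null(chans)) chans <- paste0("ch", seq_len(nrow(spectrum)))
  bn <- .band_names(scheme)
  vals <- lapply(seq_len(nrow(spectrum)), function(i) {
    vapply(seq_len(nrow(scheme$edges)), function(b) {
      sum(spectrum[i, freqs >= scheme$edges[b, 1] & freqs <= scheme$edges[b, 2]])
    }, numeric(1))
  })
  out <- unlist(vals)
  names(out) <- as.vector(t(outer(chans, bn, paste, sep = "_")))
  out
}

#' Compute the feature table for a set of epochs
#'
#' Runs [power_spectrum()] and [band_features()] on every epoch and binds
#' the results with the epoch metadata into one analysis-ready data frame.
#'
#' @param epochs An `erd_epochs` object.
#' @param scheme A [band_scheme()].
#' @param taper Hann-taper the epochs before the FFT (default `FALSE`).
#' @return Data frame: `label`, `run_id`, `t0`, `flagged`, then one numeric
#'   column per feature (channels x bands).
#' @export
epoch_features <- function(epochs, scheme = band_scheme(), taper = FALSE) {
  stopifnot(inherits(epochs, "erd_epochs"))
  feats <- t(vapply(epochs$samples, function(m) {
    band_features(power_spectrum(m, rate = epochs$rate, taper = taper), scheme)
  }, numeric(length(epochs$labels) * nrow(scheme$edges))))
  cbind(epochs$info, as.data.frame(feats))
}

# names of the feature columns in a feature table
.feature_cols <- function(df) {
  setdiff(colnames(df), c("label", "run_id", "t0", "flagged", "subject"))
}
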