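# Shared fixtures: tiny recordings, toy training sets and a cached small
# simulated session (built once per test run).

fix_montage <- build_montage()

# single-channel recording from a vector (labelled Cz by default)
rec1 <- function(x, label = "Cz", rate = 256) {
  eeg_recording(matrix(x, nrow = 1), label, rate)
}

# pure tone of `secs` seconds
tone <- function(freq, secs = 4, rate = 256, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * seq(0, secs * rate - 1) / rate + phase)
}

# steady-state RMS gain of a filtered tone (drop the first half as transient)
rms_gain <- function(rec_out, rec_in) {
  n <- ncol(rec_in$samples)
  keep <- (n %/% 2):n
  sqrt(mean(rec_out$samples[1, keep]^2) / mean(rec_in$samples[1, keep]^2))
}

# analytic magnitude of the digital Butterworth band-pass (bilinear
# transform): lowpass prototype |H|^2 = 1/(1 + W^2N) evaluated at the
# warped band-pass frequency variable
butter_bp_gain <- function(f, low, high, order, rate) {
  v <- tan(pi * f / rate)
  vl <- tan(pi * low / rate)
  vh <- tan(pi * high / rate)
  W <- (v^2 - vl * vh) / (v * (vh - vl))
  1 / sqrt(1 + W^(2 * (order / 2)))
}

# analytic magnitude of the constrained biquad notch at frequency f
notch_gain <- function(f, freq, rate, q = 35) {
  w0 <- 2 * pi * freq / rate
  beta <- tan(w0 / (2 * q))
  g <- 1 / (1 + beta)
  z <- exp(-1i * 2 * pi * f / rate)
  num <- g * (1 - 2 * cos(w0) * z + z^2)
  den <- 1 - 2 * g * cos(w0) * z + (2 * g - 1) * z^2
  Mod(num / den)
}

# two separable Gaussian blobs in `d` dimensions
blobs <- function(n = 40, d = 2, sep = 4, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n / 2 * d), ncol = d),
             matrix(stats::rnorm(n / 2 * d, mean = sep / sqrt(d)), ncol = d))
  y <- rep(c(-1, 1), each = n / 2)
  list(X = X, y = y)
}

# small session reused by several test files (3 runs, moderate effect)
small_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_session(
        erd_params(n_runs = 3, run_s = 64, erd_depth = 0.6, seed = 11))
    }
    cache
  }
})
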