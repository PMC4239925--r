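## Synthetic ERD sessions reproducing the cued reaching protocol: runs of
## 256 s made of 32 trials (3-s rest cross + 5-s movement point); the
## subject moves 1-3 s after the point appears; mu (10 Hz) and beta (20 Hz)
## oscillations over the central electrodes lose a fraction rho of their
## amplitude from erd_lead seconds before movement onset until the movement
## ends. Background is per-channel pink (1/f) noise plus a small component
## shared across channels (so the Laplacian has something to cancel) and an
## optional 50-Hz mains tone.

#' Parameters of the synthetic ERD session generator
#'
#' Defaults reproduce the cued-reaching study conditions: 6 runs of 256 s,
#' 3 s cross + 5 s point per trial, movement onset uniform 1--3 s after the
#' point appears, and an ERD (amplitude attenuation of the mu and beta
#' oscillations) starting 1.5 s before the onset — within the up-to-2-s
#' lead that precedes a voluntary movement.
#'
#' @param n_runs Runs per session (folds of the cross-validation).
#' @param run_s Run length in seconds.
#' @param cross_s,point_s Rest-cue and movement-cue durations in seconds.
#' @param onset_delay Range (s) of the uniform movement-onset delay after
#'   the point appears.
#' @param erd_depth Fractional mu/beta amplitude attenuation rho in [0, 1];
#'   0 = no effect, 1 = oscillations fully suppressed.
#' @param erd_lead Seconds before onset at which attenuation starts
#'   (>= 1 so the whole pre-movement window is attenuated).
#' @param erd_ramp Seconds over which the attenuation ramps in linearly
#'   (0 = abrupt, the default; the physiological time course is unknown).
#' @param mu_freq,beta_freq Oscillation frequencies in Hz.
#' @param mu_amp,beta_amp Oscillation amplitudes in microvolts at the
#'   spatial-profile peak.
#' @param noise_rms Per-channel pink-noise RMS in microvolts.
#' @param shared_rms RMS of the pink component common to all channels.
#' @param mains_amp Amplitude of the injected 50-Hz mains tone (microvolts).
#' @param move_s Duration of the reach (forward then back) in seconds.
#' @param eeg_rate,cursor_rate Sampling rates in Hz.
#' @param seed Integer seed; every source of randomness flows from it.
#' @return An `erd_params` object.
#' @export
erd_params <- function(n_runs = 6, run_s = 256, cross_s = 3, point_s = 5,
                       onset_delay = c(1, 3), erd_depth = 0.5,
                       erd_lead = 1.5, erd_ramp = 0,
                       mu_freq = 10, beta_freq = 20,
                       mu_amp = 4, beta_amp = 3,
                       noise_rms = 10, shared_rms = 2, mains_amp = 0.5,
                       move_s = 3, eeg_rate = 256, cursor_rate = 16,
                       seed = 1) {
  stopifnot(erd_depth >= 0, erd_depth <= 1, erd_lead >= 1, erd_ramp >= 0,
            mu_amp > 0, beta_amp > 0, noise_rms >= 0, shared_rms >= 0,
            mains_amp >= 0, n_runs >= 1,
            onset_delay[1] >= 1, onset_delay[2] >= onset_delay[1],
            onset_delay[2] <= point_s - 1)
  if (eeg_rate %% cursor_rate != 0) {
    stop("EEG rate must be an integer multiple of the cursor rate")
  }
  if (run_s %% (cross_s + point_s) != 0) {
    stop("run length must hold an integer number of trials")
  }
  structure(as.list(environment()), class = "erd_params")
}

# per-channel oscillation gain: 1 at the central row (C3, Cz, C4), lower on
# the neighbouring fronto-central/centro-parietal rows, lowest frontal and
# parietal -- a coarse sensorimotor spatial profile
.spatial_profile <- function(labels) {
  g <- rep(0.3, length(labels))
  names(g) <- labels
  g[labels %in% c("C3", "Cz", "C4")] <- 1
  g[grepl("^FC", labels) | grepl("^CP", labels)] <- 0.6
  g
}

#' Pink (1/f) noise
#'
#' Spectral-shaping generator: white Gaussian spectrum scaled by
#' `1/sqrt(f)`, inverse-transformed and normalized to the requested RMS.
#' Consumes the R random stream (seed it for reproducibility).
#'
#' @param n Number of samples.
#' @param rms Target root-mean-square amplitude.
#' @return Numeric vector of length `n`.
#' @export
pink_noise <- function(n, rms = 1) {
  if (rms == 0) return(numeric(n))
  nf <- floor(n / 2)
  amp <- 1 / sqrt(seq_len(nf))
  z <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) * amp
  spec <- complex(length.out = n)
  spec[2:(nf + 1)] <- z
  spec[n:(n - nf + 2)] <- Conj(z[seq_len(nf - 1)])
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x <- x - mean(x)
  x * rms / stats::sd(x)
}

# attenuation envelope A(t) for one run
.erd_envelope <- function(t, onsets, p) {
  A <- rep(1, length(t))
  for (on in onsets) {
    a0 <- on - p$erd_lead
    a1 <- on + p$move_s
    if (p$erd_ramp > 0) {
      ramp <- t >= a0 - p$erd_ramp & t < a0
      A[ramp] <- pmin(A[ramp], 1 - p$erd_depth * (t[ramp] - (a0 - p$erd_ramp)) / p$erd_ramp)
    }
    inside <- t >= a0 & t <= a1
    A[inside] <- 1 - p$erd_depth
  }
  A
}

#' Simulate one session of the cued reaching protocol
#'
#' Generates per run a 16-channel EEG recording and the matching 16-Hz
#' cursor trace, plus the ground truth (true onsets and movement flags).
#' Per channel c: `x_c(t) = noise_c(t) + shared(t) + mains(t) +
#' g_c A(t) [mu_amp sin(2 pi f_mu t + phi_c) + beta_amp sin(2 pi f_beta t +
#' psi_c)]` with `A(t) = 1 - rho` from `onset - erd_lead` to movement end
#' and 1 elsewhere. Identical seed gives bit-identical output.
#'
#' @param params An [erd_params()] object.
#' @param montage An `erd_montage` providing the channel set.
#' @param subject Subject identifier stored in the session.
#' @return An `erd_session`: list with `runs` (each holding `eeg`, an
#'   `eeg_recording`, and `cursor`, a `cursor_trace`), `truth` (data frame of
#'   true onsets per run/trial), `params`, `subject` and channel `labels`.
#' @export
simulate_session <- function(params = erd_params(), montage = build_montage(),
                             subject = "S1") {
  stopifnot(inherits(params, "erd_params"))
  p <- params
  set.seed(p$seed)
  labels <- montage$labels
  gains <- .spatial_profile(labels)
  n <- p$run_s * p$eeg_rate
  t_eeg <- seq(0, n - 1) / p$eeg_rate
  n_cur <- p$run_s * p$cursor_rate
  t_cur <- seq(0, n_cur - 1) / p$cursor_rate
  trial_s <- p$cross_s + p$point_s
  n_trials <- p$run_s %/% trial_s
  runs <- vector("list", p$n_runs)
  truth <- NULL
  for (r in seq_len(p$n_runs)) {
    point_starts <- (seq_len(n_trials) - 1) * trial_s + p$cross_s
    # onset delays on the cursor sampling grid so the trace and truth agree
    delays <- stats::runif(n_trials, p$onset_delay[1], p$onset_delay[2])
    delays <- round(delays * p$cursor_rate) / p$cursor_rate
    onsets <- point_starts + delays
    A <- .erd_envelope(t_eeg, onsets, p)
    shared <- pink_noise(n, p$shared_rms) +
      p$mains_amp * sin(2 * pi * 50 * t_eeg)
    sam <- matrix(0, length(labels), n)
    for (ci in seq_along(labels)) {
      # per-channel oscillation phase jitter keeps channels non-identical
      ph <- stats::runif(2, 0, 2 * pi)
      osc_c <- p$mu_amp * sin(2 * pi * p$mu_freq * t_eeg + ph[1]) +
        p$beta_amp * sin(2 * pi * p$beta_freq * t_eeg + ph[2])
      sam[ci, ] <- pink_noise(n, p$noise_rms) + shared +
        gains[ci] * A * osc_c
    }
    # cursor: y rises half-cosine to 500 units over move_s/2, then returns
    y <- numeric(n_cur)
    phase <- ifelse((t_cur %% trial_s) < p$cross_s, "cross", "point")
    for (on in onsets) {
      half <- p$move_s / 2
      fwd <- t_cur >= on & t_cur < on + half
      bck <- t_cur >= on + half & t_cur < on + p$move_s
      y[fwd] <- 500 * (1 - cos(pi * (t_cur[fwd] - on) / half)) / 2
      y[bck] <- 500 * (1 + cos(pi * (t_cur[bck] - on - half) / half)) / 2
    }
    runs[[r]] <- list(
      eeg = eeg_recording(sam, labels, p$eeg_rate),
      cursor = cursor_trace(t_cur, rep(0, n_cur), y, phase, p$cursor_rate))
    truth <- rbind(truth, data.frame(
      run_id = paste0("run", r), trial = seq_len(n_trials),
      point_start_s = point_starts, onset_s = onsets, moved = TRUE))
  }
  names(runs) <- paste0("run", seq_len(p$n_runs))
  structure(list(runs = runs, truth = truth, params = p, subject = subject,
                 labels = labels), class = "erd_session")
}

#' @export
print.erd_session <- function(x, ...) {
  cat(sprintf(
    "<erd_session> subject %s: %d runs x %g s, %d channels, erd_depth %.2f\n",
    x$subject, length(x$runs), x$params$run_s, length(x$labels),
    x$params$erd_depth))
  invisible(x)
}

#' Features for a whole session
#'
#' Preprocesses every run (notch, band-pass, Laplacian), reconstructs the
#' trials from the cursor trace, cuts the pre-movement and rest epochs and
#' computes the band-power feature table.
#'
#' @param session An `erd_session` (simulated or read from disk).
#' @param montage The electrode montage; defaults to the session's channels.
#' @param scheme A [band_scheme()].
#' @param config Processing settings, see [default_config()].
#' @return Feature data frame across all runs (one row per epoch).
#' @export
session_features <- function(session, montage = build_montage(session$labels),
                             scheme = band_scheme(),
                             config = default_config()) {
  w <- laplacian_weights(montage)
  eps <- lapply(names(session$runs), function(rn) {
    run <- session$runs[[rn]]
    rec <- preprocess_recording(run$eeg, w, config)
    ons <- detect_onsets(run$cursor, threshold = config$cursor_threshold)
    extract_epochs(rec, run$cursor, ons, run_id = rn)
  })
  df <- epoch_features(.bind_epochs(eps), scheme, taper = config$taper)
  df$subject <- session$subject
  df
}

#' Benchmark a session with the seven classifiers
#'
#' Runs leave-one-run-out cross-validation for every classifier
#' specification and aggregates the rates.
#'
#' @param session An `erd_session`, or a precomputed feature table.
#' @param specs Named list of [classifier_spec()]s
#'   (default [paper_classifiers()]).
#' @param normalize Fold-wise feature z-scoring (default `FALSE`).
#' @param ... Passed to [session_features()] when `session` is a session.
#' @return List with `folds` (per-classifier fold rates) and `summary`
#'   (see [summarize_benchmark()]).
#' @export
benchmark_session <- function(session, specs = paper_classifiers(),
                              normalize = FALSE, ...) {
  features <- if (inherits(session, "erd_session")) {
    session_features(session, ...)
  } else session
  subject <- if (!is.null(features$subject)) features$subject[1] else "S1"
  folds <- do.call(rbind, lapply(names(specs), function(nm) {
    fm <- cross_validate(features, specs[[nm]], normalize = normalize)
    cbind(classifier = nm, subject = subject, fm)
  }))
  list(folds = folds, summary = summarize_benchmark(folds))
}

#' Measure the realized ERD through the full analysis chain
#'
#' Quantifies the injected effect as seen by the classifier: the ratio of
#' mean pre-movement to mean rest band power, per channel and band, after
#' preprocessing, epoching and feature extraction. A ratio of 1 means no
#' effect; an attenuation of depth rho at an oscillation-dominated channel
#' gives about `(1 - rho)^2` in that oscillation's band.
#'
#' @inheritParams session_features
#' @return List with `per_channel` (channels x bands ratio matrix) and
#'   `per_band` (ratio of grand-mean band power, named by band).
#' @export
effect_audit <- function(session, montage = build_montage(session$labels),
                         scheme = band_scheme(),
                         config = default_config()) {
  df <- session_features(session, montage, scheme, config)
  fcols <- .feature_cols(df)
  pre <- colMeans(df[df$label == "pre_movement", fcols, drop = FALSE])
  rest <- colMeans(df[df$label == "rest", fcols, drop = FALSE])
  ratio <- pre / rest
  bn <- .band_names(scheme)
  per_channel <- matrix(ratio, ncol = length(bn), byrow = TRUE,
                        dimnames = list(session$labels, bn))
  per_band <- vapply(bn, function(b) {
    sel <- endsWith(names(pre), b)
    sum(pre[sel]) / sum(rest[sel])
  }, numeric(1))
  list(per_channel = per_channel, per_band = per_band)
}
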