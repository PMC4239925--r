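## Trial reconstruction from the cursor trace and epoching.
##
## The cued protocol alternates a 3-s rest cross with a 5-s movement point;
## the subject reaches forward and back with the mouse some time (>= 1 s by
## instruction) after the point appears. Movement onset is the first cursor
## sample that leaves the resting position; the 1-s EEG window before it is
## a pre-movement epoch, and the centred second of each cross period is a
## rest epoch.

#' Cursor trace container
#'
#' @param time_s Sample times in seconds (16 Hz grid).
#' @param x,y Cursor screen coordinates.
#' @param phase Per-sample interface state, `"cross"` (rest cue) or
#'   `"point"` (movement cue).
#' @param rate Sampling rate in Hz; the interface samples at 16 Hz.
#' @return A `cursor_trace` object.
#' @export
cursor_trace <- function(time_s, x, y, phase, rate = 16) {
  n <- length(time_s)
  stopifnot(length(x) == n, length(y) == n, length(phase) == n, rate > 0)
  phase <- as.character(phase)
  if (!all(phase %in% c("cross", "point"))) {
    stop("cursor phase must be 'cross' or 'point'")
  }
  structure(list(time_s = as.numeric(time_s), x = as.numeric(x),
                 y = as.numeric(y), phase = phase, rate = rate),
            class = "cursor_trace")
}

# contiguous segments of a given phase: data.frame(start_s, end_s) with
# end exclusive
.phase_segments <- function(trace, which) {
  r <- rle(trace$phase)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values == which
  data.frame(start_s = trace$time_s[starts[keep]],
             end_s = trace$time_s[ends[keep]] + 1 / trace$rate)
}

#' Detect movement onsets from the cursor trace
#'
#' Within each movement-cue (point) segment, the onset is the first cursor
#' sample whose Euclidean displacement from the segment's starting position
#' exceeds `threshold`. Onsets are reported both on the cursor clock and as
#' EEG sample indices (exact 16:1 rate ratio, synchronized start).
#'
#' @param trace A `cursor_trace`.
#' @param threshold Displacement in screen units needed to call a movement
#'   (default 2; any positive motion on noiseless integer traces).
#' @param min_delay Instructed minimum delay (s) between the point cue and
#'   the movement; earlier onsets are kept but flagged.
#' @param eeg_rate EEG sampling rate for the sample-index mapping.
#' @return Data frame with one row per moved trial: `trial`, `point_start_s`,
#'   `onset_s`, `eeg_sample` (1-based index of the first movement sample) and
#'   `flagged` (moved before `min_delay`). Trials without movement are
#'   omitted (with a message).
#' @export
detect_onsets <- function(trace, threshold = 2, min_delay = 1, eeg_rate = 256) {
  stopifnot(inherits(trace, "cursor_trace"))
  seg <- .phase_segments(trace, "point")
  out <- NULL
  n_still <- 0L
  for (i in seq_len(nrow(seg))) {
    idx <- which(trace$time_s >= seg$start_s[i] & trace$time_s < seg$end_s[i])
    if (!length(idx)) next
    dx <- trace$x[idx] - trace$x[idx[1]]
    dy <- trace$y[idx] - trace$y[idx[1]]
    mv <- which(sqrt(dx^2 + dy^2) > threshold)
    if (!length(mv)) {
      n_still <- n_still + 1L
      next
    }
    t_on <- trace$time_s[idx[mv[1]]]
    out <- rbind(out, data.frame(
      trial = i, point_start_s = seg$start_s[i], onset_s = t_on,
      eeg_sample = as.integer(round(t_on * eeg_rate)) + 1L,
      flagged = (t_on - seg$start_s[i]) < min_delay))
  }
  if (n_still > 0) message(n_still, " trial(s) without movement: no onset")
  if (is.null(out)) {
    out <- data.frame(trial = integer(), point_start_s = numeric(),
                      onset_s = numeric(), eeg_sample = integer(),
                      flagged = logical())
  }
  out
}

#' Cut pre-movement and rest epochs from a preprocessed run
#'
#' For every detected onset t the 1-s window `[t - 1, t)` becomes a
#' pre-movement epoch; for every rest-cross period `[a, a + 3)` the centred
#' second `[a + 1, a + 2)` becomes a rest epoch. Each epoch holds exactly
#' one second of all channels.
#'
#' @param rec A (preprocessed) `eeg_recording`.
#' @param trace The run's `cursor_trace` (provides the cross periods).
#' @param onsets Onset table from [detect_onsets()].
#' @param run_id Identifier of the run, used as the cross-validation fold key.
#' @return An `erd_epochs` object: list with `samples` (list of
#'   channels x rate matrices) and `info` (data frame with `label`
#'   (`"pre_movement"`/`"rest"`), `run_id`, `t0`, `flagged`).
#' @export
extract_epochs <- function(rec, trace, onsets, run_id = "run1") {
  stopifnot(inherits(rec, "eeg_recording"), inherits(trace, "cursor_trace"))
  rate <- rec$rate
  n <- ncol(rec$samples)
  cut1s <- function(t0) {
    i0 <- as.integer(round(t0 * rate)) + 1L
    if (i0 < 1L || i0 + rate - 1L > n) return(NULL)
    rec$samples[, i0:(i0 + rate - 1L), drop = FALSE]
  }
  samples <- list()
  info <- NULL
  for (i in seq_len(nrow(onsets))) {
    t0 <- onsets$onset_s[i] - 1
    m <- cut1s(t0)
    if (is.null(m)) {
      warning("pre-movement epoch at t0=", t0, " s outside run; skipped")
      next
    }
    samples[[length(samples) + 1L]] <- m
    info <- rbind(info, data.frame(label = "pre_movement", run_id = run_id,
                                   t0 = t0, flagged = onsets$flagged[i]))
  }
  cross <- .phase_segments(trace, "cross")
  for (i in seq_len(nrow(cross))) {
    t0 <- cross$start_s[i] + 1
    if (t0 + 1 > cross$end_s[i] + 1e-9) next  # truncated final cross
    m <- cut1s(t0)
    if (is.null(m)) next
    samples[[length(samples) + 1L]] <- m
    info <- rbind(info, data.frame(label = "rest", run_id = run_id,
                                   t0 = t0, flagged = FALSE))
  }
  if (is.null(info)) {
    info <- data.frame(label = character(), run_id = character(),
                       t0 = numeric(), flagged = logical())
  }
  structure(list(samples = samples, info = info, rate = rate,
                 labels = rec$labels), class = "erd_epochs")
}

#' @export
print.erd_epochs <- function(x, ...) {
  cat(sprintf("<erd_epochs> %d epochs (%d pre-movement, %d rest)\n",
              nrow(x$info), sum(x$info$label == "pre_movement"),
              sum(x$info$label == "rest")))
  invisible(x)
}

# concatenate erd_epochs objects (e.g. across runs)
.bind_epochs <- function(eps) {
  stopifnot(length(eps) >= 1)
  structure(list(samples = do.call(c, lapply(eps, `[[`, "samples")),
                 info = do.call(rbind, lapply(eps, `[[`, "info")),
                 rate = eps[[1]]$rate, labels = eps[[1]]$labels),
            class = "erd_epochs")
}
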