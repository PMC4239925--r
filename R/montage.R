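#' Electrode labels of the 16-channel sensorimotor montage
#'
#' The fixed channel order used throughout the package: a fronto-central to
#' parietal grid over sensorimotor cortex, named after the International
#' 10/10 placement system.
#'
#' @return Character vector of 16 electrode labels.
#' @export
#' @examples
#' erd_channels()
erd_channels <- function() {
  c("Fz", "FC5", "FC1", "FCz", "FC2", "FC6", "C3", "Cz", "C4",
    "CP5", "CP1", "CP2", "CP6", "P3", "Pz", "P4")
}

## ---- idealized spherical 10/10 geometry -----------------------------------
##
## Unit-sphere head model with landmarks nasion (0,1,0), inion (0,-1,0),
## left/right preauricular (-/+1,0,0) and vertex Cz (0,0,1).  Midline and
## central coronal electrodes sit at 10% steps (18 degrees) along their
## landmark arcs; the outer 10% ring runs through Fpz, T7, Oz, T8; the
## remaining rows are great-circle interpolations between their ring anchors
## and the midline electrode of the row.

# spherical linear interpolation between two unit vectors, t in [0, 1]
.slerp <- function(u, v, t) {
  om <- acos(max(-1, min(1, sum(u * v))))
  if (om < 1e-12) return(u)
  (sin((1 - t) * om) * u + sin(t * om) * v) / sin(om)
}

# point at inclination `incl` (deg from vertex) toward azimuth `az`
# (deg from +y/front, positive toward the left ear)
.sph_point <- function(incl, az) {
  ir <- incl * pi / 180
  ar <- az * pi / 180
  c(-sin(ar) * sin(ir), cos(ar) * sin(ir), cos(ir))
}

# full idealized 10/10 coordinate table (label -> unit xyz)
.build_1010_table <- function() {
  pos <- list()
  # sagittal midline: 10% steps nasion -> inion; inclination from vertex,
  # front positive azimuth 0, back azimuth 180
  midline <- c(Fpz = 72, AFz = 54, Fz = 36, FCz = 18, Cz = 0,
               CPz = -18, Pz = -36, POz = -54, Oz = -72)
  for (lab in names(midline)) {
    a <- midline[[lab]]
    pos[[lab]] <- .sph_point(abs(a), if (a >= 0) 0 else 180)
  }
  # central coronal chain: left negative x
  coronal <- c(T7 = 72, C5 = 54, C3 = 36, C1 = 18,
               C2 = -18, C4 = -36, C6 = -54, T8 = -72)
  for (lab in names(coronal)) {
    a <- coronal[[lab]]
    pos[[lab]] <- .sph_point(abs(a), if (a >= 0) 90 else -90)
  }
  # outer 10% ring (inclination 72), azimuth from front in 18-degree steps;
  # odd labels to the left (positive azimuth), even to the right
  ring_left <- c(Fp1 = 18, AF7 = 36, F7 = 54, FT7 = 72, T7 = 90,
                 TP7 = 108, P7 = 126, PO7 = 144, O1 = 162)
  ring_right <- c(Fp2 = -18, AF8 = -36, F8 = -54, FT8 = -72, T8 = -90,
                  TP8 = -108, P8 = -126, PO8 = -144, O2 = -162)
  for (lab in names(ring_left)) pos[[lab]] <- .sph_point(72, ring_left[[lab]])
  for (lab in names(ring_right)) pos[[lab]] <- .sph_point(72, ring_right[[lab]])
  # intermediate rows: quarter-points of the great-circle arc from the ring
  # anchor to the row's midline electrode
  rows <- list(
    AF = list(anchor = c("AF7", "AF8"), mid = "AFz", lab = c("AF3", "AF4"), t = 1 / 2),
    F  = list(anchor = c("F7", "F8"), mid = "Fz",
              lab = list(c("F5", "F3", "F1"), c("F6", "F4", "F2")), t = c(1, 2, 3) / 4),
    FC = list(anchor = c("FT7", "FT8"), mid = "FCz",
              lab = list(c("FC5", "FC3", "FC1"), c("FC6", "FC4", "FC2")), t = c(1, 2, 3) / 4),
    CP = list(anchor = c("TP7", "TP8"), mid = "CPz",
              lab = list(c("CP5", "CP3", "CP1"), c("CP6", "CP4", "CP2")), t = c(1, 2, 3) / 4),
    P  = list(anchor = c("P7", "P8"), mid = "Pz",
              lab = list(c("P5", "P3", "P1"), c("P6", "P4", "P2")), t = c(1, 2, 3) / 4),
    PO = list(anchor = c("PO7", "PO8"), mid = "POz", lab = c("PO3", "PO4"), t = 1 / 2)
  )
  for (rw in rows) {
    labs <- if (is.list(rw$lab)) rw$lab else list(rw$lab[1], rw$lab[2])
    for (side in 1:2) {
      u <- pos[[rw$anchor[side]]]
      v <- pos[[rw$mid]]
      for (i in seq_along(rw$t)) {
        pos[[labs[[side]][i]]] <- .slerp(u, v, rw$t[i])
      }
    }
  }
  pos
}

#' Build an electrode montage with 10/10 positions and pairwise distances
#'
#' Places the requested electrodes on a unit-sphere head model using an
#' idealized construction of the International 10/10 system (landmark arcs at
#' 10\% steps, great-circle interpolation for intermediate rows) and computes
#' the straight-line (chord) distance between every electrode pair.  These
#' distances feed the inverse-distance Laplacian weights of
#' [laplacian_weights()].
#'
#' @param labels Character vector of 10/10 electrode names. Defaults to the
#'   16-channel sensorimotor grid of [erd_channels()].
#' @return An object of class `erd_montage`: a list with `labels`,
#'   `positions` (n x 3 matrix of unit-sphere coordinates, x right, y front,
#'   z up) and `dist` (n x n chord-distance matrix, dimensionless head-radius
#'   units).
#' @export
#' @examples
#' m <- build_montage()
#' round(m$dist["C3", "Cz"], 3)
build_montage <- function(labels = erd_channels()) {
  stopifnot(is.character(labels), length(labels) >= 1)
  if (anyDuplicated(labels)) {
    stop("duplicate electrode labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  tab <- .build_1010_table()
  unknown <- setdiff(labels, names(tab))
  if (length(unknown)) {
    stop("unknown 10/10 electrode label(s): ", paste(unknown, collapse = ", "))
  }
  positions <- do.call(rbind, tab[labels])
  rownames(positions) <- labels
  colnames(positions) <- c("x", "y", "z")
  d <- as.matrix(stats::dist(positions))
  dimnames(d) <- list(labels, labels)
  structure(list(labels = labels, positions = positions, dist = d),
            class = "erd_montage")
}

#' @export
print.erd_montage <- function(x, ...) {
  cat("<erd_montage> ", length(x$labels), " electrodes: ",
      paste(x$labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Multichannel EEG recording container
#'
#' @param samples Numeric matrix, channels x time, in microvolts.
#' @param labels Channel names, one per row of `samples`.
#' @param rate Sampling rate in Hz (the acquisition chain runs at 256 Hz).
#' @return An `eeg_recording` object (list with `samples`, `labels`, `rate`).
#' @export
eeg_recording <- function(samples, labels, rate = 256) {
  samples <- as.matrix(samples)
  stopifnot(is.numeric(samples), length(labels) == nrow(samples),
            is.numeric(rate), length(rate) == 1, rate > 0)
  if (!all(is.finite(samples))) stop("EEG samples must be finite")
  rownames(samples) <- labels
  structure(list(samples = samples, labels = as.character(labels), rate = rate),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$rate,
              ncol(x$samples) / x$rate))
  invisible(x)
}

#' Inverse-distance surface Laplacian weights
#'
#' For each electrode i the weight of neighbour j (every other electrode) is
#' the reciprocal distance 1/d_ij normalized so the weights over the
#' neighbour set sum to one:
#' \deqn{g_{ij} = \frac{1/d_{ij}}{\sum_{j \in S_i} 1/d_{ij}}}
#' where S_i contains all electrodes except i.
#'
#' @param montage An `erd_montage` with at least two electrodes.
#' @return An `erd_laplacian`: list with the weight matrix `g` (zero diagonal,
#'   rows summing to one) and the montage `labels`.
#' @export
laplacian_weights <- function(montage) {
  stopifnot(inherits(montage, "erd_montage"))
  n <- length(montage$labels)
  if (n < 2) stop("Laplacian reference needs at least 2 electrodes")
  d <- montage$dist
  off <- d[upper.tri(d)]
  if (any(off <= 0)) stop("duplicate electrode positions (zero distance)")
  inv <- 1 / d
  diag(inv) <- 0
  g <- inv / rowSums(inv)
  dimnames(g) <- dimnames(d)
  structure(list(g = g, labels = montage$labels), class = "erd_laplacian")
}

#' Apply the surface Laplacian spatial reference
#'
#' Re-references every channel by subtracting the distance-weighted average
#' of all remaining channels, sample by sample:
#' \deqn{V_i^{LAP}(t) = V_i(t) - \sum_{j \in S_i} g_{ij} V_j(t)}
#' which sharpens local cortical activity and cancels any component common
#' to all electrodes.
#'
#' @param rec An `eeg_recording` whose channel order matches the weights.
#' @param w An `erd_laplacian` from [laplacian_weights()].
#' @return A new `eeg_recording` of identical shape.
#' @export
apply_laplacian <- function(rec, w) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(w, "erd_laplacian"))
  if (!identical(rec$labels, w$labels)) {
    stop("channel order of recording does not match Laplacian weights")
  }
  out <- rec$samples - w$g %*% rec$samples
  eeg_recording(out, rec$labels, rec$rate)
}
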