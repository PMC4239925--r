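---
title: "Detecting pre-movement ERD from EEG: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting pre-movement ERD from EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erdbench)
```

## The detection problem

A voluntary arm movement is preceded by event-related desynchronization
(ERD): the mu (8–12 Hz) and beta (13–30 Hz) rhythms over sensorimotor
cortex lose spectral power, beginning up to two seconds before the movement
onset and recovering after it ends. `erdbench` frames intention detection
as a binary classification of 1-s EEG windows: *pre-movement* (the second
immediately before a detected movement onset) versus *rest* (the centred
second of a rest cue). The package implements every stage from raw
16-channel recordings to the cross-validated benchmark of seven
classifiers, together with a synthetic session generator that makes the
chain testable end to end.

## Montage and the surface Laplacian

Electrode positions are built by an idealized spherical construction of the
International 10/10 system: a unit-sphere head with nasion, inion and the
two preauricular points on the equator, midline and central coronal
electrodes at 10% (18°) steps along their landmark arcs, the outer ring at
72° inclination, and intermediate rows (FC, CP, P, …) placed by
great-circle interpolation between their ring anchor and the row's midline
electrode. Inter-electrode distance is the 3-D chord. The chord/geodesic
choice is immaterial for the Laplacian weights up to a mild monotone
rescaling: both are strictly increasing functions of the inter-electrode
angle, so the *ordering* of weights is identical and the numerical
difference stays small at these angles.

The spatial reference is the inverse-distance surface Laplacian over **all
15 remaining electrodes**:
$$V_i^{LAP} = V_i - \sum_{j \ne i} g_{ij} V_j, \qquad
  g_{ij} = \frac{1/d_{ij}}{\sum_{j \ne i} 1/d_{ij}}.$$
Each weight row sums to one, so any signal component common to all
electrodes (reference drift, a shared noise source) is cancelled exactly;
the tests verify this annihilation property and agreement with a
per-sample double-loop evaluation.

## Frequency filtering

Two filters are applied to whole runs *before* epoching, so the 1-s
analysis windows never contain filter edge transients:

* a 50-Hz notch for mains interference. In the original acquisition chain
  this lived in amplifier hardware with unspecified characteristics; here
  it is a constrained 2nd-order IIR biquad with quality factor Q = 35
  (≈ 1.4 Hz rejection band), a standard mains-rejection design, and Q is
  configurable;
* an 8th-order Butterworth band-pass, 5–40 Hz, which removes DC/drift and
  high-frequency noise while keeping the mu and beta bands.

Filtering is causal (single forward pass) by default, matching online
operation of an acquisition chain; a zero-phase forward–backward mode is
available behind `zero_phase` in the configuration, default off. Filter
magnitudes are tested against the closed-form Butterworth and biquad
responses at ten probe frequencies within 1%.

## Epoching

Movement onset is the first cursor sample (16 Hz) whose displacement from
the rest position exceeds a threshold (default 2 screen units — robust to
small jitter in a real trace, while still within one cursor sample of the
truth for the synthetic traces). The EEG clock is mapped by the exact 16:1
sample-rate ratio; drift correction is out of scope. Per onset *t* the
pre-movement epoch is `[t−1 s, t)`; per 3-s rest cross starting at *a* the
rest epoch is the centred second `[a+1, a+2)` — "the middle" read as the
centred second. Trials where the subject moved earlier than the instructed
1 s after the cue are kept but flagged rather than discarded, since no
exclusion rule is part of the protocol; trials without any movement yield
no pre-movement epoch and are logged.

## Band-power features

Each 1-s, 256-sample epoch is transformed with a plain (untapered) FFT —
the bins then fall exactly on integer frequencies — and converted to a
one-sided power spectrum `P(f) = |X(f)|²/N²` with non-DC/non-Nyquist bins
doubled, so `Σ_f P(f)` equals the mean squared amplitude (Parseval,
tested). Features are the sums of `P(f)` over the inclusive integer bands
8–12, 13–24 and 25–30 Hz (5, 12 and 6 bins) per electrode: 48 features.
The amplitude-versus-power normalization behind published absolute feature
values is not derivable, so the absolute feature scale here is a
convention (documented, configurable via `taper`); all downstream results
depend only on relative differences. A Hann taper option exists, default
off. Per-feature z-scoring (fitted on training folds only) is available
but default off.

## The seven classifiers

All trainers are deterministic given the data and specification; labels
are encoded pre-movement = +1, rest = −1.

* **LS-SVM** solves the least-squares SVM KKT conditions as one linear
  system (regularization γ = 1 by default).
* **QP-SVM** solves the standard soft-margin dual quadratic program with
  the interior-point solver `kernlab::ipop` (C = 1); dual feasibility is
  checked after the solve, and a Gram-scaled ridge of 1e-8 keeps the
  iterations well posed.
* **SMO-SVM** optimizes the identical dual by analytic two-variable steps
  over the maximal-violating pair, stopping at a violation gap below 1e-6;
  the tests verify its objective matches the QP optimum to 1e-4.
* **k-NN** (k = 10, 20, 30) is brute-force Euclidean; with two classes and
  even k a tied vote is resolved by the label of the single nearest
  neighbour — deterministic and distance-respecting.
* **Gaussian naive Bayes** uses per-class, per-feature Gaussians with a
  variance floor of 1e-9.

The original benchmark's kernels and hyperparameters are unknown; the
package defaults to a **linear** kernel for all SVMs (a 48-dimensional
feature space with a few hundred samples rarely benefits from RBF), with
C, γ and an RBF option configurable. This is a deliberate, documented
choice of this package.

## Cross-validation and the report

Each run is one fold; the classifier is trained on the other runs' epochs
and tested on the held-out run, so the fold partition is a true partition
(tested). Per fold, TPR and FPR are percentage rates of the positive and
negative class; per subject the mean ± sd over folds and
GAP = mean TPR / mean FPR; the all-users column is the unweighted mean of
per-subject means, of per-subject sds, and of per-subject GAPs. These
conventions were fixed by verifying them against the shipped six-subject
reference table: the recomputed all-users cells agree with the printed
ones to one printed decimal (32 of 35 exactly; the other three differ by
one unit in the last digit because the per-user cells are themselves
rounded). Notably the GAP convention is the mean of per-user GAPs — the
ratio of pooled means would give ≈ 2.6 rather than the printed 2.8 for the
LS row. A subject with zero FPR has infinite GAP and is excluded from the
all-users GAP with a warning.

ANOVA comparisons use the classic equal-variance one-way test. The
observation unit is the per-subject fold-mean rate (6 observations per
classifier); this was an inference from the published per-user box plots,
and it is corroborated by reproduction: recomputing from the reference
table's per-user means gives p = 0.02250 for FPR (printed: 0.0225) and
p = 0.880 for TPR (printed: 0.8774 — close but not exact, as expected from
rounded inputs). The 21 pairwise two-group ANOVAs are uncorrected for
multiple testing, matching the published table; recomputation reproduces
it within ≈ 0.002. With a single subject the package falls back to
per-fold rates, the only replication available. Report tables round half
away from zero to one decimal.

## The synthetic session generator

`simulate_session()` emulates the cued reaching protocol: `n_runs = 6`
runs of `run_s = 256` s, each trial a 3-s cross then a 5-s point
(32 trials/run), movement onset uniform 1–3 s after the point (on the
16-Hz cursor grid), a half-cosine reach of 3 s (forward 1.5 s, back
1.5 s, 500 screen units). Per channel the EEG is

$$x_c(t) = n_c(t) + s(t) + m(t) +
  g_c\,A(t)\,[a_\mu \sin(2\pi f_\mu t + \phi_c) +
             a_\beta \sin(2\pi f_\beta t + \psi_c)]$$

with per-channel pink noise `n_c` (10 µV RMS), a shared pink component `s`
(2 µV — it gives the Laplacian something to cancel), a small 50-Hz mains
tone `m` (0.5 µV — it exercises the notch), oscillations at 10 and 20 Hz
(4 and 3 µV at the spatial peak), a spatial profile `g_c` peaking at
C3/Cz/C4 (1.0; 0.6 on the FC/CP rows; 0.3 elsewhere), and the ERD envelope
`A(t) = 1 − ρ` from `onset − erd_lead` (default 1.5 s, within the
up-to-2-s physiological lead) until the movement ends, 1 elsewhere. The
attenuation onset is abrupt by default — the physiological time course is
not established — with a linear-ramp option (`erd_ramp`). All randomness
(onset delays, phases, noise) flows from one seed; identical seeds give
bit-identical sessions.

The amplitude and noise defaults were chosen once as a realistic operating
point: scalp rhythms of a few microvolts over ~10 µV broadband background,
calibrated so that a deep attenuation (ρ = 0.6) is reliably detectable
(LS-SVM TPR ≥ 90, FPR ≤ 10 on a 6-run session) while ρ = 0 sits at
chance — the regime the pipeline is designed to resolve. The study's true
ERD depth is unknown; `erd_depth` defaults to the mid-range 0.5.

What the generator does *not* emulate: volume conduction (channels are
correlated only through the shared component, not through a head model),
non-stationary background (drowsiness, alpha blocking), eye-blink/EMG
artifacts, the slow readiness potential, and between-subject variability.
Passing tests on synthetic sessions therefore demonstrate the chain's
correctness and its sensitivity to a controlled effect — not performance
on real recordings, where the published benchmark's ≈ 71%/28% operating
point shows the problem is far harder.

## Numerical choices and degenerate inputs

* Laplacian weight rows sum to 1 within 1e-12; duplicate electrode
  positions (zero distance) are rejected.
* The LS-SVM system is solved by dense LU; singularity is reported, not
  silently regularized. SMO caps at 1e5 iterations and reports
  non-convergence.
* Epochs must contain exactly one second of samples; onsets closer than
  1 s to the run start are skipped with a warning.
* A test fold missing one class yields `NA` for the undefined rate, with a
  warning, rather than a fabricated number.
* Variance floors: 1e-9 (naive Bayes); scaler sds below 1e-12 are treated
  as 1.

## Problem sizes used by the shipped checks

Unit tests run on short sessions (1–3 runs of 32–200 s) — the protocol
arithmetic is scale-invariant, so nothing is lost. The end-to-end checks
(chance level over 20 seeds, depth monotonicity, the ρ = 0.6 detection
point, and the acceptance script's benchmark) use full-scale 6-run × 256-s
sessions, the study's own geometry: 384 epochs per session, 48 features,
six-fold leave-one-run-out CV.

## Known limitations

* EDF import/export is not provided; sessions interchange as CSV + JSON.
* Electrode positions are idealized spherical, not digitized scalp
  coordinates; distances are chords on a unit sphere (no head radius).
* Real-time sliding-window operation, artifact removal (ICA/PCA), CAR and
  alternative spectral estimators are out of scope.
* The ANOVA observation unit for the published p-values is an inference;
  the package reports its reproduction rather than asserting exactness.
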