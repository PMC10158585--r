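---
title: "Event-related electrocortical analysis of cyclic motor behaviour with dual-layer mobile EEG"
author: "swingcycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-related electrocortical analysis of cyclic motor behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Brain dynamics during real, whole-body motor behaviour — here, table
tennis — can be recorded with mobile EEG, but the signals are swamped by
motion and muscle artifacts, and the behaviour itself provides the only
event structure. The measurement design this package targets has three
ingredients: a *dual-layer* electrode system in which every scalp
electrode is paired with a mechanically coupled, electrically isolated
noise electrode that experiences the same non-physiological artifacts but
records no brain activity; dedicated neck-EMG channels; and inertial
sensors on the paddles that timestamp every hit. The analysis asks how
cortical activity is organised around the *swing cycle* — ball appears,
participant hits, next ball appears — and how it differs between a
metronomic ball machine (temporally predictable delivery) and a human
feeder (variable delivery).

The package implements the full chain as composable, tested functions,
and couples it to a synthetic-study generator so that every stage can be
scored against planted ground truth.

## The synthetic study

`generateStudy()` draws, per participant and condition:

* **Events.** Ball feeds on a regular `1/eventRate` grid (default 0.5 Hz,
  one ball every 2 s) with uniform timing jitter whose SD is 25 ms in the
  machine condition and 150 ms in the human condition; one participant
  hit per feed at a mean latency of 640 ms. A regular grid with jitter —
  rather than a Poisson process — matches a machine that feeds
  metronomically. The machine's true timing jitter is not documented for
  the apparatus; 25 ms is our free choice of "metronomic".
* **Sources.** Eight cortical sources: the four parieto-occipital
  locations that are the analysis' focus (left/right parieto-occipital,
  precuneus, cuneus, at their canonical MNI coordinates) plus four
  others (frontal pair, supplementary motor, left sensorimotor), each
  jittered by 4 mm per participant to emulate anatomy. Every source is a
  1/f background (exponent `aperiodicExponent`, default 1.5) plus alpha
  (10 Hz) and beta (20 Hz) narrowband oscillations whose amplitude drops
  by `erdDepth` (defaults 0.5 / 0.3) between ball-appear and hit and
  rebounds for 500 ms after the hit. A slow multiplicative amplitude
  drift makes the sources super-Gaussian, which is both physiological
  (waxing and waning rhythms) and what makes them identifiable by ICA.
  In the machine condition only, a fixed-latency biphasic evoked
  waveform (peak ~200 ms after ball-appear, amplitude `erpAmplitude`,
  default 4 µV) is added identically on every trial — this is the planted
  analogue of the phase-locked response that predictable delivery evokes.
* **Channels.** Scalp data are smooth distance-based gains from the
  sources (no real leadfield — head modelling is out of scope) plus
  shared motion artifacts, muscle leakage and sensor noise; noise-layer
  channels carry the *same* artifacts with independent sensor noise and
  no brain signal; muscle channels are bursty 20–100 Hz noise that leaks
  into the lowest scalp electrodes; the paddle accelerometer has a ~1 g
  baseline and a sharp biphasic impact at every hit.

What the generator does *not* emulate: realistic volume conduction, eye
movements, skin-potential drifts beyond 1/f, or biomechanics. Passing
tests therefore demonstrate that the algorithms recover what they are
designed to recover under the stated signal model — not that any specific
neuroscientific claim holds on real recordings.

## Stage-by-stage notes and design choices

**Hit detection.** The "first derivative" is the per-sample forward
difference of the resultant acceleration in g, compared *strictly* to the
0.75 g threshold; suprathreshold excursions within a 0.5 s refractory
window merge into one event (one per swing). Cross-correlation alignment
of annotation trains is computed on 1 ms binned impulse trains over a
±30 s lag window; the 200 ms reference tolerance is inclusive.

**Filtering.** The high-pass is a windowed-sinc (Hamming) linear-phase
FIR applied zero-phase with reflection padding; the transition band is
`min(max(0.25·cutoff, 2 Hz), cutoff)` centred on the cutoff. Line noise
is removed by sliding-window (4 s, Hann-stitched) sinusoidal regression
at the line frequency — a deliberately simple stand-in for multitaper
line-noise tools that adapts to amplitude/phase drift while leaving
neighbouring bands untouched. Resampling is band-limited via the FFT,
which preserves passband amplitude essentially exactly; we chose it over
`signal::resample` after measuring ~2.5% passband ripple in the latter.

**Channel hygiene.** The per-channel statistic is log RMS; a channel is
rejected when it deviates from the median of the remaining channels of
its layer by more than 3 of their SDs, iterated once. Scalp and noise
layers are screened, referenced and interpolated independently.
Spherical-spline interpolation uses the stiffness-4 g-function with a
50-term Legendre truncation. Interpolation of electrodes at the montage
boundary is extrapolation and is correspondingly worse; the tests score
reconstruction against the field's global RMS.

**Dual-layer CCA.** In 2 s windows (50% hop, Hann overlap-add), both
sides are first projected onto their significant principal subspaces
(relative eigenvalue tolerance 1e-6) so that near-zero-variance
directions of a rank-deficient reference cannot produce spurious
canonical correlations; a small ridge (1e-6 of the covariance trace)
stabilises short windows. Canonical pairs with squared correlation above
the threshold (0.85 against the noise layer, 0.40 against muscle) are
removed by regressing the scalp window on the *reference-side* canonical
variates. Those variates contain artifact but no brain signal, so brain
activity uncorrelated with the reference is not drawn into the projector;
regressing on the scalp-side variates instead measurably removed brain
variance (each scalp variate is artifact *plus* a sliver of brain).
Sub-window-frequency artifact lives in the window means and is outside
CCA's reach, which is why the pipeline high-passes at 1 Hz first.

**Window rejection.** Our stand-in for amplitude-based artifact windowing
marks 1 s windows (50% overlap) bad when more than 30% of scalp channels
exceed 30 robust SDs (1.4826×MAD). Masked samples are excluded from ICA
fitting but kept in the continuous record, so decompositions apply to the
full timeline.

**ICA.** After PCA rank reduction by the maximum number of interpolated
channels, the default decomposition is JADE — joint diagonalisation of
the parallel set of fourth-order cumulant matrices by Jacobi rotations,
with cumulants estimated on at most 20 000 (strided) samples. We
implemented symmetric FastICA (still available as `method = "fastica"`)
and an annealed extended Infomax first; on these band-limited,
moderately super-Gaussian mixtures FastICA's symmetric fixed point
oscillates in the near-Gaussian subspace and Infomax required
learning-rate tuning per dataset, while JADE is deterministic, converges
exactly, and is itself a standard published ICA for EEG at these channel
counts (its O(k⁴) cumulant set is the reason it is *not* the default
choice above ~64 channels). Components are ordered by explained scalp
variance and sign-fixed in channel space (largest mixing weight
positive), which keeps polarity consistent across participants — without
this, grand-average ERPs cancel.

**Component annotation.** Equivalent-dipole fitting and automated
component classification need real head models and are out of scope;
positions and labels are inputs. On synthetic data,
`annotateComponentsFromTruth()` stands in: a component whose scalp map
correlates with a planted source's forward gains at |r| ≥ 0.6 is labelled
brain and assigned that source's position plus a 2 mm localisation
error. The 0.6 threshold tolerates the residual mixing that remains at
desk-scale channel counts.

**Clustering.** k-means (50 seeded restarts) on component positions with
k chosen by maximum mean silhouette over `kRange`. The 3 SD outlier rule
is applied as a z-score on the Euclidean point-to-centroid distances
(`d > mean(d) + 3·sd(d)`): 3-D distances are chi-distributed with a mean
well above their SD, so thresholding the raw distance at `3·sd(d)` would
flag a fifth of perfectly good dipoles. Centroids are recomputed without
outliers and one component per participant per cluster is retained (the
one explaining the most scalp variance). Downstream analysis is
restricted to clusters that draw on more than half the participants and,
by default, to clusters whose centroid lies within 30 mm of the four
canonical parieto-occipital locations — the region this analysis is
about; `clusterFocus = NULL` lifts the restriction.

**Spectra.** Welch PSDs use non-overlapping 250-sample Hamming segments
(1 Hz resolution at 250 Hz). The spectral model fits a no-knee aperiodic
line in log10-log10 coordinates (robust: refit excluding the top 2.5%
positive residuals), extracts up to two Gaussian peaks greedily from the
flattened residual (minimum height 0.05 log10-power units, width limits
interpreted as bounds on twice the Gaussian SD), then alternates
peak-removal and aperiodic refits twice — one pass leaves the aperiodic
slope measurably biased by the peaks. A knee variant is available by
argument. Flattened spectra are compared per frequency with the paired
two-sided Wilcoxon signed-rank test (exact distribution through the
doubled-rank generating function for n ≤ 25, normal approximation with
tie and continuity corrections above), BH-corrected within the
cluster-condition family.

**Time-frequency.** Epochs span [−1.0, 2.5) s around ball-appear (875
samples at 250 Hz, half-open); the 10% highest-amplitude trials are
rejected (ties resolved toward keeping the lower trial index). Morlet
cycles rise linearly from 3 at the grid minimum to 64 at the maximum;
kernels are unit-gain calibrated so a unit sinusoid yields |coefficient|
≈ 1. The lowest-frequency wavelet must fit inside the epoch; longer
wavelets further up the schedule are zero-padded and act as temporal
smoothers, which matters for the short (−0.5–1.0 s) coherence epochs.
Warping maps each trial's (0, hit, next-appear) onto the study-wide
median latencies piecewise-linearly with the epoch edges fixed, applied
to power and phase (unit phasors) after the transform; ITPC and ERPs are
computed unwarped. The ERSP baseline is the mean single-trial power over
the whole swing cycle pooled across both conditions, computed per
participant; per-trial power is averaged arithmetically before the log.
Rally and serve sub-analyses subsample each cell to 70 epochs (seeded;
all are kept, with a warning, when fewer are available). Coherence
epochs skip the amplitude-based trial rejection so that the two
components of a pair see identical trials.

**Resampling statistics.** The time-shuffled null circularly shifts each
unit's map along time by an independent offset per iteration, preserving
within-unit spectra; p-values are two-sided with the (b+1)/(n+1)
convention, BH-corrected across all map cells, and non-significant cells
are zeroed in the masked output. The condition contrast uses
participant-level pairing: per-cell paired t statistics, cluster-forming
threshold at two-sided α = 0.05, 4-connectivity, cluster mass = Σ|t|,
and a max-mass null over random within-pair condition flips
(sign-flipping leaves the per-cell second moment invariant, so the
permuted t maps are computed from one matrix product per batch; the
connected-component labelling is the package's only compiled code).

## Problem sizes used by the tests

The canonical configuration (120+120 channels at 500 Hz, 7.5 min
sessions, 2000 resampling iterations) is the package default. The test
and acceptance suites run the same code on reduced sizes chosen once for
desk-scale runtimes: studies of 6–12 participants, 8–32 channels per
layer, 60–80 s sessions at 250–500 Hz, 10–25 wavelet frequencies,
200–500 bootstrap/permutation iterations, and 600 s single-source
simulations for spectral-exponent recovery. The headline
machine-vs-human contrast is scored over 20 seeded end-to-end runs at 12
participants each. Type-I calibration of the cluster permutation uses
200 null replicates at 500 permutations.

## Known limitations

* The forward model is a smooth gain function, not a leadfield; absolute
  topographies and localisation accuracy are not meaningful beyond the
  planted geometry.
* Component activations are in normalised units (unit-variance scaling
  from whitening), so ERPs are comparable across conditions but not in
  absolute microvolts.
* The line-noise and window-rejection stages are simplified stand-ins
  for their EEGLAB counterparts, with semantics documented above rather
  than reproduced bit-for-bit.
* Phase is interpolated through unit phasors during warping; warped
  phase is provided for completeness but phase-locking measures should
  use unwarped maps (as the pipeline does).
* File interchange covers the BrainVision triplet and CSV; EDF and HDF5
  are not implemented.
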