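# swingcycle

Event-related electrocortical analysis of continuous, cyclic motor
behaviour — table tennis is the motivating case — recorded with mobile
**dual-layer EEG**: every scalp electrode is paired with a mechanically
coupled, electrically isolated *noise* electrode that sees the same motion
artifacts but no brain signal, and dedicated neck-EMG channels capture
muscle activity. The package implements the full analysis chain for such
recordings, together with a ground-truth synthetic-study generator so that
every stage can be validated without access to raw recordings.

## What the pipeline computes

1. **Hit events from inertial sensors.** An event is marked whenever the
   first difference of the paddle's resultant acceleration
   `r[i] = sqrt(ax² + ay² + az²)` exceeds 0.75 g; externally annotated
   relative events are placed on the recording time base by
   cross-correlation of 1 ms event trains, and events farther than 200 ms
   from a reference marker are discarded. Ball-appear / participant-hit /
   next-ball-appear triplets form *swing cycles*.
2. **Continuous cleaning.** 1 Hz zero-phase FIR high-pass, sliding-window
   sinusoidal regression at the line frequency, band-limited resampling to
   250 Hz, robust (3 SD, log-RMS) channel rejection per layer, full-rank
   average reference with spherical-spline interpolation, and dual-layer
   denoising: in 2 s sliding windows, canonical correlation analysis finds
   the scalp subspaces correlated with the noise layer (rejected at
   r² > 0.85) and with the muscle channels (r² > 0.40), and projects them
   out. High-amplitude windows are masked (SD threshold 30, window
   criterion 0.3).
3. **Decomposition and source clustering.** PCA rank reduction by the
   number of interpolated channels, ICA (JADE by default), selection of
   brain components (participants contributing fewer than five are
   dropped), and k-means clustering of component locations (MNI mm) with
   the cluster count chosen by mean silhouette, a 3 SD outlier rule, and
   one component per participant per cluster (largest scalp variance).
4. **Spectral parameterisation.** Welch PSDs (250-sample non-overlapping
   Hamming windows), an aperiodic + periodic model over 3–40 Hz
   (`log10 P(f) ≈ b − χ·log10 f` plus at most two Gaussian peaks, width
   limits [1, 8], minimum height 0.05), flattened spectra, and per-frequency
   two-sided Wilcoxon signed-rank condition comparisons with
   Benjamini–Hochberg FDR.
5. **Time–frequency measures.** Epochs −1.0–2.5 s around ball-appear with
   10% peak-amplitude epoch rejection, Morlet wavelets whose cycles rise
   linearly from 3 to 64 across the frequency grid, linear time warping of
   single-trial spectrograms to the median swing-cycle latencies, and:
   - `ERSP(f,t) = 10·log10( mean_trials P(f,t) / baseline(f) )` with the
     baseline pooled over the full swing cycle of both conditions,
   - `ITPC(f,t) = | mean_trials e^{iφ(f,t)} |` (not warped),
   - event-related potentials (trial mean per participant, then grand mean),
   - inter-cluster event-related coherence
     `|Σ A·conj(B)| / sqrt(Σ|A|²·Σ|B|²)` on −0.5–1.0 s epochs, restricted
     to participants contributing components to both clusters.
6. **Resampling statistics.** Bootstrap significance masks against
   time-shuffled nulls (2000 iterations, α = 0.05, BH-corrected across
   cells) and cluster-based permutation tests for paired condition
   contrasts (per-cell paired t, 4-connected clusters, max-mass null,
   2000 permutations).

The synthetic generator (`simConfig()` / `generateStudy()`) emulates the
recording structure end to end: dipolar cortical sources with 1/f
background and event-locked alpha/beta suppression, a phase-locked evoked
response present only in the machine-fed condition (low timing jitter),
motion artifacts shared between scalp and noise layers, bursty muscle
channels leaking into the scalp, and accelerometer traces with impact
transients at every hit.

## Worked example

```r
library(swingcycle)

cfg <- simConfig(nParticipants = 6, sessionLength = 60, nScalp = 10,
                 nNoise = 10, nMuscle = 4, fsEeg = 250, fsImu = 500,
                 rngSeed = 42)
params <- analysisParams(nFreqs = 10, freqRange = c(3, 30), tfDecim = 8,
                         kRange = 2:10, nBoot = 200, nPerm = 200,
                         maxClusters = 2, rallyServe = TRUE, seed = 42)
res <- runPipeline(cfg, params)
res
#> StudyResults: 6 participants, k = 8 clusters, 2 analysed
headlineSummary(res)[c("itpcPeakMachine", "itpcPeakHuman",
                       "erpPeakMachine", "erpPeakHuman")]
#> $itpcPeakMachine
#> [1] 0.8062973
#> $itpcPeakHuman
#> [1] 0.2492411
#> $erpPeakMachine
#> [1] 0.2140811
#> $erpPeakHuman
#> [1] 0.1876026
```

The peak intertrial phase coherence in the most populated
parieto-occipital cluster is ~0.81 in the machine-fed condition against
~0.25 with a human feeder: phase-locked activity appears when ball
delivery is temporally predictable (at this small example size the ERP
peaks are noisier than the ITPC, which is the more sensitive phase-locking
measure). `writeStudyReport(res, "report/")` exports a markdown summary
and per-cluster CSV maps.

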