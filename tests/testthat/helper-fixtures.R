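## Shared fixture builders for the test suite.  Everything is generated in
## code; no data files.

## Wrap a channels x samples matrix into a Recording with a standard
## montage; roles default to scalp for all channels.
makeTestRecording <- function(data, fs, roles = rep("scalp", nrow(data)),
                              participant = "P01", condition = "machine") {
  n <- nrow(data)
  nScalp <- sum(roles == "scalp")
  positions <- matrix(NA_real_, n, 3)
  montage <- sphericalMontage(max(nScalp, 1))
  positions[roles == "scalp", ] <- montage[seq_len(nScalp), , drop = FALSE]
  if (sum(roles == "noise") == nScalp)
    positions[roles == "noise", ] <- montage[seq_len(nScalp), , drop = FALSE]
  new("Recording", data = data, fs = fs,
      channels = data.frame(
        name = sprintf("%s %03d", c(scalp = "EEG", noise = "NOISE",
                                    muscle = "EMG")[roles], seq_len(n)),
        role = roles, stringsAsFactors = FALSE),
      positions = positions,
      annotations = data.frame(onset = numeric(0), duration = numeric(0),
                               label = character(0),
                               stringsAsFactors = FALSE),
      interpolated = integer(0), participant = participant,
      condition = condition)
}

## Dual-layer fixture: scalp = brain + artifact, noise = artifact (+ optional
## sensor noise), already 1 Hz high-passed as in the pipeline order.
makeDualLayerFixture <- function(nc = 16, fs = 250, dur = 40,
                                 artifactAmp = 5, sensorNoise = 0,
                                 seed = 1, highpassed = TRUE) {
  withr::with_seed(seed, {
    n <- dur * fs
    brain <- matrix(rnorm(nc * n), nc)
    for (i in seq_len(nc))
      brain[i, ] <- stats::filter(brain[i, ], rep(1, 5) / 5,
                                  circular = TRUE)
    art <- matrix(rnorm(3 * n), 3)
    for (i in 1:3)
      art[i, ] <- stats::filter(art[i, ], rep(1, 25) / 25, circular = TRUE)
    pat <- matrix(rnorm(nc * 3), nc)
    A <- artifactAmp * pat %*% art
    noiseLayer <- A + matrix(rnorm(nc * n, sd = sensorNoise), nc)
    rec <- makeTestRecording(rbind(brain + A, noiseLayer), fs,
                             roles = rep(c("scalp", "noise"), each = nc))
    recBrain <- makeTestRecording(rbind(brain, noiseLayer), fs,
                                  roles = rep(c("scalp", "noise"), each = nc))
    if (highpassed) {
      rec <- highpass(rec)
      recBrain <- highpass(recBrain)
    }
    list(rec = rec, brain = recBrain@data[seq_len(nc), , drop = FALSE],
         recBrainOnly = recBrain,
         artifact = rec@data[seq_len(nc), ] -
           recBrain@data[seq_len(nc), , drop = FALSE])
  })
}

## Epochs fixture: trials of a given generator function f(trialIndex) ->
## sample vector.
makeTestEpochs <- function(nTrials, times, fs, gen,
                           t_hit = 0.64, t_next = 2.0) {
  data <- t(vapply(seq_len(nTrials), gen, numeric(length(times))))
  new("Epochs", data = data, times = times, fs = fs,
      trialInfo = data.frame(t_hit = rep(t_hit, nTrials),
                             t_next = rep(t_next, nTrials),
                             condition = "machine", subcondition = "rally",
                             stringsAsFactors = FALSE),
      participant = "P01", cluster = "")
}

## TimeFreqMap fixture from an explicit complex trials x freqs x times array.
makeTestTf <- function(coefArr, freqs, times, t_hit = 0.64, t_next = 2.0) {
  nT <- dim(coefArr)[1]
  new("TimeFreqMap", coef = coefArr, freqs = freqs, times = times,
      cycles = rep(3, length(freqs)),
      trialInfo = data.frame(t_hit = rep(t_hit, nT),
                             t_next = rep(t_next, nT),
                             condition = "machine", subcondition = "rally",
                             stringsAsFactors = FALSE),
      participant = "P01", cluster = "")
}

## Analytic power-law + Gaussian-peak Psd object (noiseless).
makeAnalyticPsd <- function(offset = 1, exponent = 1.5,
                            peaks = NULL, freqs = seq(1, 60, by = 0.5)) {
  y <- offset - exponent * log10(freqs)
  if (!is.null(peaks))
    for (i in seq_len(nrow(peaks)))
      y <- y + peaks$height[i] *
        exp(-(freqs - peaks$center[i])^2 / (2 * peaks$width[i]^2))
  structure(list(freqs = freqs, power = 10^y, logPower = 10 * y,
                 fs = NA_real_, winLen = NA_integer_, nSegments = 1L),
            class = "Psd")
}

## Small deterministic study configuration used across tests.
smallStudyConfig <- function(seed = 11, nParticipants = 2,
                             sessionLength = 90, nScalp = 12) {
  simConfig(nParticipants = nParticipants, sessionLength = sessionLength,
            nScalp = nScalp, nNoise = nScalp, nMuscle = 4,
            fsEeg = 250, fsImu = 500, rngSeed = seed)
}

## Adjusted Rand index (independent implementation for cluster checks).
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sumIj <- sum(comb2(tab))
  sumI <- sum(comb2(rowSums(tab)))
  sumJ <- sum(comb2(colSums(tab)))
  nC2 <- comb2(sum(tab))
  exp_ <- sumI * sumJ / nC2
  (sumIj - exp_) / ((sumI + sumJ) / 2 - exp_)
}
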