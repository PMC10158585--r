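## Synthetic-study generator.  Produces ground-truth-annotated multimodal
## sessions (scalp/noise/muscle EEG + inertial traces + event tables) with
## the statistical structure the downstream analysis assumes: dipolar
## cortical sources with 1/f background and event-locked band-power
## modulation, a condition-dependent phase-locked evoked response, motion
## artifacts shared between the scalp and noise layers, muscle bursts
## partially leaking into scalp channels, and paddle-impact impulses in the
## accelerometer traces.

## ---- elementary signal generators --------------------------------------

## Unit-SD noise with power-law spectrum P(f) ~ f^-exponent (FFT shaping).
shapedNoise <- function(n, fs, exponent) {
  L <- nextPow2(n)
  nf <- L / 2 + 1
  f <- seq(0, fs / 2, length.out = nf)
  amp <- c(0, f[-1]^(-exponent / 2))
  ph <- runif(nf, 0, 2 * pi)
  spec <- amp * exp(1i * ph)
  spec[nf] <- Re(spec[nf])
  full <- c(spec, Conj(rev(spec[2:(nf - 1)])))
  x <- Re(fft(full, inverse = TRUE))[seq_len(n)]
  x / sd(x)
}

## Unit-SD narrowband noise: Gaussian spectral envelope around `center`.
narrowbandNoise <- function(n, fs, center, bw) {
  L <- nextPow2(n)
  nf <- L / 2 + 1
  f <- seq(0, fs / 2, length.out = nf)
  amp <- exp(-(f - center)^2 / (2 * (bw / 2)^2))
  ph <- runif(nf, 0, 2 * pi)
  spec <- amp * exp(1i * ph)
  spec[c(1, nf)] <- Re(spec[c(1, nf)])
  full <- c(spec, Conj(rev(spec[2:(nf - 1)])))
  x <- Re(fft(full, inverse = TRUE))[seq_len(n)]
  x / sd(x)
}

## Unit-SD very-slow (< ~0.2 Hz) drift used as a multiplicative
## amplitude modulator.
smoothDrift <- function(n, fs) {
  L <- nextPow2(n)
  nf <- L / 2 + 1
  f <- seq(0, fs / 2, length.out = nf)
  amp <- exp(-(f / 0.1)^2); amp[1] <- 0
  ph <- runif(nf, 0, 2 * pi)
  spec <- amp * exp(1i * ph)
  spec[nf] <- Re(spec[nf])
  x <- Re(fft(c(spec, Conj(rev(spec[2:(nf - 1)]))),
              inverse = TRUE))[seq_len(n)]
  s <- sd(x)
  if (s == 0) rep(0, n) else x / s
}

## Smooth a 0/1-ish piecewise envelope with a 25 ms Gaussian kernel.
smoothEnvelope <- function(env, fs) {
  sdS <- max(1, round(0.025 * fs))
  k <- exp(-0.5 * ((-3 * sdS):(3 * sdS) / sdS)^2)
  k <- k / sum(k)
  Re(fftConvSame(env, k))
}

## Biphasic phase-locked evoked waveform (N2-like), peak ~200 ms
## post-ball-appear, unit peak amplitude, 500 ms support.
erpWaveform <- function(fs) {
  t <- seq(0, 0.5, by = 1 / fs)
  w <- -exp(-(t - 0.18)^2 / (2 * 0.030^2)) +
    0.6 * exp(-(t - 0.30)^2 / (2 * 0.050^2))
  w / max(abs(w))
}

## ---- event schedule -----------------------------------------------------

## Ball-appear events on a regular 1/eventRate grid with uniform timing
## jitter of the requested SD; one participant hit per feed at
## hitLatency (+/- uniform 100 ms).  Rally/serve blocks alternate.
simulateEventSchedule <- function(cfg, condition, seed) {
  withSeed(seed, {
    spacing <- 1 / cfg@eventRate
    grid <- seq(3, cfg@sessionLength - spacing - 1.5, by = spacing)
    w <- cfg@eventJitterSd[[condition]] * sqrt(3)
    appear <- grid + runif(length(grid), -w, w)
    hit <- appear + cfg@hitLatency + runif(length(grid), -0.1, 0.1)
    block <- ((seq_along(grid) - 1) %/% 15) %% 2
    sub <- ifelse(block == 0, "rally", "serve")
    eventTable(onset = c(appear, hit),
               type = rep(c("ball_appear", "participant_hit"),
                          each = length(grid)),
               condition = condition,
               subcondition = c(sub, sub),
               source = "synthetic")
  })
}

## Matched (appear, hit) pairs from an event table.
eventCycles <- function(events) {
  ap <- events$onset[events$type == "ball_appear"]
  ht <- events$onset[events$type == "participant_hit"]
  hitFor <- vapply(ap, function(a) {
    cand <- ht[ht > a]
    if (length(cand)) cand[1] else NA_real_
  }, numeric(1))
  data.frame(t_appear = ap, t_hit = hitFor)[!is.na(hitFor), ]
}

## ---- source dynamics ----------------------------------------------------

#' Default band profiles of the synthetic cortical sources
#'
#' One profile per canonical source: a 1/f background (5 uV SD), an alpha
#' (10 Hz) and a beta (20 Hz) oscillation whose amplitudes are suppressed by
#' the configured event-related desynchronization depth between ball-appear
#' and hit and rebound (+25% of the depth) for 500 ms after the hit, plus a
#' unit gain for the phase-locked evoked response.
#'
#' @param cfg a [SimConfig].
#' @return a list with one profile per source row of
#'   [syntheticSourceLayout()]: the parieto-occipital sources carry the
#'   full desynchronization depth and evoked gain, the remaining sources
#'   half the depth and a weak evoked gain.
#' @export
defaultSourceProfiles <- function(cfg) {
  depth <- cfg@erdDepth
  nPO <- nrow(defaultSourceCentroids())
  nAll <- nrow(syntheticSourceLayout())
  erpGain <- c(1, 1, 0.7, 1.2, rep(0.3, nAll - nPO))
  lapply(seq_len(nAll), function(i) {
    scale <- if (i <= nPO) 1 else 0.5
    bands <- data.frame(
      band = c("alpha", "beta"),
      center = c(10, 20), bw = c(2, 3), sd = c(3, 1.5),
      depth = scale * c(depth[["alpha"]] %||% 0, depth[["beta"]] %||% 0))
    list(bgSd = 5, bands = bands, erpGain = erpGain[i])
  })
}

#' Generate source time courses for one session
#'
#' Each cortical source is the sum of a 1/f background with exponent
#' `exponent` (so its log-PSD is a straight line in log-log coordinates), a
#' set of narrowband oscillations with Gaussian spectral peaks whose
#' amplitude envelope is modulated around the swing-cycle events
#' (suppression between ball-appear and hit, rebound after the hit), and,
#' when `erpAmplitude > 0`, a fixed-latency biphasic evoked waveform added
#' identically at every ball-appear event.
#'
#' @param profiles per-source profiles as from [defaultSourceProfiles()].
#' @param events an event table containing `ball_appear` and
#'   `participant_hit` rows (see [eventTable()]).
#' @param fs sampling rate, Hz.
#' @param duration session length, seconds; must cover all events with 3 s
#'   margin.
#' @param exponent aperiodic exponent chi of the background.
#' @param erpAmplitude evoked-response amplitude, microvolts (0 = none).
#' @param seed integer seed; the output is deterministic given it.
#' @return sources x samples numeric matrix, microvolts.
#' @export
generateSourceDynamics <- function(profiles, events, fs, duration,
                                   exponent = 1.5, erpAmplitude = 0,
                                   seed = 1) {
  if (nrow(events) && (min(events$onset) < 0 ||
                       max(events$onset) > duration - 1))
    scStop("events must lie inside the session duration (with margin)")
  n <- round(duration * fs)
  cyc <- if (nrow(events)) eventCycles(events) else
    data.frame(t_appear = numeric(0), t_hit = numeric(0))
  erpW <- erpWaveform(fs)
  withSeed(seed, {
    out <- matrix(0, length(profiles), n)
    for (s in seq_along(profiles)) {
      pr <- profiles[[s]]
      x <- shapedNoise(n, fs, exponent) * pr$bgSd
      for (b in seq_len(nrow(pr$bands))) {
        bb <- pr$bands[b, ]
        if (bb$sd <= 0) next
        env <- rep(1, n)
        if (bb$depth > 0 && nrow(cyc)) {
          for (ci in seq_len(nrow(cyc))) {
            i0 <- max(1, round((cyc$t_appear[ci] + 0.05) * fs))
            i1 <- min(n, round(cyc$t_hit[ci] * fs))
            if (i1 > i0) env[i0:i1] <- 1 - bb$depth
            r0 <- min(n, round((cyc$t_hit[ci] + 0.1) * fs))
            r1 <- min(n, round((cyc$t_hit[ci] + 0.6) * fs))
            if (r1 > r0) env[r0:r1] <- 1 + 0.25 * bb$depth
          }
          env <- smoothEnvelope(env, fs)
        }
        x <- x + narrowbandNoise(n, fs, bb$center, bb$bw) * bb$sd * env
      }
      ## slow multiplicative amplitude drift: physiological waxing/waning
      ## that also makes the sources super-Gaussian (separable by ICA)
      drift <- exp(0.4 * smoothDrift(n, fs))
      x <- x * drift / sd(x * drift) * sd(x)
      if (erpAmplitude > 0 && nrow(cyc)) {
        g <- pr$erpGain %||% 1
        for (ta in cyc$t_appear) {
          i0 <- round(ta * fs) + 1
          idx <- i0:min(n, i0 + length(erpW) - 1)
          x[idx] <- x[idx] + erpAmplitude * g * erpW[seq_along(idx)]
        }
      }
      out[s, ] <- x
    }
    out
  })
}

## ---- forward model and channel mixing ----------------------------------

## Smooth distance-based gains from MNI source positions to scalp
## electrodes on an 85 mm sphere centred near the head centre; no real
## leadfield (head modelling is out of scope), but smooth and full rank.
makeForwardModel <- function(cfg, sourcePositions, seed) {
  withSeed(seed, {
    montage <- sphericalMontage(cfg@nScalp)
    chMm <- montage * 85
    chMm[, 2] <- chMm[, 2] - 15   # montage origin sits anterior of MNI origin
    chMm[, 3] <- chMm[, 3] + 10
    nS <- nrow(sourcePositions)
    mixing <- matrix(0, cfg@nScalp, nS)
    for (s in seq_len(nS)) {
      d <- sqrt(rowSums((chMm - matrix(sourcePositions[s, ], cfg@nScalp, 3,
                                       byrow = TRUE))^2))
      g <- exp(-d^2 / (2 * 45^2))
      mixing[, s] <- g * (1 + 0.1 * runif(cfg@nScalp, -1, 1))
    }
    nArt <- 3
    artDir <- matrix(rnorm(3 * nArt), 3, nArt)
    artPatterns <- apply(artDir, 2, function(u) {
      u <- u / sqrt(sum(u^2))
      drop(montage %*% u) + 0.3 * rnorm(cfg@nScalp)
    })
    artPatterns <- artPatterns / max(abs(artPatterns))
    muscleLeak <- matrix(0, cfg@nScalp, cfg@nMuscle)
    for (m in seq_len(cfg@nMuscle)) {
      ## each neck-muscle channel leaks into the lowest (most posterior-
      ## inferior) scalp electrodes
      ord <- order(montage[, 3] + 0.2 * rnorm(cfg@nScalp))
      nl <- max(1, round(cfg@nScalp * 0.1))
      muscleLeak[ord[seq_len(nl)], m] <- 0.15 * runif(nl, 0.5, 1)
    }
    list(montage = montage, mixing = mixing,
         artPatterns = artPatterns, muscleLeak = muscleLeak)
  })
}

#' Mix source dynamics into a dual-layer recording
#'
#' Projects cortical source time courses to the scalp channels through the
#' forward gains, adds shared motion artifacts to scalp *and* paired noise
#' channels (the noise layer carries no brain signal), synthesises bursty
#' 20-100 Hz muscle channels that partially leak into scalp electrodes, and
#' adds white sensor noise everywhere.
#'
#' @param sources sources x samples matrix from [generateSourceDynamics()].
#' @param forward forward model list from the generator (fields `montage`,
#'   `mixing`, `artPatterns`, `muscleLeak`).
#' @param cfg a [SimConfig].
#' @param seed integer seed for artifact/noise streams.
#' @param participant,condition identifiers stored in the [Recording].
#' @param events optional event table stored as annotations.
#' @param muscleAmplitude muscle-burst amplitude, microvolts (0 disables
#'   the muscle generator entirely).
#' @return a [Recording] with scalp, noise and muscle channels.
#' @export
mixToChannels <- function(sources, forward, cfg, seed,
                          participant = "P01", condition = "machine",
                          events = NULL, muscleAmplitude = 20) {
  if (qr(forward$mixing)$rank < ncol(forward$mixing))
    scStop("forward mixing matrix is rank deficient")
  n <- ncol(sources)
  fs <- cfg@fsEeg
  withSeed(seed, {
    brain <- forward$mixing %*% sources
    nArt <- ncol(forward$artPatterns)
    art <- t(vapply(seq_len(nArt), function(i) {
      ## low-pass motion spectrum (~< 10 Hz), heavy amplitude
      L <- nextPow2(n); nf <- L / 2 + 1
      f <- seq(0, fs / 2, length.out = nf)
      amp <- 1 / (1 + (f / 8)^4)
      ph <- runif(nf, 0, 2 * pi)
      spec <- amp * exp(1i * ph); spec[c(1, nf)] <- Re(spec[c(1, nf)])
      x <- Re(fft(c(spec, Conj(rev(spec[2:(nf - 1)]))),
                  inverse = TRUE))[seq_len(n)]
      30 * x / sd(x)
    }, numeric(n)))
    artScalp <- cfg@artifactGain * (forward$artPatterns %*% art)
    muscle <- t(vapply(seq_len(cfg@nMuscle), function(m) {
      burst <- narrowbandNoise(n, fs, 60, 80)
      slow <- shapedNoise(n, fs, 2)
      env <- smoothEnvelope(as.numeric(slow > 0.8), fs) + 0.15
      muscleAmplitude * burst * env
    }, numeric(n)))
    scalp <- brain + artScalp + forward$muscleLeak %*% muscle +
      matrix(rnorm(cfg@nScalp * n, sd = cfg@sensorNoiseSd), cfg@nScalp)
    noise <- artScalp +
      matrix(rnorm(cfg@nNoise * n, sd = cfg@sensorNoiseSd), cfg@nNoise)
    muscleCh <- muscle +
      matrix(rnorm(cfg@nMuscle * n, sd = cfg@sensorNoiseSd), cfg@nMuscle)
    data <- rbind(scalp, noise, muscleCh)
    channels <- data.frame(
      name = c(sprintf("EEG %03d", seq_len(cfg@nScalp)),
               sprintf("NOISE %03d", seq_len(cfg@nNoise)),
               sprintf("EMG %02d", seq_len(cfg@nMuscle))),
      role = rep(c("scalp", "noise", "muscle"),
                 c(cfg@nScalp, cfg@nNoise, cfg@nMuscle)),
      stringsAsFactors = FALSE)
    positions <- rbind(forward$montage, forward$montage,
                       matrix(NA_real_, cfg@nMuscle, 3))
    ann <- if (!is.null(events) && nrow(events))
      data.frame(onset = events$onset, duration = 0, label = events$type,
                 stringsAsFactors = FALSE)
    else data.frame(onset = numeric(0), duration = numeric(0),
                    label = character(0), stringsAsFactors = FALSE)
    new("Recording", data = data, fs = fs, channels = channels,
        positions = positions, annotations = ann, interpolated = integer(0),
        participant = participant, condition = condition)
  })
}

## ---- inertial traces ----------------------------------------------------

#' Generate a paddle accelerometer trace
#'
#' Triaxial acceleration with ~1 g resultant baseline plus white noise, and
#' a sharp biphasic impact transient at every `participant_hit` event whose
#' leading edge exceeds `impulseAmplitude` within one sample (so the first
#' derivative of the resultant crosses the detection threshold exactly at
#' the hit time).
#'
#' @param events event table; `participant_hit` rows mark impacts.
#' @param fsImu sampling rate, Hz (>= 100).
#' @param duration trace length, seconds.
#' @param noiseSd white accelerometer noise SD, g.
#' @param impulseAmplitude leading-edge amplitude of the impact, g.
#' @param seed integer seed.
#' @param label,participant,condition identifiers.
#' @return an [ImuTrace].
#' @export
generateImuTrace <- function(events, fsImu = 2000, duration,
                             noiseSd = 0.02, impulseAmplitude = 4,
                             seed = 1, label = "paddle",
                             participant = "P01", condition = "machine") {
  if (fsImu < 100) scStop("fsImu must be >= 100 Hz")
  n <- round(duration * fsImu)
  shape <- impulseAmplitude * c(1, -0.7, 0.45, -0.25, 0.1)
  withSeed(seed, {
    acc <- cbind(ax = rnorm(n, 0, noiseSd),
                 ay = rnorm(n, 0, noiseSd),
                 az = 1 + rnorm(n, 0, noiseSd))
    hits <- events$onset[events$type == "participant_hit"]
    for (h in hits) {
      i0 <- round(h * fsImu) + 1
      idx <- i0:min(n, i0 + length(shape) - 1)
      if (length(idx) && idx[1] >= 1)
        acc[idx, 1] <- acc[idx, 1] + shape[seq_along(idx)]
    }
    new("ImuTrace", acc = acc, fs = fsImu, label = label,
        participant = participant, condition = condition)
  })
}

## ---- whole-study generation --------------------------------------------

#' Generate a complete synthetic study
#'
#' Produces one dual-layer [Recording] and one paddle [ImuTrace] per
#' participant per condition (`machine`, `human`), together with a ground
#' truth object recording everything the generator planted: per-participant
#' source positions (canonical parieto-occipital centroids plus a few mm of
#' anatomical jitter), forward gains, event tables and per-stream seeds.
#' All randomness derives from `cfg@rngSeed`: identical configurations give
#' bit-identical studies.
#'
#' The `machine` condition uses the small timing jitter and carries the
#' phase-locked evoked response; the `human` condition uses the large jitter
#' and none.  Both conditions share the alpha/beta event-related
#' desynchronization profile.
#'
#' @param cfg a [SimConfig].
#' @return a list with elements `recordings` (named list of [Recording]),
#'   `imu` (named list of [ImuTrace]), and `truth` (class `GroundTruth`).
#' @examples
#' cfg <- simConfig(nParticipants = 1, sessionLength = 40, nScalp = 6,
#'                  nNoise = 6, nMuscle = 2, fsEeg = 250, fsImu = 500)
#' study <- generateStudy(cfg)
#' names(study$recordings)
#' @export
generateStudy <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  centroids <- syntheticSourceLayout()
  if (cfg@nScalp < nrow(centroids))
    scStop("field 'nScalp': need at least %d scalp channels for the %d planted sources",
           nrow(centroids), nrow(centroids))
  profiles <- defaultSourceProfiles(cfg)
  participants <- sprintf("P%02d", seq_len(cfg@nParticipants))
  conditions <- c("machine", "human")
  recordings <- list(); imu <- list()
  sourcePositions <- list(); forward <- list(); eventsList <- list()
  seeds <- list()
  for (p in participants) {
    posSeed <- deriveSeed(cfg@rngSeed, paste0(p, ":pos"))
    sourcePositions[[p]] <- withSeed(posSeed,
      centroids + matrix(rnorm(length(centroids), sd = 4), nrow(centroids)))
    forward[[p]] <- makeForwardModel(cfg, sourcePositions[[p]],
                                     deriveSeed(cfg@rngSeed, paste0(p, ":fwd")))
    for (cond in conditions) {
      id <- paste(p, cond, sep = "_")
      evSeed <- deriveSeed(cfg@rngSeed, paste0(id, ":events"))
      srcSeed <- deriveSeed(cfg@rngSeed, paste0(id, ":sources"))
      mixSeed <- deriveSeed(cfg@rngSeed, paste0(id, ":mix"))
      imuSeed <- deriveSeed(cfg@rngSeed, paste0(id, ":imu"))
      ev <- simulateEventSchedule(cfg, cond, evSeed)
      src <- generateSourceDynamics(profiles, ev, cfg@fsEeg,
                                    cfg@sessionLength,
                                    exponent = cfg@aperiodicExponent,
                                    erpAmplitude = cfg@erpAmplitude[[cond]],
                                    seed = srcSeed)
      recordings[[id]] <- mixToChannels(src, forward[[p]], cfg, mixSeed,
                                        participant = p, condition = cond,
                                        events = ev)
      imu[[id]] <- generateImuTrace(ev, cfg@fsImu, cfg@sessionLength,
                                    seed = imuSeed, participant = p,
                                    condition = cond)
      eventsList[[id]] <- ev
      seeds[[id]] <- c(events = evSeed, sources = srcSeed, mix = mixSeed,
                       imu = imuSeed)
    }
  }
  truth <- structure(list(cfg = cfg, centroids = centroids,
                          profiles = profiles,
                          sourcePositions = sourcePositions,
                          forward = forward, events = eventsList,
                          seeds = seeds, participants = participants),
                     class = "GroundTruth")
  list(recordings = recordings, imu = imu, truth = truth)
}

#' @export
print.GroundTruth <- function(x, ...) {
  cat(sprintf("GroundTruth: %d participants x 2 conditions, %d sources\n",
              length(x$participants), nrow(x$centroids)))
  invisible(x)
}

#' Regenerate planted source signals or artifact-free scalp data
#'
#' Deterministically rebuilds, from the seeds stored in the ground truth,
#' the cortical source time courses (`trueSources`) or the brain-only scalp
#' projection before artifacts and sensor noise (`trueCleanScalp`) for one
#' session.  Used to score artifact-removal and source-recovery accuracy.
#'
#' @param truth `GroundTruth` from [generateStudy()].
#' @param participant,condition session identifiers.
#' @return sources x samples matrix (`trueSources`) or scalp-channels x
#'   samples matrix (`trueCleanScalp`), microvolts.
#' @export
trueSources <- function(truth, participant, condition) {
  id <- paste(participant, condition, sep = "_")
  cfg <- truth$cfg
  generateSourceDynamics(truth$profiles, truth$events[[id]], cfg@fsEeg,
                         cfg@sessionLength,
                         exponent = cfg@aperiodicExponent,
                         erpAmplitude = cfg@erpAmplitude[[condition]],
                         seed = truth$seeds[[id]][["sources"]])
}

#' @rdname trueSources
#' @export
trueCleanScalp <- function(truth, participant, condition) {
  truth$forward[[participant]]$mixing %*%
    trueSources(truth, participant, condition)
}
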