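#' Configure a synthetic dual-layer EEG study
#'
#' Builds a validated [SimConfig] describing a synthetic two-condition table
#' tennis study.  The defaults emulate the recording structure the pipeline
#' assumes: 120 scalp channels paired one-to-one with 120 noise channels and
#' 8 neck-muscle channels sampled at 500 Hz, inertial sensors at 2000 Hz,
#' and balls fed at 0.5 Hz (one every 2 s).  The `machine` condition feeds
#' on a metronomic grid with small timing jitter (25 ms SD) and elicits a
#' phase-locked evoked response ~200 ms after the ball appears; the `human`
#' condition has large timing jitter (150 ms SD) and no evoked component.
#' Both conditions carry alpha/beta desynchronization between ball-appear
#' and hit with a rebound after the hit.
#'
#' @param nParticipants number of participants.
#' @param sessionLength seconds of play per condition.
#' @param fsEeg,fsImu sampling rates, Hz.
#' @param nScalp,nNoise,nMuscle channel counts (`nNoise` must equal `nScalp`).
#' @param eventRate ball-feed rate, Hz.
#' @param eventJitterSd named numeric: ball-appear timing jitter SD per
#'   condition, seconds.
#' @param erpAmplitude named numeric: evoked-response source amplitude per
#'   condition, microvolts.
#' @param erdDepth named numeric: fractional amplitude suppression per band
#'   between ball-appear and hit.
#' @param aperiodicExponent exponent chi of the 1/f source background.
#' @param artifactGain gain on the motion artifacts shared by scalp and
#'   noise layers (0 disables them).
#' @param sensorNoiseSd white sensor noise SD, microvolts.
#' @param hitLatency mean ball-appear to hit latency, seconds.
#' @param rngSeed master seed for all generator streams.
#' @return a [SimConfig] object.
#' @examples
#' cfg <- simConfig(nParticipants = 2, sessionLength = 60, nScalp = 8,
#'                  nNoise = 8, nMuscle = 2)
#' cfg
#' @export
simConfig <- function(nParticipants = 3,
                      sessionLength = 450,
                      fsEeg = 500, fsImu = 2000,
                      nScalp = 120, nNoise = nScalp, nMuscle = 8,
                      eventRate = 0.5,
                      eventJitterSd = c(machine = 0.025, human = 0.150),
                      erpAmplitude = c(machine = 4, human = 0),
                      erdDepth = c(alpha = 0.5, beta = 0.3),
                      aperiodicExponent = 1.5,
                      artifactGain = 1,
                      sensorNoiseSd = 1,
                      hitLatency = 0.640,
                      rngSeed = 1) {
  obj <- try(new("SimConfig",
                 nParticipants = nParticipants, sessionLength = sessionLength,
                 fsEeg = fsEeg, fsImu = fsImu, nScalp = nScalp,
                 nNoise = nNoise, nMuscle = nMuscle, eventRate = eventRate,
                 eventJitterSd = eventJitterSd, erpAmplitude = erpAmplitude,
                 erdDepth = erdDepth, aperiodicExponent = aperiodicExponent,
                 artifactGain = artifactGain, sensorNoiseSd = sensorNoiseSd,
                 hitLatency = hitLatency, rngSeed = rngSeed), silent = TRUE)
  if (inherits(obj, "try-error"))
    scStop("invalid simulation configuration: %s",
           sub(".*invalid class .SimConfig. object: ", "",
               conditionMessage(attr(obj, "condition"))))
  obj
}

#' Canonical parieto-occipital source centroids
#'
#' The four parieto-occipital cortical locations (MNI millimetres) used as
#' ground-truth source positions by the synthetic-study generator: left and
#' right parieto-occipital cortex, precuneus and cuneus.
#'
#' @return a 4 x 3 matrix of MNI coordinates with named rows.
#' @export
defaultSourceCentroids <- function() {
  matrix(c(-26.0, -68.2, 26.7,
            29.3, -66.5, 30.5,
             2.7, -53.4, 50.6,
             0.5, -85.8, 33.9),
         ncol = 3, byrow = TRUE,
         dimnames = list(c("left_parieto_occipital",
                           "right_parieto_occipital",
                           "precuneus", "cuneus"),
                         c("x", "y", "z")))
}

#' Full synthetic source layout
#'
#' The ground-truth cortical sources planted by the generator: the four
#' parieto-occipital centroids of [defaultSourceCentroids()] plus four
#' further sources (left/right frontal, supplementary motor area, left
#' sensorimotor) so that participants contribute a realistic number of
#' brain components (the canonical study retained a median of nine per
#' participant; here eight).
#'
#' @return an 8 x 3 matrix of MNI coordinates with named rows.
#' @export
syntheticSourceLayout <- function() {
  extra <- matrix(c(-35,  30, 28,
                     35,  30, 28,
                      0,  -5, 60,
                    -40, -20, 50),
                  ncol = 3, byrow = TRUE,
                  dimnames = list(c("left_frontal", "right_frontal",
                                    "supplementary_motor",
                                    "left_sensorimotor"),
                                  c("x", "y", "z")))
  rbind(defaultSourceCentroids(), extra)
}

#' Spherical scalp montage
#'
#' Deterministic quasi-uniform electrode layout on the upper unit
#' hemisphere (Fibonacci lattice), used for the synthetic montage and for
#' spherical-spline interpolation tests.
#'
#' @param n number of electrodes.
#' @return an n x 3 matrix of unit-sphere coordinates (z mostly positive).
#' @export
sphericalMontage <- function(n) {
  i <- seq_len(n) - 0.5
  ## upper hemisphere: z from ~1 down to slightly below the equator
  z <- 1 - i / n * 1.1
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  theta <- golden * (seq_len(n) - 1)
  cbind(x = r * cos(theta), y = r * sin(theta), z = z)
}
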