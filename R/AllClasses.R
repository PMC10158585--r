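#' @import methods
#' @importFrom stats sd median quantile fft rnorm runif rexp mad approx
#'   kmeans dist p.adjust pt coef optim var setNames pnorm wilcox.test
#' @importFrom minpack.lm nlsLM
#' @importFrom utils head tail write.csv read.csv
#' @importFrom Rcpp evalCpp
#' @useDynLib swingcycle, .registration = TRUE
NULL

## Central data containers.  Continuous recordings, component decompositions
## and time-frequency maps are S4 classes with validity checks; light-weight
## results (spectral models, significance masks, cluster assignments) are
## plain lists with a class attribute and print methods.

#' Simulation configuration for a synthetic dual-layer EEG study
#'
#' Holds every parameter of the synthetic-study generator: recording
#' geometry (scalp/noise/muscle channel counts), sampling rates, the event
#' schedule (rate and per-condition timing jitter), the strength of the
#' phase-locked evoked response per condition, band-specific event-related
#' desynchronization depths, the aperiodic (1/f) background exponent, the
#' motion-artifact gain shared between scalp and noise layers, and the
#' master RNG seed.  Construct with [simConfig()].
#'
#' @slot nParticipants number of participants.
#' @slot sessionLength session length per condition, seconds.
#' @slot fsEeg,fsImu EEG and inertial-sensor sampling rates, Hz.
#' @slot nScalp,nNoise,nMuscle channel counts per layer; the noise layer is
#'   paired one-to-one with the scalp layer.
#' @slot eventRate ball-feed rate, Hz.
#' @slot eventJitterSd named numeric (`machine`, `human`): SD of ball-appear
#'   timing jitter around the regular feed grid, seconds.
#' @slot erpAmplitude named numeric (`machine`, `human`): amplitude of the
#'   phase-locked evoked transient at the source, microvolts.
#' @slot erdDepth named numeric (band -> fractional amplitude suppression
#'   between ball-appear and hit, e.g. `c(alpha = 0.5, beta = 0.3)`).
#' @slot aperiodicExponent spectral exponent chi of the 1/f background.
#' @slot artifactGain gain applied to the shared motion-artifact signals.
#' @slot sensorNoiseSd per-sample sensor noise SD, microvolts.
#' @slot hitLatency mean ball-appear to paddle-hit latency, seconds.
#' @slot rngSeed master seed; every stream is derived from it.
#' @exportClass SimConfig
setClass("SimConfig", representation(
  nParticipants = "numeric", sessionLength = "numeric",
  fsEeg = "numeric", fsImu = "numeric",
  nScalp = "numeric", nNoise = "numeric", nMuscle = "numeric",
  eventRate = "numeric", eventJitterSd = "numeric",
  erpAmplitude = "numeric", erdDepth = "numeric",
  aperiodicExponent = "numeric", artifactGain = "numeric",
  sensorNoiseSd = "numeric", hitLatency = "numeric",
  rngSeed = "numeric"))

setValidity("SimConfig", function(object) {
  bad <- function(msg) msg
  for (f in c("nParticipants", "sessionLength", "fsEeg", "fsImu", "nScalp",
              "nNoise", "nMuscle", "eventRate")) {
    v <- slot(object, f)
    if (length(v) != 1 || !is.finite(v) || v <= 0)
      return(bad(sprintf("field '%s' must be a single positive number", f)))
  }
  if (object@nNoise != object@nScalp)
    return(bad("field 'nNoise' must equal 'nScalp' (paired dual layers)"))
  if (object@eventRate * object@sessionLength < 10)
    return(bad("field 'sessionLength': eventRate * sessionLength must be >= 10 events"))
  for (f in c("eventJitterSd", "erpAmplitude")) {
    v <- slot(object, f)
    if (!all(c("machine", "human") %in% names(v)))
      return(bad(sprintf("field '%s' must be named with 'machine' and 'human'", f)))
    if (any(!is.finite(v)) || any(v < 0))
      return(bad(sprintf("field '%s' must be finite and non-negative", f)))
  }
  if (any(object@erdDepth < 0) || any(object@erdDepth > 1))
    return(bad("field 'erdDepth' entries must lie in [0, 1]"))
  if (object@aperiodicExponent < 0)
    return(bad("field 'aperiodicExponent' must be >= 0"))
  if (object@hitLatency <= 0 || object@hitLatency >= 1 / object@eventRate)
    return(bad("field 'hitLatency' must lie inside one feed interval"))
  TRUE
})

#' Continuous multichannel recording
#'
#' Channels-by-samples container for one participant-condition session of a
#' dual-layer mobile EEG recording, in microvolts.  Each channel carries a
#' role: `scalp` (brain + artifact), `noise` (mechanically coupled,
#' electrically isolated artifact reference), or `muscle` (EMG reference).
#' Scalp and noise channels have unit-sphere montage positions.
#'
#' @slot data numeric matrix, channels x samples (microvolts).
#' @slot fs sampling rate, Hz.
#' @slot channels data.frame with columns `name`, `role`.
#' @slot positions channels x 3 matrix of unit-sphere montage coordinates
#'   (rows of non-scalp channels may be NA).
#' @slot annotations data.frame (`onset`, `duration`, `label`), seconds.
#' @slot interpolated integer indices of channels that were reconstructed by
#'   spherical-spline interpolation.
#' @slot participant,condition identifiers.
#' @exportClass Recording
setClass("Recording", representation(
  data = "matrix", fs = "numeric", channels = "data.frame",
  positions = "matrix", annotations = "data.frame",
  interpolated = "integer", participant = "character",
  condition = "character"))

setValidity("Recording", function(object) {
  if (nrow(object@channels) != nrow(object@data))
    return("channel table and data row count differ")
  if (!all(object@channels$role %in% c("scalp", "noise", "muscle")))
    return("channel roles must be one of scalp/noise/muscle")
  if (length(object@fs) != 1 || object@fs <= 0)
    return("fs must be a single positive number")
  if (nrow(object@positions) != nrow(object@data) || ncol(object@positions) != 3)
    return("positions must be channels x 3")
  sc <- which(object@channels$role == "scalp")
  if (length(sc) && any(!is.finite(object@positions[sc, ])))
    return("positions must be finite for all scalp channels")
  TRUE
})

#' Inertial measurement unit trace
#'
#' Triaxial acceleration from a paddle- or machine-mounted inertial sensor,
#' in units of gravitational acceleration (g), sampled uniformly from time 0.
#'
#' @slot acc samples x 3 matrix (`ax`, `ay`, `az`), in g.
#' @slot fs sampling rate, Hz.
#' @slot label device label (`paddle`, `machine`, ...).
#' @slot participant,condition identifiers.
#' @exportClass ImuTrace
setClass("ImuTrace", representation(
  acc = "matrix", fs = "numeric", label = "character",
  participant = "character", condition = "character"))

setValidity("ImuTrace", function(object) {
  if (ncol(object@acc) != 3) return("acc must have 3 columns (ax, ay, az)")
  if (object@fs <= 0) return("fs must be positive")
  TRUE
})

#' Independent component decomposition for one participant
#'
#' Unmixing/mixing matrices on the scalp channels, component activations,
#' per-component source position (MNI mm), a brain/nonbrain label and the
#' fraction of scalp variance each component explains.
#'
#' @slot unmixing components x channels matrix.
#' @slot mixing channels x components matrix.
#' @slot activations components x samples matrix.
#' @slot fs sampling rate of the activations, Hz.
#' @slot participant participant identifier.
#' @slot positions components x 3 matrix, MNI millimetres (NA if unknown).
#' @slot labels character, `brain`/`nonbrain`/`unknown` per component.
#' @slot varianceExplained numeric fraction per component.
#' @exportClass ComponentSet
setClass("ComponentSet", representation(
  unmixing = "matrix", mixing = "matrix", activations = "matrix",
  fs = "numeric", participant = "character", positions = "matrix",
  labels = "character", varianceExplained = "numeric"))

setValidity("ComponentSet", function(object) {
  k <- nrow(object@unmixing)
  if (ncol(object@mixing) != k) return("mixing/unmixing dimensions disagree")
  if (nrow(object@activations) != k && length(object@activations))
    return("activations rows must equal component count")
  if (nrow(object@positions) != k || ncol(object@positions) != 3)
    return("positions must be components x 3")
  if (length(object@labels) != k || length(object@varianceExplained) != k)
    return("labels and varianceExplained must have one entry per component")
  if (!all(object@labels %in% c("brain", "nonbrain", "unknown")))
    return("labels must be brain/nonbrain/unknown")
  P <- object@unmixing %*% object@mixing
  if (max(abs(P - diag(nrow(P)))) > 1e-6)
    return("unmixing %*% mixing must be the identity on the reduced subspace")
  TRUE
})

#' Epoched single-trial data
#'
#' Trials x samples matrix of one component's (or channel's) activity,
#' time-locked to ball-appear (t = 0), with per-trial swing-cycle event
#' latencies and condition labels.
#'
#' @slot data trials x samples matrix (microvolts).
#' @slot times sample times relative to ball-appear, seconds.
#' @slot fs sampling rate, Hz.
#' @slot trialInfo data.frame, one row per trial: `t_hit`, `t_next`,
#'   `condition`, `subcondition`.
#' @slot participant,cluster identifiers.
#' @exportClass Epochs
setClass("Epochs", representation(
  data = "matrix", times = "numeric", fs = "numeric",
  trialInfo = "data.frame", participant = "character",
  cluster = "character"))

setValidity("Epochs", function(object) {
  if (ncol(object@data) != length(object@times))
    return("times must have one entry per sample")
  if (nrow(object@trialInfo) != nrow(object@data))
    return("trialInfo must have one row per trial")
  TRUE
})

#' Time-frequency decomposition of epoched data
#'
#' Complex Morlet coefficients on a trials x frequencies x times grid,
#' normalised so that a unit-amplitude sinusoid at a grid frequency yields
#' coefficient magnitude ~1 (power = squared amplitude).
#'
#' @slot coef complex array, trials x freqs x times.
#' @slot freqs analysis frequencies, Hz.
#' @slot times sample times relative to ball-appear, seconds.
#' @slot cycles wavelet cycles used at each frequency.
#' @slot trialInfo per-trial event latencies and labels (as in [Epochs]).
#' @slot participant,cluster identifiers.
#' @exportClass TimeFreqMap
setClass("TimeFreqMap", representation(
  coef = "array", freqs = "numeric", times = "numeric",
  cycles = "numeric", trialInfo = "data.frame",
  participant = "character", cluster = "character"))

setValidity("TimeFreqMap", function(object) {
  d <- dim(object@coef)
  if (length(d) != 3) return("coef must be a trials x freqs x times array")
  if (d[2] != length(object@freqs)) return("freqs length must match coef dim 2")
  if (d[3] != length(object@times)) return("times length must match coef dim 3")
  if (length(object@cycles) != length(object@freqs))
    return("cycles must have one entry per frequency")
  TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nParticipants, "participants x 2 conditions,",
      object@sessionLength, "s/session\n")
  cat("  EEG", object@fsEeg, "Hz (", object@nScalp, "scalp +", object@nNoise,
      "noise +", object@nMuscle, "muscle ch ), IMU", object@fsImu, "Hz\n")
  cat(sprintf("  events %.2g Hz; jitter SD machine %.0f ms / human %.0f ms; ERP %g / %g uV\n",
              object@eventRate, 1000 * object@eventJitterSd[["machine"]],
              1000 * object@eventJitterSd[["human"]],
              object@erpAmplitude[["machine"]], object@erpAmplitude[["human"]]))
  cat(sprintf("  chi = %.2g, artifact gain %.2g, seed %d\n",
              object@aperiodicExponent, object@artifactGain,
              as.integer(object@rngSeed)))
})

setMethod("show", "Recording", function(object) {
  tab <- table(object@channels$role)
  cat(sprintf("Recording [%s / %s]: %d ch x %d samples @ %g Hz (%.1f s)\n",
              object@participant, object@condition, nrow(object@data),
              ncol(object@data), object@fs, ncol(object@data) / object@fs))
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  if (length(object@interpolated))
    cat("  interpolated channels:",
        paste(object@interpolated, collapse = ", "), "\n")
  if (nrow(object@annotations))
    cat("  annotations:", nrow(object@annotations), "\n")
})

setMethod("show", "ImuTrace", function(object) {
  cat(sprintf("ImuTrace [%s / %s / %s]: %d samples @ %g Hz\n",
              object@participant, object@condition, object@label,
              nrow(object@acc), object@fs))
})

setMethod("show", "ComponentSet", function(object) {
  cat(sprintf("ComponentSet [%s]: %d components x %d samples @ %g Hz\n",
              object@participant, nrow(object@unmixing),
              ncol(object@activations), object@fs))
  cat("  labels:", paste(sprintf("%s=%d", names(table(object@labels)),
                                 table(object@labels)), collapse = ", "), "\n")
})

setMethod("show", "Epochs", function(object) {
  cat(sprintf("Epochs [%s%s]: %d trials x %d samples, t in [%.3g, %.3g] s\n",
              object@participant,
              if (length(object@cluster)) paste0(" / ", object@cluster) else "",
              nrow(object@data), ncol(object@data),
              min(object@times), max(object@times)))
})

setMethod("show", "TimeFreqMap", function(object) {
  d <- dim(object@coef)
  cat(sprintf("TimeFreqMap [%s]: %d trials x %d freqs (%.3g-%.3g Hz) x %d times\n",
              object@participant, d[1], d[2], min(object@freqs),
              max(object@freqs), d[3]))
})
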