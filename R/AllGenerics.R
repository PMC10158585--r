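## Accessor generics for the S4 containers.  Slot access from user code is
## discouraged; these are the supported surface.

#' Accessors for swingcycle containers
#'
#' `recData()` returns the channels x samples (or trials x samples) numeric
#' matrix; `sampleRate()` the sampling rate in Hz; `channelInfo()` the
#' channel table (`name`, `role`); `channelPositions()` the montage
#' coordinates; `componentActivations()`, `componentPositions()`,
#' `componentLabels()` and `varianceExplained()` the per-component fields of
#' a [ComponentSet]; `tfPower()`, `tfPhase()`, `tfFreqs()` and `tfTimes()`
#' the derived fields of a [TimeFreqMap]; `trialInfo()` the per-trial event
#' table of [Epochs] or [TimeFreqMap]; `epochTimes()` the epoch time axis.
#'
#' @param x a package container object.
#' @return the corresponding field; see Details.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("recData", function(x) standardGeneric("recData"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("channelInfo", function(x) standardGeneric("channelInfo"))
#' @rdname accessors
#' @export
setGeneric("channelPositions", function(x) standardGeneric("channelPositions"))
#' @rdname accessors
#' @export
setGeneric("componentActivations",
           function(x) standardGeneric("componentActivations"))
#' @rdname accessors
#' @export
setGeneric("componentPositions",
           function(x) standardGeneric("componentPositions"))
#' @rdname accessors
#' @export
setGeneric("componentLabels", function(x) standardGeneric("componentLabels"))
#' @rdname accessors
#' @export
setGeneric("varianceExplained", function(x) standardGeneric("varianceExplained"))
#' @rdname accessors
#' @export
setGeneric("tfPower", function(x) standardGeneric("tfPower"))
#' @rdname accessors
#' @export
setGeneric("tfPhase", function(x) standardGeneric("tfPhase"))
#' @rdname accessors
#' @export
setGeneric("tfFreqs", function(x) standardGeneric("tfFreqs"))
#' @rdname accessors
#' @export
setGeneric("tfTimes", function(x) standardGeneric("tfTimes"))
#' @rdname accessors
#' @export
setGeneric("trialInfo", function(x) standardGeneric("trialInfo"))
#' @rdname accessors
#' @export
setGeneric("epochTimes", function(x) standardGeneric("epochTimes"))

#' @rdname accessors
setMethod("recData", "Recording", function(x) x@data)
#' @rdname accessors
setMethod("recData", "Epochs", function(x) x@data)
#' @rdname accessors
setMethod("sampleRate", "Recording", function(x) x@fs)
#' @rdname accessors
setMethod("sampleRate", "ImuTrace", function(x) x@fs)
#' @rdname accessors
setMethod("sampleRate", "ComponentSet", function(x) x@fs)
#' @rdname accessors
setMethod("sampleRate", "Epochs", function(x) x@fs)
#' @rdname accessors
setMethod("channelInfo", "Recording", function(x) x@channels)
#' @rdname accessors
setMethod("channelPositions", "Recording", function(x) x@positions)
#' @rdname accessors
setMethod("componentActivations", "ComponentSet", function(x) x@activations)
#' @rdname accessors
setMethod("componentPositions", "ComponentSet", function(x) x@positions)
#' @rdname accessors
setMethod("componentLabels", "ComponentSet", function(x) x@labels)
#' @rdname accessors
setMethod("varianceExplained", "ComponentSet", function(x) x@varianceExplained)
#' @rdname accessors
setMethod("tfPower", "TimeFreqMap", function(x) {
  p <- abs(x@coef)^2
  dimnames(p) <- NULL
  p
})
#' @rdname accessors
setMethod("tfPhase", "TimeFreqMap", function(x) Arg(x@coef))
#' @rdname accessors
setMethod("tfFreqs", "TimeFreqMap", function(x) x@freqs)
#' @rdname accessors
setMethod("tfTimes", "TimeFreqMap", function(x) x@times)
#' @rdname accessors
setMethod("trialInfo", "Epochs", function(x) x@trialInfo)
#' @rdname accessors
setMethod("trialInfo", "TimeFreqMap", function(x) x@trialInfo)
#' @rdname accessors
setMethod("epochTimes", "Epochs", function(x) x@times)

#' Roles of channels in a recording
#'
#' Convenience wrapper returning the indices of channels with a given role.
#'
#' @param x a [Recording].
#' @param role one of `"scalp"`, `"noise"`, `"muscle"`.
#' @return integer vector of channel indices.
#' @export
channelsWithRole <- function(x, role) {
  stopifnot(is(x, "Recording"))
  role <- match.arg(role, c("scalp", "noise", "muscle"))
  which(x@channels$role == role)
}
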