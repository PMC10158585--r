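## Epoching, Morlet time-frequency decomposition with linearly scaled
## cycles, swing-cycle time warping, ERSP, ITPC, ERP, and pairwise
## event-related coherence.

#' Epoch a continuous activation around ball-appear events
#'
#' Cuts half-open `[window[1], window[2])` windows (relative to each
#' ball-appear) out of a continuous component activation.  Trials whose
#' window leaves the recording or overlaps a masked-bad sample are
#' dropped.
#'
#' @param x numeric continuous activation (microvolts).
#' @param fs sampling rate, Hz.
#' @param cycles data.frame with `t_appear`, `t_hit`, `t_next` (seconds;
#'   see [buildSwingCycles()]); extra columns `condition`/`subcondition`
#'   are carried into the trial table.
#' @param window epoch limits relative to ball-appear, seconds (default
#'   c(-1.0, 2.5): 875 samples at 250 Hz).
#' @param mask optional logical per-sample bad mask; overlapping trials
#'   are dropped.
#' @param participant,cluster identifiers.
#' @return an [Epochs] object.
#' @export
makeEpochs <- function(x, fs, cycles, window = c(-1.0, 2.5), mask = NULL,
                       participant = "P01", cluster = "") {
  nSamp <- round((window[2] - window[1]) * fs)
  rel <- round(window[1] * fs) + seq_len(nSamp) - 1
  n <- length(x)
  rows <- list(); info <- list()
  for (i in seq_len(nrow(cycles))) {
    i0 <- round(cycles$t_appear[i] * fs)
    idx <- i0 + rel + 1
    if (idx[1] < 1 || idx[length(idx)] > n) next
    if (!is.null(mask) && any(mask[idx])) next
    rows[[length(rows) + 1]] <- x[idx]
    info[[length(info) + 1]] <- data.frame(
      t_hit = cycles$t_hit[i] - cycles$t_appear[i],
      t_next = cycles$t_next[i] - cycles$t_appear[i],
      condition = cycles$condition[i] %||% NA_character_,
      subcondition = cycles$subcondition[i] %||% NA_character_,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) scStop("no valid epochs (all trials out of range or masked)")
  new("Epochs", data = do.call(rbind, rows), times = rel / fs, fs = fs,
      trialInfo = do.call(rbind, info), participant = participant,
      cluster = cluster)
}

#' Reject the highest-amplitude epochs
#'
#' Ranks trials by their maximum absolute voltage and removes the top
#' `ceiling(frac * n)`; ties are broken toward keeping the lower trial
#' index.
#'
#' @param ep an [Epochs] object.
#' @param frac fraction to reject (default 0.10).
#' @return the reduced [Epochs].
#' @export
rejectEpochsByMax <- function(ep, frac = 0.10) {
  stopifnot(is(ep, "Epochs"))
  n <- nrow(ep@data)
  if (frac <= 0) return(ep)
  nRej <- min(n, ceiling(frac * n))
  peak <- apply(abs(ep@data), 1, max)
  drop <- order(-peak, -seq_len(n))[seq_len(nRej)]
  keep <- setdiff(seq_len(n), drop)
  ep@data <- ep@data[keep, , drop = FALSE]
  ep@trialInfo <- ep@trialInfo[keep, , drop = FALSE]
  rownames(ep@trialInfo) <- NULL
  ep
}

#' Randomly subsample epochs to a fixed count
#'
#' Draws a seeded uniform subset of `n` trials so that conditions with
#' very different trial counts can be compared on equal footing.  When
#' fewer than `n` trials are available all are kept, with a warning.
#'
#' @param ep an [Epochs] object.
#' @param n target trial count (default 70).
#' @param seed integer seed.
#' @return the subsampled [Epochs].
#' @export
subsampleEpochs <- function(ep, n = 70, seed = 1) {
  stopifnot(is(ep, "Epochs"))
  nt <- nrow(ep@data)
  if (nt < n) {
    warning(sprintf("only %d epochs available (requested %d): keeping all",
                    nt, n))
    return(ep)
  }
  keep <- sort(withSeed(seed, sample.int(nt, n)))
  ep@data <- ep@data[keep, , drop = FALSE]
  ep@trialInfo <- ep@trialInfo[keep, , drop = FALSE]
  rownames(ep@trialInfo) <- NULL
  ep
}

## Linear cycle schedule between the grid extremes.
cycleSchedule <- function(freqs, cycleRange = c(3, 64)) {
  fmin <- min(freqs); fmax <- max(freqs)
  if (fmax == fmin) return(rep(cycleRange[1], length(freqs)))
  cycleRange[1] + (cycleRange[2] - cycleRange[1]) * (freqs - fmin) / (fmax - fmin)
}

#' Default log-spaced analysis frequency grid
#'
#' @param range frequency range, Hz.
#' @param n number of bins.
#' @return numeric vector of frequencies.
#' @export
defaultFreqGrid <- function(range = c(3, 50), n = 60)
  exp(seq(log(range[1]), log(range[2]), length.out = n))

#' Morlet time-frequency transform of epoched data
#'
#' Convolves every trial with complex Morlet wavelets whose cycle count
#' increases linearly with frequency from `cycleRange[1]` at the lowest
#' grid frequency to `cycleRange[2]` at the highest.  Coefficients are
#' normalised so a unit-amplitude sinusoid at a grid frequency yields
#' magnitude ~1 (power = squared amplitude).
#'
#' @param ep an [Epochs] object.
#' @param freqs analysis frequencies, Hz (default [defaultFreqGrid()]).
#' @param cycleRange cycles at the grid extremes (default c(3, 64)).
#' @param decim keep every `decim`-th time sample of the output (1 = all).
#' @return a [TimeFreqMap].
#' @export
morletTransform <- function(ep, freqs = defaultFreqGrid(),
                            cycleRange = c(3, 64), decim = 1) {
  stopifnot(is(ep, "Epochs"))
  fs <- ep@fs
  nS <- ncol(ep@data)
  cyc <- cycleSchedule(freqs, cycleRange)
  epochLen <- nS / fs
  ## the lowest-frequency wavelet must fit inside the epoch; longer
  ## wavelets higher up the linear cycle schedule are zero-padded and
  ## increasingly temporally smoothed instead
  if (cyc[1] / freqs[1] > epochLen) {
    usable <- freqs[cyc / freqs <= epochLen]
    if (length(usable))
      scStop("epoch too short for %g cycles at %.3g Hz; minimum usable frequency is %.3g Hz",
             cyc[1], freqs[1], min(usable))
    scStop("epoch too short for %g cycles at %.3g Hz; no requested frequency is usable",
           cyc[1], freqs[1])
  }
  kernels <- lapply(seq_along(freqs), function(i) {
    sdT <- cyc[i] / (2 * pi * freqs[i])
    tW <- seq(-3.5 * sdT, 3.5 * sdT, by = 1 / fs)
    env <- exp(-tW^2 / (2 * sdT^2))
    k <- exp(2i * pi * freqs[i] * tW) * env
    k * 2 / sum(env)
  })
  maxLen <- max(vapply(kernels, length, integer(1)))
  L <- nextPow2(nS + maxLen - 1)
  Kf <- lapply(kernels, function(k) fft(c(k, rep(0, L - length(k)))))
  starts <- vapply(kernels, function(k) as.integer(length(k) %/% 2 + 1), integer(1))
  tIdx <- seq(1, nS, by = decim)
  nT <- nrow(ep@data)
  out <- array(0i, c(nT, length(freqs), length(tIdx)))
  for (tr in seq_len(nT)) {
    Xf <- fft(c(ep@data[tr, ], rep(0, L - nS)))
    for (i in seq_along(freqs)) {
      full <- fft(Xf * Kf[[i]], inverse = TRUE) / L
      out[tr, i, ] <- full[(starts[i] - 1) + tIdx]
    }
  }
  new("TimeFreqMap", coef = out, freqs = freqs, times = ep@times[tIdx],
      cycles = cyc, trialInfo = ep@trialInfo, participant = ep@participant,
      cluster = ep@cluster)
}

## Piecewise-linear template->trial time map through the swing-cycle
## anchors, with the epoch edges fixed.
warpSourceTimes <- function(times, trialAnchors, templateAnchors) {
  src <- c(times[1], trialAnchors, times[length(times)])
  dst <- c(times[1], templateAnchors, times[length(times)])
  if (any(diff(src) <= 0) || any(diff(dst) <= 0)) return(NULL)
  approx(dst, src, xout = times, rule = 2)$y
}

#' Linearly time-warp single-trial spectrograms to a template swing cycle
#'
#' Each trial's time axis is piecewise-linearly mapped so that its
#' ball-appear (0), hit and next-appear latencies land on the template
#' (median) latencies, with the epoch edges held fixed.  Power and phase
#' are interpolated linearly (phase via unit phasors); trials with
#' non-monotone anchors are dropped.
#'
#' @param tf a [TimeFreqMap].
#' @param template named numeric with `hit` and `next_appear` template
#'   latencies, seconds (see [buildSwingCycles()]).
#' @return the warped [TimeFreqMap]; its trial table carries the original
#'   latencies.
#' @export
timeWarp <- function(tf, template) {
  stopifnot(is(tf, "TimeFreqMap"))
  tmpl <- c(0, template[["hit"]], template[["next_appear"]])
  d <- dim(tf@coef)
  keep <- logical(d[1])
  out <- tf@coef
  for (tr in seq_len(d[1])) {
    anchors <- c(0, tf@trialInfo$t_hit[tr], tf@trialInfo$t_next[tr])
    srcT <- warpSourceTimes(tf@times, anchors, tmpl)
    if (is.null(srcT)) next
    keep[tr] <- TRUE
    for (i in seq_len(d[2])) {
      pw <- abs(tf@coef[tr, i, ])^2
      ph <- tf@coef[tr, i, ] / pmax(abs(tf@coef[tr, i, ]), 1e-300)
      pwW <- approx(tf@times, pw, xout = srcT, rule = 2)$y
      re <- approx(tf@times, Re(ph), xout = srcT, rule = 2)$y
      im <- approx(tf@times, Im(ph), xout = srcT, rule = 2)$y
      mag <- pmax(sqrt(re^2 + im^2), 1e-300)
      out[tr, i, ] <- sqrt(pmax(pwW, 0)) * complex(real = re, imaginary = im) / mag
    }
  }
  if (!any(keep)) scStop("no trials with monotone swing-cycle anchors")
  if (any(!keep))
    message(sprintf("timeWarp: dropped %d trial(s) with non-monotone anchors",
                    sum(!keep)))
  tf@coef <- out[keep, , , drop = FALSE]
  tf@trialInfo <- tf@trialInfo[keep, , drop = FALSE]
  rownames(tf@trialInfo) <- NULL
  tf
}

#' Swing-cycle baseline pooled across conditions
#'
#' Mean single-trial power per frequency over all times and all trials of
#' every supplied map (both conditions), i.e. the average power across the
#' swing cycle for all conditions.
#'
#' @param tfList list of [TimeFreqMap]s.
#' @return numeric baseline power per frequency.
#' @export
pooledBaseline <- function(tfList) {
  if (is(tfList, "TimeFreqMap")) tfList <- list(tfList)
  num <- 0; den <- 0
  for (tf in tfList) {
    p <- abs(tf@coef)^2
    num <- num + apply(p, 2, sum)
    den <- den + dim(p)[1] * dim(p)[3]
  }
  num / den
}

#' Event-related spectral perturbation
#'
#' `ERSP(f, t) = 10 log10(mean_trials P(f, t) / baseline(f))`, with the
#' baseline taken as the swing-cycle average power pooled across
#' conditions (pass the same `baseline` to every condition's call; by
#' default the map's own pooled baseline is used).
#'
#' @param tf a [TimeFreqMap] (typically time-warped).
#' @param baseline per-frequency baseline power from [pooledBaseline()].
#' @return freqs x times ERSP matrix, dB.
#' @export
ersp <- function(tf, baseline = NULL) {
  stopifnot(is(tf, "TimeFreqMap"))
  if (is.null(baseline)) baseline <- pooledBaseline(tf)
  if (any(baseline <= 0)) scStop("zero baseline power")
  p <- abs(tf@coef)^2
  m <- apply(p, c(2, 3), mean)
  10 * log10(m / baseline)
}

#' Intertrial phase coherence
#'
#' Resultant length of the per-trial unit phase vectors at each
#' time-frequency cell: 1 = perfect phase locking, ~0 = uniform phase.
#' Computed on unwarped maps (phase locking is defined relative to the
#' ball-appear event itself).
#'
#' @param tf a [TimeFreqMap].
#' @return freqs x times ITPC matrix in `[0, 1]`.
#' @export
itpc <- function(tf) {
  stopifnot(is(tf, "TimeFreqMap"))
  u <- tf@coef / pmax(abs(tf@coef), 1e-300)
  Mod(apply(u, c(2, 3), mean))
}

#' Subset the trials of an Epochs object or TimeFreqMap
#'
#' Because the Morlet transform is per-trial, subsetting coefficients is
#' identical to transforming the subset; used to partition rally and serve
#' trials without recomputing the decomposition.
#'
#' @param x an [Epochs] or [TimeFreqMap].
#' @param idx trial indices to keep.
#' @return the subset object.
#' @export
subsetTrials <- function(x, idx) {
  if (is(x, "Epochs")) {
    x@data <- x@data[idx, , drop = FALSE]
  } else if (is(x, "TimeFreqMap")) {
    x@coef <- x@coef[idx, , , drop = FALSE]
  } else scStop("x must be Epochs or TimeFreqMap")
  x@trialInfo <- x@trialInfo[idx, , drop = FALSE]
  rownames(x@trialInfo) <- NULL
  x
}

#' Event-related potential
#'
#' Trial-mean waveform per participant, then the grand mean across
#' participants.
#'
#' @param epList an [Epochs] object or list of them (one per participant).
#' @return list: `times`, `participantMeans` (participants x samples),
#'   `grand` (numeric waveform).
#' @export
erp <- function(epList) {
  if (is(epList, "Epochs")) epList <- list(epList)
  pm <- do.call(rbind, lapply(epList, function(e) colMeans(e@data)))
  list(times = epList[[1]]@times, participantMeans = pm,
       grand = colMeans(pm))
}

#' Event-related coherence between two components
#'
#' Normalised magnitude of the trial-summed cross-spectrum,
#' `|sum A conj(B)| / sqrt(sum |A|^2 sum |B|^2)`, on matched epochs of two
#' simultaneously recorded components (same trials in both maps).
#'
#' @param tfA,tfB [TimeFreqMap]s with identical trial structure.
#' @return freqs x times coherence matrix in `[0, 1]`.
#' @export
eventRelatedCoherence <- function(tfA, tfB) {
  stopifnot(is(tfA, "TimeFreqMap"), is(tfB, "TimeFreqMap"))
  if (!all(dim(tfA@coef) == dim(tfB@coef)))
    scStop("trial mismatch: the two maps must hold the same matched epochs")
  cross <- apply(tfA@coef * Conj(tfB@coef), c(2, 3), sum)
  pa <- apply(abs(tfA@coef)^2, c(2, 3), sum)
  pb <- apply(abs(tfB@coef)^2, c(2, 3), sum)
  Mod(cross) / pmax(sqrt(pa * pb), 1e-300)
}
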