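## Continuous-data cleaning: zero-phase FIR high-pass, sliding-window
## sinusoidal line-noise regression, band-limited FFT resampling, robust
## bad-channel rejection, full-rank average reference with spherical-spline
## interpolation, dual-layer CCA denoising, and amplitude-based window
## rejection.  Pipeline order: highpass -> line noise -> resample ->
## channel rejection -> rereference/interpolate -> ccaClean(noise, 0.85)
## -> ccaClean(muscle, 0.40) -> rejectWindows.

## Zero-phase application of an odd-length linear-phase FIR kernel with
## reflection padding.
firFilterZeroPhase <- function(x, h) {
  p <- (length(h) - 1) / 2
  n <- length(x)
  pr <- min(p, n - 1)
  xp <- c(rev(x[2:(pr + 1)]), x, rev(x[(n - pr):(n - 1)]))
  if (pr < p) xp <- c(rep(xp[1], p - pr), xp, rep(xp[length(xp)], p - pr))
  y <- Re(fftConvSame(xp, h))
  y[(p + 1):(p + n)]
}

#' High-pass filter a recording
#'
#' Windowed-sinc (Hamming) zero-phase linear-phase FIR high-pass applied to
#' every channel, with the transition bandwidth `min(max(cutoff * 0.25,
#' 2 Hz), cutoff)` centred on the cutoff, and channel means removed.
#'
#' @param rec a [Recording].
#' @param cutoff high-pass cutoff (passband edge), Hz; must be below
#'   Nyquist.
#' @return the filtered [Recording].
#' @export
highpass <- function(rec, cutoff = 1.0) {
  stopifnot(is(rec, "Recording"))
  fs <- rec@fs
  if (cutoff >= fs / 2) scStop("cutoff must be below the Nyquist frequency")
  tb <- min(max(cutoff * 0.25, 2), cutoff)
  ord <- ceiling(3.3 / (tb / fs))
  if (ord %% 2 == 1) ord <- ord + 1           # even order -> odd length
  f6 <- max(cutoff - tb / 2, cutoff / 2)      # -6 dB point
  h <- signal::fir1(ord, f6 / (fs / 2), type = "high",
                    window = signal::hamming(ord + 1))
  x <- rec@data - rowMeans(rec@data)
  for (i in seq_len(nrow(x))) x[i, ] <- firFilterZeroPhase(x[i, ], h)
  rec@data <- x
  rec
}

#' Remove power-line noise
#'
#' Sliding-window sinusoidal regression: in 4 s Hann-stitched windows
#' (50% overlap) the best-fitting sine/cosine pair at `lineFreq` (and its
#' first harmonic, if below Nyquist) is estimated per channel and
#' subtracted.  Adapts to slow amplitude/phase drift of the line component
#' while leaving neighbouring frequencies essentially untouched.
#'
#' @param rec a [Recording].
#' @param lineFreq line frequency, Hz (60 by default).
#' @param harmonics number of harmonics to remove (1 = fundamental only).
#' @param window regression window length, seconds.
#' @return the cleaned [Recording].
#' @export
removeLineNoise <- function(rec, lineFreq = 60, harmonics = 1, window = 4) {
  stopifnot(is(rec, "Recording"))
  fs <- rec@fs
  if (lineFreq >= fs / 2) scStop("lineFreq must be below the Nyquist frequency")
  X <- rec@data
  n <- ncol(X)
  wl <- min(n, round(window * fs))
  hop <- max(1, floor(wl / 2))
  starts <- unique(c(seq(1, max(1, n - wl + 1), by = hop), n - wl + 1))
  w <- hannWindow(wl)
  acc <- matrix(0, nrow(X), n)
  wsum <- numeric(n)
  freqs <- lineFreq * seq_len(harmonics)
  freqs <- freqs[freqs < fs / 2]
  for (s in starts) {
    idx <- s:(s + wl - 1)
    tW <- (idx - 1) / fs
    Xw <- X[, idx, drop = FALSE]
    fit <- matrix(0, nrow(X), wl)
    for (f in freqs) {
      cs <- cos(2 * pi * f * tW); sn <- sin(2 * pi * f * tW)
      a <- (Xw %*% cs) * 2 / wl
      b <- (Xw %*% sn) * 2 / wl
      fit <- fit + a %*% t(cs) + b %*% t(sn)
    }
    acc[, idx] <- acc[, idx] + sweep(Xw - fit, 2, w, `*`)
    wsum[idx] <- wsum[idx] + w
  }
  bad <- wsum < 1e-12
  acc[, !bad] <- sweep(acc[, !bad, drop = FALSE], 2, wsum[!bad], `/`)
  acc[, bad] <- X[, bad]
  rec@data <- acc
  rec
}

## Band-limited FFT resampling of one vector to n2 samples.
fftResampleVec <- function(x, n2) {
  n <- length(x)
  if (n2 == n) return(x)
  X <- fft(x)
  Y <- complex(n2)
  m <- min(n, n2)
  half <- m %/% 2
  Y[1] <- X[1]
  if (half > 1) {
    k <- seq_len(half - 1)
    Y[k + 1] <- X[k + 1]
    Y[n2 - k + 1] <- X[n - k + 1]
  }
  if (m %% 2 == 0) {
    ## shared Nyquist bin: fold symmetric energy
    if (n2 < n) Y[half + 1] <- X[half + 1] + X[n - half + 1]
    else { Y[half + 1] <- 0.5 * X[half + 1]; Y[n2 - half + 1] <- 0.5 * X[n - half + 1] }
  }
  Re(fft(Y, inverse = TRUE)) / n
}

#' Resample a recording
#'
#' Band-limited (FFT) resampling of every channel; the implicit brick-wall
#' anti-aliasing filter at the new Nyquist frequency leaves passband
#' amplitudes untouched.  Annotations stay in seconds and need no change.
#'
#' @param rec a [Recording].
#' @param targetFs target sampling rate, Hz (must not exceed the current
#'   rate unless `allowUpsample`).
#' @param allowUpsample permit `targetFs > fs`.
#' @return the resampled [Recording].
#' @export
resampleRecording <- function(rec, targetFs = 250, allowUpsample = FALSE) {
  stopifnot(is(rec, "Recording"))
  if (targetFs > rec@fs && !allowUpsample)
    scStop("upsampling requested (%g -> %g Hz) but not allowed",
           rec@fs, targetFs)
  n <- ncol(rec@data)
  n2 <- round(n * targetFs / rec@fs)
  out <- matrix(0, nrow(rec@data), n2)
  for (i in seq_len(nrow(rec@data)))
    out[i, ] <- fftResampleVec(rec@data[i, ], n2)
  rec@data <- out
  rec@fs <- targetFs
  rec
}

#' Reject outlying channels per layer
#'
#' For each channel role with at least `minChannels` channels, computes a
#' robust per-channel amplitude statistic (log RMS) and flags channels
#' whose statistic deviates from the median of the remaining channels by
#' more than `zThresh` standard deviations (of the remaining channels);
#' the screen is iterated once more on the survivors.  Flat channels fall
#' far below the median and are caught by the same rule.
#'
#' @param rec a [Recording].
#' @param zThresh rejection threshold in SD units (default 3).
#' @param roles which roles to screen.
#' @param minChannels smallest layer size screened.
#' @return list with `recording` (unchanged data) and `rejected` (integer
#'   channel indices).
#' @export
rejectBadChannels <- function(rec, zThresh = 3,
                              roles = c("scalp", "noise"),
                              minChannels = 8) {
  stopifnot(is(rec, "Recording"))
  rejected <- integer(0)
  for (role in roles) {
    chans <- channelsWithRole(rec, role)
    if (length(chans) < minChannels) next
    stat <- logRms(rec@data[chans, , drop = FALSE])
    bad <- logical(length(chans))
    for (pass in 1:2) {
      pool <- which(!bad)
      for (i in pool) {
        others <- stat[setdiff(pool, i)]
        dev <- stat[i] - median(others)
        s <- sd(others)
        if (s > 0 && abs(dev) > zThresh * s) bad[i] <- TRUE
      }
    }
    if (sum(bad) > 0.5 * length(chans))
      scStop("data quality: more than half of the %s channels rejected", role)
    rejected <- c(rejected, chans[bad])
  }
  list(recording = rec, rejected = sort(rejected))
}

## ---- spherical-spline interpolation ------------------------------------

## Perrin-style g function: truncated Legendre series with stiffness m = 4.
sphericalG <- function(cosTheta, m = 4, nTerms = 50) {
  dd <- dim(cosTheta)
  cosTheta <- pmin(1, pmax(-1, cosTheta))
  dim(cosTheta) <- dd
  g <- 0 * cosTheta
  Pprev <- 1 + 0 * cosTheta   # P_0
  Pcur <- cosTheta            # P_1
  for (l in seq_len(nTerms)) {
    g <- g + (2 * l + 1) / (l^m * (l + 1)^m) * Pcur
    Pnext <- ((2 * l + 1) * cosTheta * Pcur - l * Pprev) / (l + 1)
    Pprev <- Pcur; Pcur <- Pnext
  }
  g / (4 * pi)
}

## Interpolate bad channels from good ones on the unit sphere.
sphericalSplineInterpolate <- function(goodPos, badPos, goodData,
                                       lambda = 1e-8) {
  ng <- nrow(goodPos)
  G <- sphericalG(tcrossprod(goodPos))
  A <- rbind(cbind(G + diag(lambda, ng), rep(1, ng)), c(rep(1, ng), 0))
  rhs <- rbind(goodData, 0)
  sol <- solve(A, rhs)
  C <- sol[seq_len(ng), , drop = FALSE]
  d <- sol[ng + 1, ]
  Gb <- sphericalG(tcrossprod(badPos, goodPos))
  Gb %*% C + matrix(d, nrow(badPos), length(d), byrow = TRUE)
}

#' Average-reference a recording and interpolate rejected channels
#'
#' The scalp and noise layers are processed independently: within each
#' layer the average reference over the retained channels is subtracted
#' (full rank: no channel is removed from the dataset) and every rejected
#' channel is reconstructed by spherical-spline interpolation (stiffness 4,
#' 50-term Legendre truncation) from the retained channels of its layer.
#' Muscle channels are untouched.
#'
#' @param rec a [Recording].
#' @param rejected integer channel indices from [rejectBadChannels()].
#' @return the re-referenced [Recording], with the `interpolated` slot set.
#' @export
rereferenceInterpolate <- function(rec, rejected = integer(0)) {
  stopifnot(is(rec, "Recording"))
  for (role in c("scalp", "noise")) {
    chans <- channelsWithRole(rec, role)
    if (!length(chans)) next
    badHere <- intersect(chans, rejected)
    good <- setdiff(chans, badHere)
    if (length(badHere) && any(!is.finite(rec@positions[badHere, ])))
      scStop("missing montage positions for rejected channels")
    ref <- colMeans(rec@data[good, , drop = FALSE])
    rec@data[chans, ] <- sweep(rec@data[chans, , drop = FALSE], 2, ref)
    if (length(badHere)) {
      rec@data[badHere, ] <- sphericalSplineInterpolate(
        rec@positions[good, , drop = FALSE],
        rec@positions[badHere, , drop = FALSE],
        rec@data[good, , drop = FALSE])
    }
  }
  rec@interpolated <- sort(unique(c(rec@interpolated,
                                    as.integer(rejected))))
  rec
}

## ---- dual-layer CCA denoising ------------------------------------------

## Regularized CCA between two centred sample x variable matrices.
## Returns squared canonical correlations and the X-side canonical
## directions (columns), ordered by decreasing r^2.
regularizedCca <- function(X, Y, ridge = 1e-6, pcTol = 1e-6) {
  n <- nrow(X)
  Cxx <- crossprod(X) / n
  Cyy <- crossprod(Y) / n
  ## restrict both sides to their significant principal subspaces so that
  ## near-zero-variance directions (e.g. a rank-deficient reference layer)
  ## cannot produce spurious canonical correlations
  ex <- eigen(Cxx, symmetric = TRUE)
  kx <- which(ex$values > pcTol * ex$values[1])
  ey <- eigen(Cyy, symmetric = TRUE)
  ky <- which(ey$values > pcTol * ey$values[1])
  if (!length(kx) || !length(ky))
    return(list(r2 = numeric(0), xdirs = matrix(0, ncol(X), 0)))
  evx <- ex$values[kx] * (1 + ridge)
  Wx <- ex$vectors[, kx, drop = FALSE] %*% diag(1 / sqrt(evx), length(kx))
  evy <- ey$values[ky] * (1 + ridge)
  Wy <- ey$vectors[, ky, drop = FALSE] %*% diag(1 / sqrt(evy), length(ky))
  ## whitened cross-covariance; its singular values are the canonical corrs
  K <- crossprod(Wx, crossprod(X, Y) / n) %*% Wy
  sv <- svd(K)
  list(r2 = pmin(1, sv$d^2), xdirs = Wx %*% sv$u, ydirs = Wy %*% sv$v)
}

#' Remove reference-correlated subspaces by sliding-window CCA
#'
#' In Hann-stitched sliding windows (default 2 s, 50% hop), canonical
#' correlation analysis is run between the scalp channels and the
#' reference layer (`noise` for motion artifacts, `muscle` for EMG).
#' Canonical scalp components whose squared canonical correlation exceeds
#' `r2Thresh` are projected out of the scalp data within the window.  A
#' small ridge (1e-6 of the covariance trace) keeps the estimates stable
#' when windows are short relative to the channel count.  Reference and
#' muscle channels are never modified.
#'
#' @param rec a [Recording].
#' @param referenceRole `"noise"` or `"muscle"`.
#' @param window window length, seconds.
#' @param r2Thresh squared-canonical-correlation rejection threshold
#'   (0.85 for the noise layer, 0.40 for the muscle layer).
#' @return the cleaned [Recording].
#' @export
ccaClean <- function(rec, referenceRole = c("noise", "muscle"),
                     window = 2.0, r2Thresh = 0.85) {
  stopifnot(is(rec, "Recording"))
  referenceRole <- match.arg(referenceRole)
  scalp <- channelsWithRole(rec, "scalp")
  refCh <- channelsWithRole(rec, referenceRole)
  if (!length(refCh)) scStop("no channels with role '%s'", referenceRole)
  X <- t(rec@data[scalp, , drop = FALSE])    # samples x channels
  Y <- t(rec@data[refCh, , drop = FALSE])
  n <- nrow(X)
  wl <- min(n, round(window * rec@fs))
  hop <- max(1, floor(wl / 2))
  starts <- unique(c(seq(1, max(1, n - wl + 1), by = hop), n - wl + 1))
  w <- hannWindow(wl)
  acc <- matrix(0, n, ncol(X))
  wsum <- numeric(n)
  skipped <- 0L
  for (s in starts) {
    idx <- s:(s + wl - 1)
    Xw <- X[idx, , drop = FALSE]
    Yw <- Y[idx, , drop = FALSE]
    mx <- colMeans(Xw)
    Xc <- sweep(Xw, 2, mx)
    Yc <- sweep(Yw, 2, colMeans(Yw))
    cleaned <- Xw
    if (all(apply(Yc, 2, function(v) all(v == 0)))) {
      skipped <- skipped + 1L
    } else if (r2Thresh < 1) {
      cc <- regularizedCca(Xc, Yc)
      sel <- which(cc$r2 > r2Thresh)
      if (length(sel)) {
        ## the scalp subspace to reject is estimated from the reference-side
        ## canonical variates (artifact-only time courses), so brain signal
        ## uncorrelated with the reference is not drawn into the projector
        V <- Yc %*% cc$ydirs[, sel, drop = FALSE]
        beta <- solve(crossprod(V) + diag(1e-12, ncol(V)), crossprod(V, Xc))
        cleaned <- sweep(Xc - V %*% beta, 2, mx, `+`)
      }
    }
    acc[idx, ] <- acc[idx, ] + w * cleaned
    wsum[idx] <- wsum[idx] + w
  }
  ok <- wsum > 1e-12
  acc[ok, ] <- acc[ok, , drop = FALSE] / wsum[ok]
  acc[!ok, ] <- X[!ok, , drop = FALSE]
  rec@data[scalp, ] <- t(acc)
  if (skipped > 0)
    message(sprintf("ccaClean: %d window(s) skipped (zero-variance reference)",
                    skipped))
  rec
}

#' Mark high-amplitude time windows as bad
#'
#' Scans 1 s windows (50% overlap) and marks a window bad when the
#' fraction of scalp channels whose peak absolute amplitude exceeds
#' `sdThresh` times the channel's robust SD (1.4826 x MAD over the whole
#' recording) is greater than `windowCriterion`.  Bad samples are returned
#' as a mask; the continuous record is never altered, so masked stretches
#' can be excluded from ICA fitting while decompositions are still applied
#' to the full timeline.
#'
#' @param rec a [Recording].
#' @param sdThresh per-channel amplitude threshold, robust-SD units.
#' @param windowCriterion fraction of offending channels that condemns a
#'   window.
#' @param window window length, seconds.
#' @return list with `recording`, `mask` (logical per sample, TRUE = bad)
#'   and `fractionRejected`.
#' @export
rejectWindows <- function(rec, sdThresh = 30, windowCriterion = 0.3,
                          window = 1.0) {
  stopifnot(is(rec, "Recording"))
  scalp <- channelsWithRole(rec, "scalp")
  X <- rec@data[scalp, , drop = FALSE]
  n <- ncol(X)
  robustSd <- apply(X, 1, mad) * 1  # mad() already scales by 1.4826
  robustSd <- pmax(robustSd, .Machine$double.eps)
  wl <- min(n, max(2, round(window * rec@fs)))
  hop <- max(1, floor(wl / 2))
  starts <- unique(c(seq(1, max(1, n - wl + 1), by = hop), n - wl + 1))
  mask <- rep(FALSE, n)
  for (s in starts) {
    idx <- s:(s + wl - 1)
    peak <- apply(abs(X[, idx, drop = FALSE]), 1, max)
    frac <- mean(peak > sdThresh * robustSd)
    if (frac > windowCriterion) mask[idx] <- TRUE
  }
  if (mean(mask) > 0.8)
    scStop("data quality: more than 80%% of samples marked bad")
  list(recording = rec, mask = mask, fractionRejected = mean(mask))
}

#' Run the full continuous-cleaning chain on one recording
#'
#' Applies, in order: high-pass filtering, line-noise removal, resampling,
#' per-layer bad-channel rejection, full-rank average referencing with
#' spherical interpolation, CCA denoising against the noise layer
#' (r2 > 0.85) then against the muscle layer (r2 > 0.40), and bad-window
#' marking.
#'
#' @param rec a [Recording].
#' @param params parameter list from [analysisParams()].
#' @return list with `recording` (cleaned), `mask`, `rejectedChannels`,
#'   `fractionRejected`.
#' @export
preprocessRecording <- function(rec, params = analysisParams()) {
  rec <- highpass(rec, params$hpCutoff)
  rec <- removeLineNoise(rec, params$lineFreq)
  if (params$targetFs < rec@fs)
    rec <- resampleRecording(rec, params$targetFs)
  rb <- rejectBadChannels(rec, params$chanZ)
  rec <- rereferenceInterpolate(rb$recording, rb$rejected)
  rec <- ccaClean(rec, "noise", params$ccaWindow, params$ccaR2Noise)
  if (length(channelsWithRole(rec, "muscle")))
    rec <- ccaClean(rec, "muscle", params$ccaWindow, params$ccaR2Muscle)
  rw <- rejectWindows(rec, params$rwSd, params$rwCrit)
  list(recording = rw$recording, mask = rw$mask,
       rejectedChannels = rb$rejected,
       fractionRejected = rw$fractionRejected)
}
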