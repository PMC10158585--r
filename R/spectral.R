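## Welch power spectra of component activations, aperiodic + periodic
## spectral parameterisation, flattened spectra, and per-frequency paired
## condition comparison with BH-FDR.

#' Welch power spectral density
#'
#' Average periodogram over non-overlapping Hamming-windowed segments.
#' With `fs = 250` and the default 250-sample window the frequency grid
#' spacing is 1 Hz.  Powers are densities in signal-units^2 per Hz
#' (one-sided), so a unit-amplitude sinusoid integrates to ~0.5.
#'
#' @param x numeric signal (component activation, microvolts).
#' @param fs sampling rate, Hz.
#' @param winLen segment length, samples (default 250).
#' @return list of class `Psd`: `freqs` (Hz), `power` (uV^2/Hz),
#'   `logPower` (dB, 10 log10 power), `fs`, `winLen`, `nSegments`.
#' @export
welchPsd <- function(x, fs, winLen = 250) {
  n <- length(x)
  if (n < 2 * winLen)
    scStop("signal too short: need at least two %d-sample segments", winLen)
  nSeg <- n %/% winLen
  w <- signal::hamming(winLen)
  scale <- fs * sum(w^2)
  nf <- winLen %/% 2 + 1
  acc <- numeric(nf)
  for (s in seq_len(nSeg)) {
    seg <- x[((s - 1) * winLen + 1):(s * winLen)] * w
    P <- abs(fft(seg))^2 / scale
    acc <- acc + P[seq_len(nf)]
  }
  pw <- acc / nSeg
  ## one-sided: double everything except DC and (for even winLen) Nyquist
  dbl <- rep(2, nf); dbl[1] <- 1
  if (winLen %% 2 == 0) dbl[nf] <- 1
  pw <- pw * dbl
  structure(list(freqs = seq(0, by = fs / winLen, length.out = nf),
                 power = pw, logPower = 10 * log10(pmax(pw, 1e-300)),
                 fs = fs, winLen = winLen, nSegments = nSeg),
            class = "Psd")
}

#' @export
print.Psd <- function(x, ...) {
  cat(sprintf("Psd: %d bins, %.3g-%.3g Hz (df = %.3g Hz), %d segments\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              x$freqs[2] - x$freqs[1], x$nSegments))
  invisible(x)
}

## Robust aperiodic (offset + exponent) fit in log10-log10 coordinates:
## ordinary fit, then refit excluding the top 2.5% positive residuals so
## oscillatory peaks do not drag the line up.
aperiodicFit <- function(logF, y) {
  fit <- stats::lm.fit(cbind(1, logF), y)
  res <- fit$residuals
  keep <- res <= quantile(res, 0.975)
  fit <- stats::lm.fit(cbind(1, logF[keep]), y[keep])
  c(offset = fit$coefficients[[1]], slope = fit$coefficients[[2]])
}

gaussianPeak <- function(f, center, height, width)
  height * exp(-(f - center)^2 / (2 * width^2))

## Fit one Gaussian to a residual spectrum around its maximum, bounded.
fitOnePeak <- function(f, resid, widthLimits, minHeight) {
  i <- which.max(resid)
  h0 <- resid[i]
  if (h0 < minHeight) return(NULL)
  c0 <- f[i]
  ## half-height span estimate for the width
  above <- resid >= h0 / 2
  lo <- i; while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- i; while (hi < length(f) && above[hi + 1]) hi <- hi + 1
  w0 <- max(widthLimits[1], min(widthLimits[2], (f[hi] - f[lo]) / 2.355))
  dfr <- data.frame(f = f, y = resid)
  fit <- try(suppressWarnings(nlsLM(
    y ~ h * exp(-(f - c)^2 / (2 * w^2)), data = dfr,
    start = list(h = h0, c = c0, w = w0),
    lower = c(h = minHeight / 2, c = min(f), w = widthLimits[1]),
    upper = c(h = Inf, c = max(f), w = widthLimits[2]),
    control = minpack.lm::nls.lm.control(maxiter = 200))), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(c(center = c0, height = h0, width = w0))
  p <- coef(fit)
  c(center = p[["c"]], height = p[["h"]], width = p[["w"]])
}

#' Parameterise a power spectrum into aperiodic and periodic parts
#'
#' Models log10 power over `fitRange` as a straight aperiodic line in
#' log-log coordinates (offset b and exponent chi, no knee by default)
#' plus up to `maxPeaks` Gaussian peaks in linear frequency.  The
#' aperiodic component is fit robustly, peaks are extracted greedily from
#' the flattened residual (largest first; each must exceed
#' `minPeakHeight` in log10-power units and respect the width limits),
#' and the aperiodic line is refit on the peak-removed spectrum.
#'
#' @param psd a `Psd` from [welchPsd()].
#' @param fitRange frequency range to model, Hz (default 3-40).
#' @param peakWidthLimits Gaussian width (SD) limits, Hz (default 1-8,
#'   applied as limits/2 on the SD, i.e. the limits describe approximate
#'   full widths).
#' @param minPeakHeight minimum peak height over the aperiodic fit,
#'   log10-power units (default 0.05).
#' @param maxPeaks maximum number of peaks (default 2).
#' @param knee fit an aperiodic knee parameter (default FALSE).
#' @return list of class `SpectralModel`: `offset`, `exponent`, `knee`,
#'   `peaks` (data.frame `center`, `height`, `width`), `fitRange`,
#'   `freqs`, `aperiodic` (log10 power of the aperiodic fit on the
#'   modelled grid), `fitted`, `rSquared`.
#' @export
fitSpectralModel <- function(psd, fitRange = c(3, 40),
                             peakWidthLimits = c(1, 8),
                             minPeakHeight = 0.05, maxPeaks = 2,
                             knee = FALSE) {
  sel <- psd$freqs >= fitRange[1] & psd$freqs <= fitRange[2]
  f <- psd$freqs[sel]
  if (length(f) < 5) scStop("fit range must be inside the PSD frequency grid")
  y <- psd$logPower[sel] / 10          # log10 power
  if (any(!is.finite(y))) scStop("non-finite power inside the fit range")
  logF <- log10(f)
  widthLim <- peakWidthLimits / 2      # SD bounds from width limits
  ap <- aperiodicFit(logF, y)
  extractPeaks <- function(flat) {
    peaks <- list()
    for (j in seq_len(maxPeaks)) {
      pk <- fitOnePeak(f, flat, widthLim, minPeakHeight)
      if (is.null(pk)) break
      peaks[[j]] <- pk
      flat <- flat - gaussianPeak(f, pk["center"], pk["height"], pk["width"])
    }
    peaks
  }
  peakSum <- function(peaks) {
    pm <- numeric(length(f))
    for (pk in peaks)
      pm <- pm + gaussianPeak(f, pk["center"], pk["height"], pk["width"])
    pm
  }
  ## two rounds: peaks biased by the initial aperiodic fit are re-extracted
  ## after the aperiodic line is refit on the peak-removed spectrum
  peaks <- extractPeaks(y - (ap[1] + ap[2] * logF))
  for (round in 1:2) {
    fitAp <- stats::lm.fit(cbind(1, logF), y - peakSum(peaks))
    apVals0 <- fitAp$coefficients[[1]] + fitAp$coefficients[[2]] * logF
    peaks <- extractPeaks(y - apVals0)
  }
  peakModel <- peakSum(peaks)
  ## final aperiodic fit on the peak-removed spectrum
  yAp <- y - peakModel
  if (knee) {
    dfr <- data.frame(lf = f, y = yAp)
    kf <- try(suppressWarnings(nlsLM(
      y ~ b - log10(k + lf^chi), data = dfr,
      start = list(b = ap[1], k = 1, chi = max(0.1, -ap[2])),
      lower = c(b = -Inf, k = 0, chi = 0))), silent = TRUE)
    if (!inherits(kf, "try-error")) {
      p <- coef(kf)
      apVals <- p[["b"]] - log10(p[["k"]] + f^p[["chi"]])
      model <- list(offset = p[["b"]], exponent = p[["chi"]], knee = p[["k"]])
    } else knee <- FALSE
  }
  if (!knee) {
    fit <- stats::lm.fit(cbind(1, logF), yAp)
    model <- list(offset = fit$coefficients[[1]],
                  exponent = max(0, -fit$coefficients[[2]]), knee = NULL)
    apVals <- model$offset - model$exponent * logF
  }
  fitted <- apVals + peakModel
  rsq <- if (sd(y) > 0) cor(y, fitted)^2 else 1
  pk <- if (length(peaks))
    as.data.frame(do.call(rbind, peaks)) else
      data.frame(center = numeric(0), height = numeric(0),
                 width = numeric(0))
  names(pk) <- c("center", "height", "width")
  structure(list(offset = model$offset, exponent = model$exponent,
                 knee = model$knee, peaks = pk, fitRange = fitRange,
                 freqs = f, aperiodic = apVals, fitted = fitted,
                 rSquared = rsq),
            class = "SpectralModel")
}

#' @export
print.SpectralModel <- function(x, ...) {
  cat(sprintf("SpectralModel: offset %.3g, exponent %.3g%s, %d peak(s), R2 = %.3f\n",
              x$offset, x$exponent,
              if (!is.null(x$knee)) sprintf(", knee %.3g", x$knee) else "",
              nrow(x$peaks), x$rSquared))
  if (nrow(x$peaks)) print(round(x$peaks, 3))
  invisible(x)
}

#' Flatten a power spectrum
#'
#' Subtracts the fitted aperiodic component from the observed log10 power
#' over the model's fit range, leaving only the oscillatory residual.
#'
#' @param psd the `Psd` the model was fit on.
#' @param model a `SpectralModel` from [fitSpectralModel()].
#' @return list of class `FlatPsd`: `freqs`, `flattened` (log10-power
#'   units).
#' @export
flattenPsd <- function(psd, model) {
  sel <- psd$freqs >= model$fitRange[1] & psd$freqs <= model$fitRange[2]
  f <- psd$freqs[sel]
  if (length(f) != length(model$freqs) || max(abs(f - model$freqs)) > 1e-9)
    scStop("frequency grid mismatch between PSD and model")
  structure(list(freqs = f, flattened = psd$logPower[sel] / 10 - model$aperiodic),
            class = "FlatPsd")
}

#' Compare flattened spectra between conditions, per frequency
#'
#' Two-sided Wilcoxon signed-rank test (exact for n <= 25) across
#' participants at each frequency of the paired flattened spectra, with
#' Benjamini-Hochberg FDR correction across frequencies.
#'
#' @param flatA,flatB participants x frequencies matrices (or lists of
#'   `FlatPsd` in matching participant order).
#' @param freqs frequency grid (taken from the inputs when lists).
#' @param q FDR level (default 0.05).
#' @return data.frame: `freq`, `statistic` (signed-rank W+), `p`, `pAdj`,
#'   `significant`.
#' @export
compareConditionsPerFreq <- function(flatA, flatB, freqs = NULL, q = 0.05) {
  toMat <- function(x) {
    if (is.list(x) && !is.data.frame(x) && inherits(x[[1]], "FlatPsd"))
      do.call(rbind, lapply(x, `[[`, "flattened"))
    else as.matrix(x)
  }
  if (is.null(freqs) && is.list(flatA) && inherits(flatA[[1]], "FlatPsd"))
    freqs <- flatA[[1]]$freqs
  A <- toMat(flatA); B <- toMat(flatB)
  if (!all(dim(A) == dim(B)))
    scStop("condition matrices must have identical dimensions")
  if (nrow(A) < 5) scStop("need at least 5 participant pairs")
  if (is.null(freqs)) freqs <- seq_len(ncol(A))
  res <- t(vapply(seq_len(ncol(A)), function(j) {
    wt <- wilcoxonSignedRank(A[, j] - B[, j])
    c(wt$statistic, wt$p)
  }, numeric(2)))
  pAdj <- p.adjust(res[, 2], method = "BH")
  data.frame(freq = freqs, statistic = res[, 1], p = res[, 2],
             pAdj = pAdj, significant = pAdj <= q)
}
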