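sinusoidRecording <- function(freqs, amps, fs = 250, dur = 30, offset = 0) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- offset + rowSums(vapply(seq_along(freqs), function(i)
    amps[i] * sin(2 * pi * freqs[i] * t), numeric(length(t))))
  makeTestRecording(matrix(x, 1), fs)
}

## amplitude of a sinusoid estimated away from the edges
midAmplitude <- function(rec, skip = 2) {
  x <- recData(rec)[1, ]
  n <- length(x); fs <- sampleRate(rec)
  sqrt(2 * mean(x[(skip * fs):(n - skip * fs)]^2))
}

test_that("high-pass removes DC and slow drift but spares the passband", {
  recDc <- sinusoidRecording(10, 1, offset = 50)
  out <- highpass(recDc, 1.0)
  expect_lt(abs(mean(recData(out))), 1e-6 * 50)
  expect_lt(abs(midAmplitude(out) - 1), 0.01)          # 10 Hz: < 1% loss
  recSlow <- sinusoidRecording(0.1, 1)
  outS <- highpass(recSlow, 1.0)
  expect_lt(midAmplitude(outS), 10^(-20 / 20))         # > 20 dB down
  expect_error(highpass(recDc, 200), "Nyquist")
})

test_that("line-noise regression notches the line frequency only", {
  withr::with_seed(5, {
    fs <- 250; dur <- 40
    noise <- rnorm(fs * dur)
    line <- 4 * sin(2 * pi * 60 * seq(0, dur - 1 / fs, by = 1 / fs))
    rec <- makeTestRecording(matrix(noise + line, 1), fs)
    out <- removeLineNoise(rec, 60)
    p0 <- welchPsd(recData(rec)[1, ], fs, 500)
    p1 <- welchPsd(recData(out)[1, ], fs, 500)
    at <- function(p, f) p$logPower[which.min(abs(p$freqs - f))]
    expect_gt(at(p0, 60) - at(p1, 60), 20)             # >= 20 dB at 60 Hz
    nb <- p0$freqs >= 55 & p0$freqs <= 65 &
      !(p0$freqs > 59 & p0$freqs < 61)
    expect_lt(max(abs(p0$logPower[nb] - p1$logPower[nb])), 1)
    ## no line component: output ~ input (RMS change < 1%, residual small)
    recN <- makeTestRecording(matrix(noise, 1), fs)
    outN <- removeLineNoise(recN, 60)
    expect_lt(abs(sqrt(mean(recData(outN)^2)) /
                    sqrt(mean(recData(recN)^2)) - 1), 0.01)
    expect_lt(sqrt(mean((recData(outN) - recData(recN))^2)) /
                sqrt(mean(recData(recN)^2)), 0.05)
    ## parameterised frequency: acts at 50 Hz instead
    line50 <- 4 * sin(2 * pi * 50 * seq(0, dur - 1 / fs, by = 1 / fs))
    rec50 <- makeTestRecording(matrix(noise + line50, 1), fs)
    out50 <- removeLineNoise(rec50, 50)
    p2 <- welchPsd(recData(out50)[1, ], fs, 500)
    expect_gt(at(welchPsd(recData(rec50)[1, ], fs, 500), 50) - at(p2, 50), 20)
  })
})

test_that("resampling preserves passband amplitude and the time base", {
  rec <- sinusoidRecording(10, 1, fs = 500, dur = 20)
  rec@annotations <- data.frame(onset = 1.0, duration = 0,
                                label = "ball_appear")
  out <- resampleRecording(rec, 250)
  expect_equal(ncol(recData(out)), ncol(recData(rec)) / 2)
  expect_lt(abs(midAmplitude(out) - 1), 0.01)
  expect_equal(out@annotations$onset, 1.0)   # seconds: unchanged
  expect_equal(sampleRate(out), 250)
  expect_error(resampleRecording(out, 500), "upsampling")
})

test_that("channel rejection flags amplitude outliers per layer", {
  withr::with_seed(8, {
    X <- matrix(rnorm(32 * 2000), 32)
    X[17, ] <- X[17, ] * sqrt(10)          # one channel at 10x variance
    rec <- makeTestRecording(X, 250)
    rb <- rejectBadChannels(rec)
    expect_identical(rb$rejected, 17L)
    ## identical channels: none rejected
    X2 <- matrix(rep(rnorm(2000), each = 16), 16, byrow = FALSE)
    expect_length(rejectBadChannels(makeTestRecording(X2, 250))$rejected, 0)
    ## a flat channel deviates below the median and is rejected
    X3 <- matrix(rnorm(32 * 2000), 32); X3[5, ] <- 0
    expect_identical(rejectBadChannels(makeTestRecording(X3, 250))$rejected,
                     5L)
  })
})

test_that("average reference zeroes the layer mean and interpolation
           reconstructs a smooth field", {
  withr::with_seed(9, {
    nc <- 32
    pos <- sphericalMontage(nc)
    ## smooth dipolar field: potential from two interior poles, plus a
    ## small shared time course
    dip <- function(p, src) 1 / sqrt(rowSums(sweep(p, 2, src)^2))
    field <- dip(pos, c(0.2, 0.1, 0.4)) - dip(pos, c(-0.2, -0.1, 0.4))
    tc <- sin(2 * pi * 5 * seq(0, 4, by = 1 / 250))
    X <- field %*% t(tc)
    rec <- makeTestRecording(X, 250)
    out <- rereferenceInterpolate(rec, integer(0))
    expect_lt(max(abs(colSums(recData(out)))), 1e-8)
    ## leave-one-out: every channel reconstructed within 10% RMS of the
    ## field scale (normalising per channel would divide by ~0 where the
    ## dipolar field crosses zero)
    relErr <- vapply(seq_len(nc), function(i) {
      o <- rereferenceInterpolate(rec, i)
      truthRef <- sweep(X, 2, colMeans(X[-i, , drop = FALSE]))
      sqrt(mean((recData(o)[i, ] - truthRef[i, ])^2) / mean(truthRef^2))
    }, numeric(1))
    expect_lt(max(relErr), 0.10)
    ## with no rejected channels, data change only by the reference
    shifted <- sweep(X, 2, colMeans(X))
    expect_equal(recData(out), shifted, tolerance = 1e-10)
  })
})

test_that("CCA cleaning removes shared artifact subspaces and nothing else", {
  fx <- makeDualLayerFixture(nc = 16, dur = 30, artifactAmp = 5, seed = 3)
  out <- ccaClean(fx$rec, "noise", 2, 0.85)
  res <- recData(out)[1:16, ]
  supp <- 1 - mean(rowMeans((res - fx$brain)^2)) / mean(rowMeans(fx$artifact^2))
  expect_gt(supp, 0.90)
  ## reference channels are untouched
  expect_identical(recData(out)[17:32, ], recData(fx$rec)[17:32, ])
  ## artifact-free channels are distorted < 5%
  outF <- ccaClean(fx$recBrainOnly, "noise", 2, 0.85)
  dist <- sqrt(rowMeans((recData(outF)[1:16, ] - fx$brain)^2)) /
    sqrt(rowMeans(fx$brain^2))
  expect_lt(max(dist), 0.05)
  ## r2 threshold 1.0: nothing can exceed it, output == input
  outI <- ccaClean(fx$rec, "noise", 2, 1.0)
  expect_equal(recData(outI), recData(fx$rec), tolerance = 1e-9)
})

test_that("a statistically independent reference leaves the scalp alone", {
  withr::with_seed(12, {
    nc <- 12; fs <- 250; n <- 30 * fs
    brain <- matrix(rnorm(nc * n), nc)
    ref <- matrix(rnorm(nc * n), nc)
    rec <- makeTestRecording(rbind(brain, ref), fs,
                             roles = rep(c("scalp", "noise"), each = nc))
    out <- ccaClean(rec, "noise", 2, 0.85)
    change <- sqrt(rowMeans((recData(out)[1:nc, ] - brain)^2)) /
      sqrt(rowMeans(brain^2))
    expect_lt(max(change), 0.05)
  })
})

test_that("window rejection marks high-amplitude stretches", {
  withr::with_seed(14, {
    fs <- 250; n <- 60 * fs; nc <- 10
    X <- matrix(rnorm(nc * n), nc)
    rec <- makeTestRecording(X, fs)
    rw <- rejectWindows(rec)
    expect_lt(rw$fractionRejected, 0.01)
    ## a 2 s burst of 100x amplitude on 40% of the channels is masked
    Xb <- X
    burst <- (20 * fs):(22 * fs)
    Xb[1:4, burst] <- 100 * Xb[1:4, burst]
    rwB <- rejectWindows(makeTestRecording(Xb, fs))
    expect_true(all(rwB$mask[burst]))
    expect_lt(mean(rwB$mask), 0.10)
    ## an infinite threshold masks nothing
    rwI <- rejectWindows(rec, sdThresh = Inf)
    expect_false(any(rwI$mask))
  })
})

test_that("cleaning improves correlation with the artifact-free truth", {
  ## end-to-end on generator fixtures: denoised scalp beats raw in every
  ## seeded run
  for (seed in c(41, 42, 43)) {
    cfg <- simConfig(nParticipants = 1, sessionLength = 60, nScalp = 8,
                     nNoise = 8, nMuscle = 2, fsEeg = 250, fsImu = 500,
                     rngSeed = seed)
    st <- generateStudy(cfg)
    rec <- st$recordings[["P01_machine"]]
    pp <- preprocessRecording(rec, analysisParams())
    ## truth through the same linear filter chain
    recT <- rec
    recT@data[1:8, ] <- trueCleanScalp(st$truth, "P01", "machine")
    recT <- resampleRecording(highpass(recT), 250)
    good <- setdiff(1:8, pp$rejectedChannels)
    truthRef <- sweep(recData(recT)[1:8, ], 2,
                      colMeans(recData(recT)[good, , drop = FALSE]))
    rawR <- resampleRecording(highpass(rec), 250)
    rawRef <- sweep(recData(rawR)[1:8, ], 2,
                    colMeans(recData(rawR)[good, , drop = FALSE]))
    corOf <- function(M) mean(vapply(seq_len(8), function(i)
      cor(M[i, ], truthRef[i, ]), numeric(1)))
    expect_gt(corOf(recData(pp$recording)[1:8, ]), corOf(rawRef))
  }
})
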