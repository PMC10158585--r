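test_that("epoching cuts half-open windows and drops invalid trials", {
  fs <- 250
  x <- rnorm(60 * fs)
  cyc <- data.frame(t_appear = c(0.5, 10, 20, 30),
                    t_hit = c(0.5, 10, 20, 30) + 0.64,
                    t_next = c(0.5, 10, 20, 30) + 2)
  ep <- makeEpochs(x, fs, cyc)
  ## the 0.5 s event lacks a full 1 s pre-window: dropped; 875 samples
  expect_equal(nrow(recData(ep)), 3)
  expect_equal(ncol(recData(ep)), 875)
  expect_equal(range(epochTimes(ep)), c(-1.0, 2.5 - 1 / fs))
  ## a masked-bad stretch drops the overlapping trial
  mask <- rep(FALSE, length(x)); mask[round(10.5 * fs)] <- TRUE
  ep2 <- makeEpochs(x, fs, cyc, mask = mask)
  expect_equal(nrow(recData(ep2)), 2)
  expect_error(makeEpochs(x, fs, cyc[1, , drop = FALSE]), "no valid epochs")
})

test_that("amplitude-based epoch rejection removes the top fraction with a
           deterministic tie-break", {
  times <- seq(0, 1 - 1 / 100, by = 1 / 100)
  ep <- makeTestEpochs(100, times, 100, function(i) rep(i, length(times)))
  out <- rejectEpochsByMax(ep, 0.10)
  expect_equal(nrow(recData(out)), 90)
  expect_equal(max(recData(out)), 90)   # the 10 largest trials removed
  ## all-equal maxima: later trial indices are removed first
  epEq <- makeTestEpochs(10, times, 100, function(i) rep(1, length(times)))
  outEq <- rejectEpochsByMax(epEq, 0.10)
  expect_equal(nrow(recData(outEq)), 9)
  ## frac = 0: unchanged
  expect_equal(nrow(recData(rejectEpochsByMax(ep, 0))), 100)
})

test_that("epoch subsampling is seeded and falls back gracefully", {
  times <- seq(0, 0.2 - 1 / 100, by = 1 / 100)
  ep <- makeTestEpochs(472, times, 100, function(i) rnorm(length(times)))
  s1 <- subsampleEpochs(ep, 70, seed = 4)
  s2 <- subsampleEpochs(ep, 70, seed = 4)
  expect_equal(nrow(recData(s1)), 70)
  expect_identical(recData(s1), recData(s2))
  s3 <- subsampleEpochs(ep, 70, seed = 5)
  expect_false(identical(recData(s1), recData(s3)))
  epSmall <- makeTestEpochs(50, times, 100, function(i) rnorm(length(times)))
  expect_warning(sAll <- subsampleEpochs(epSmall, 70, seed = 1), "keeping all")
  expect_equal(nrow(recData(sAll)), 50)
})

test_that("the Morlet transform is calibrated in amplitude, frequency and
           phase", {
  fs <- 250
  times <- seq(-1, 2.5 - 1 / fs, by = 1 / fs)
  freqs <- defaultFreqGrid(c(3, 50), 20)
  ## cycle schedule is linear between the grid extremes
  cyc <- swingcycle:::cycleSchedule(c(3, (3 + 50) / 2, 50), c(3, 64))
  expect_equal(cyc[2], (3 + 64) / 2)
  ## zero in, zero out
  ep0 <- makeTestEpochs(2, times, fs, function(i) numeric(length(times)))
  expect_true(all(abs(morletTransform(ep0, freqs)@coef) == 0))
  ## unit-amplitude 10 Hz sinusoid: power peaks on the 10 Hz row with
  ## magnitude ~1, and phase advances at 2 pi f rad/s
  ep <- makeTestEpochs(1, times, fs, function(i) sin(2 * pi * 10 * times))
  tf <- morletTransform(ep, freqs)
  mid <- which(abs(times) < 0.8)[-1]
  rowPow <- rowMeans(abs(tf@coef[1, , mid])^2)
  expect_equal(which.max(rowPow), which.min(abs(freqs - 10)))
  iF <- which.min(abs(freqs - 10))
  expect_lt(abs(sqrt(max(rowPow)) - 1), 0.05)
  ph <- Arg(tf@coef[1, iF, mid])
  dph <- diff(ph); dph[dph < -pi] <- dph[dph < -pi] + 2 * pi
  rate <- mean(dph) * fs
  expect_lt(abs(rate - 2 * pi * 10) / (2 * pi * 10), 0.01)
  ## epoch too short for the requested low frequency
  timesShort <- seq(0, 0.5 - 1 / fs, by = 1 / fs)
  epS <- makeTestEpochs(1, timesShort, fs, function(i) rnorm(length(timesShort)))
  expect_error(morletTransform(epS, c(3, 20, 40)), "epoch too short")
})

test_that("time warping is anchored, exact at the template, and matches a
           linear-interpolation oracle", {
  fs <- 50
  times <- seq(-1, 2.5 - 1 / fs, by = 1 / fs)
  freqs <- c(5, 10)
  withr::with_seed(8, {
    coef <- array(complex(real = rnorm(2 * 2 * length(times)),
                          imaginary = rnorm(2 * 2 * length(times))),
                  c(2, 2, length(times)))
    template <- c(hit = 0.64, next_appear = 2.0)
    ## trials already at the template: identity
    tf <- makeTestTf(coef, freqs, times, t_hit = 0.64, t_next = 2.0)
    w <- timeWarp(tf, template)
    expect_equal(abs(w@coef)^2, abs(tf@coef)^2, tolerance = 1e-12)
    ## a power burst at 500 ms relocates to the 640 ms template anchor
    pow <- array(1, c(1, 1, length(times)))
    pow[1, 1, which.min(abs(times - 0.50))] <- 100
    tfB <- makeTestTf(array(complex(real = sqrt(pow)), dim(pow)), 5,
                      times, t_hit = 0.50, t_next = 2.0)
    wB <- timeWarp(tfB, template)
    expect_equal(times[which.max(abs(wB@coef[1, 1, ])^2)], 0.64,
                 tolerance = 1 / fs)
    ## random smooth trial vs an independent interpolation oracle
    tfR <- makeTestTf(coef, freqs, times, t_hit = 0.5, t_next = 1.8)
    wR <- timeWarp(tfR, template)
    anchors <- c(times[1], 0, 0.5, 1.8, times[length(times)])
    tmplA <- c(times[1], 0, 0.64, 2.0, times[length(times)])
    srcT <- approx(tmplA, anchors, xout = times)$y
    for (i in 1:2) {
      oracle <- approx(times, abs(coef[1, i, ])^2, xout = srcT, rule = 2)$y
      expect_lt(max(abs(abs(wR@coef[1, i, ])^2 - oracle)), 1e-10)
    }
    ## non-monotone anchors: trial dropped with a message
    tfBad <- makeTestTf(coef, freqs, times, t_hit = 2.2, t_next = 1.8)
    expect_error(suppressMessages(timeWarp(tfBad, template)), "monotone")
  })
})

test_that("ERSP is a dB ratio against the pooled swing-cycle baseline", {
  fs <- 100
  times <- seq(-1, 2.5 - 1 / fs, by = 1 / fs)
  freqs <- c(5, 10)
  nT <- 30
  ## stationary unit-power trials: ERSP ~ 0 dB
  mk <- function(gainWindow = NULL) {
    coef <- array(complex(real = rnorm(nT * 2 * length(times), sd = sqrt(0.5)),
                          imaginary = rnorm(nT * 2 * length(times), sd = sqrt(0.5))),
                  c(nT, 2, length(times)))
    if (!is.null(gainWindow))
      coef[, 2, times >= gainWindow[1] & times <= gainWindow[2]] <-
        coef[, 2, times >= gainWindow[1] & times <= gainWindow[2]] *
          gainWindow[3]
    makeTestTf(coef, freqs, times)
  }
  withr::with_seed(3, {
    e0 <- ersp(mk())
    expect_lt(max(abs(e0)), 3.0)   # single-cell noise at 30 trials
    expect_lt(abs(mean(e0)), 0.2)
    ## amplitude x2 inside a window: +6.02 dB there (against a baseline
    ## diluted by the window itself, corrected below)
    tf2 <- mk(c(0.0, 0.5, 2))
    base <- pooledBaseline(tf2)
    inWin <- times >= 0.05 & times <= 0.45
    e2 <- ersp(tf2, base)
    winFrac <- mean(times >= 0 & times <= 0.5)
    dilution <- 10 * log10(1 + 3 * winFrac)   # power x4 in winFrac of time
    expect_lt(abs(mean(e2[2, inWin]) - (10 * log10(4) - dilution)), 0.5)
    ## amplitude x0.5: -6.02 dB with its own (smaller) dilution
    tfH <- mk(c(0.0, 0.5, 0.5))
    eH <- ersp(tfH, pooledBaseline(tfH))
    dilH <- 10 * log10(1 - 0.75 * winFrac)
    expect_lt(abs(mean(eH[2, inWin]) - (10 * log10(0.25) - dilH)), 0.5)
  })
})

test_that("ITPC measures phase locking on the unit circle", {
  fs <- 100
  times <- seq(0, 1 - 1 / fs, by = 1 / fs)
  base <- matrix(complex(real = cos(2 * pi * 5 * times),
                         imaginary = sin(2 * pi * 5 * times)), 1)
  ## identical trials: ITPC = 1 everywhere
  coef <- array(0i, c(20, 1, length(times)))
  for (tr in 1:20) coef[tr, 1, ] <- base
  expect_true(all(abs(itpc(makeTestTf(coef, 5, times)) - 1) < 1e-12))
  ## two trials in antiphase: ITPC = 0
  coef2 <- array(0i, c(2, 1, length(times)))
  coef2[1, 1, ] <- base; coef2[2, 1, ] <- -base
  expect_true(all(itpc(makeTestTf(coef2, 5, times)) < 1e-12))
  ## n independent uniform phases: E[ITPC] ~ sqrt(pi)/(2 sqrt(n))
  withr::with_seed(9, {
    n <- 100
    coefU <- array(exp(2i * pi * runif(n * 1 * length(times))),
                   c(n, 1, length(times)))
    vals <- itpc(makeTestTf(coefU, 5, times))
    expect_lt(abs(mean(vals) - sqrt(pi) / (2 * sqrt(n))), 0.015)
  })
})

test_that("the ERP is the participant-then-grand trial average", {
  fs <- 100
  times <- seq(0, 0.5 - 1 / fs, by = 1 / fs)
  wave <- sin(2 * pi * 4 * times)
  epSame <- makeTestEpochs(5, times, fs, function(i) wave)
  expect_equal(erp(epSame)$grand, wave)
  ## alternating-sign trials cancel
  epAlt <- makeTestEpochs(10, times, fs, function(i) (-1)^i * wave)
  expect_lt(max(abs(erp(epAlt)$grand)), 1e-12)
  ## residual noise shrinks as sigma/sqrt(n)
  withr::with_seed(5, {
    n <- 64
    epN <- makeTestEpochs(n, times, fs, function(i) wave + rnorm(length(times)))
    resid <- erp(epN)$grand - wave
    expect_lt(abs(sqrt(mean(resid^2)) / (1 / sqrt(n)) - 1), 0.35)
  })
})

test_that("event-related coherence is 1 for identical inputs and detects a
           planted shared driver", {
  fs <- 100
  times <- seq(-0.5, 1 - 1 / fs, by = 1 / fs)
  withr::with_seed(11, {
    nT <- 40
    mkNoise <- function() array(
      complex(real = rnorm(nT * 1 * length(times)),
              imaginary = rnorm(nT * 1 * length(times))),
      c(nT, 1, length(times)))
    a <- makeTestTf(mkNoise(), 6, times)
    expect_true(all(abs(eventRelatedCoherence(a, a) - 1) < 1e-12))
    b <- makeTestTf(mkNoise(), 6, times)
    cNull <- eventRelatedCoherence(a, b)
    expect_lt(max(cNull), 0.5)
    ## a common driver during [0, 0.5] s elevates coherence only there
    driver <- mkNoise()
    aD <- a@coef; bD <- b@coef
    win <- times >= 0 & times <= 0.5
    aD[, , win] <- aD[, , win] + 3 * driver[, , win]
    bD[, , win] <- bD[, , win] + 3 * driver[, , win]
    cDrv <- eventRelatedCoherence(makeTestTf(aD, 6, times),
                                  makeTestTf(bD, 6, times))
    expect_gt(mean(cDrv[1, win]), 0.8)
    expect_lt(mean(cDrv[1, !win]), 0.4)
    expect_error(eventRelatedCoherence(a, makeTestTf(mkNoise()[1:10, , ,
                                                               drop = FALSE],
                                                     6, times)),
                 "mismatch")
  })
})
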