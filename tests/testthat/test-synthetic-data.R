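test_that("invalid configurations are rejected with the field named", {
  expect_error(simConfig(nScalp = 8, nNoise = 6), "nNoise")
  expect_error(simConfig(sessionLength = 10, eventRate = 0.5),
               "sessionLength")
  expect_error(simConfig(eventRate = -1), "eventRate")
  expect_error(simConfig(erdDepth = c(alpha = 2, beta = 0)), "erdDepth")
})

test_that("identical configurations generate bit-identical studies", {
  cfg <- smallStudyConfig(seed = 7, nParticipants = 1, sessionLength = 40,
                          nScalp = 8)
  a <- generateStudy(cfg)
  b <- generateStudy(cfg)
  expect_identical(recData(a$recordings[[1]]), recData(b$recordings[[1]]))
  expect_identical(a$imu[[1]]@acc, b$imu[[1]]@acc)
  expect_identical(a$truth$events, b$truth$events)
})

test_that("the event schedule matches the configured feed rate", {
  cfg <- simConfig(nParticipants = 1, sessionLength = 300, nScalp = 8,
                   nNoise = 8, nMuscle = 2, fsEeg = 250, fsImu = 500,
                   rngSeed = 5)
  ev <- swingcycle:::simulateEventSchedule(cfg, "machine", 11)
  nAppear <- sum(ev$type == "ball_appear")
  ## ~0.5 Hz over 300 s: close to 150 feeds
  expect_gt(nAppear, 140)
  expect_lt(nAppear, 155)
  ## conservation: every generated event appears in the table
  expect_equal(sum(ev$type == "participant_hit"), nAppear)
  ## machine jitter is small: appear times near the 2 s grid
  ap <- ev$onset[ev$type == "ball_appear"]
  expect_lt(max(abs(ap - round((ap - 3) / 2) * 2 - 3)), 0.05)
})

test_that("source backgrounds follow the configured power law", {
  prof <- list(list(bgSd = 5,
                    bands = data.frame(band = character(0),
                                       center = numeric(0), bw = numeric(0),
                                       sd = numeric(0), depth = numeric(0)),
                    erpGain = 1))
  for (chi in c(0.5, 1.5)) {
    src <- generateSourceDynamics(prof, eventTable(), fs = 250,
                                  duration = 600, exponent = chi, seed = 21)
    psd <- welchPsd(src[1, ], 250, 500)
    m <- fitSpectralModel(psd, fitRange = c(3, 40))
    expect_lt(abs(m$exponent - chi), 0.1)
  }
})

test_that("events outside the session are rejected", {
  prof <- defaultSourceProfiles(smallStudyConfig())
  bad <- eventTable(onset = c(5, 59.9), type = "ball_appear")
  expect_error(generateSourceDynamics(prof, bad, 250, 60, seed = 1),
               "inside the session")
})

test_that("band suppression depth is expressed in the generated envelope", {
  ## one source, alpha fully described: 50% amplitude suppression between
  ## appear and hit should halve the alpha-band envelope there
  prof <- list(list(bgSd = 0.5,
                    bands = data.frame(band = "alpha", center = 10, bw = 2,
                                       sd = 3, depth = 0.5),
                    erpGain = 0))
  ap <- seq(3, 115, by = 2)
  ev <- eventTable(onset = c(ap, ap + 0.64),
                   type = rep(c("ball_appear", "participant_hit"),
                              each = length(ap)))
  src <- generateSourceDynamics(prof, ev, fs = 250, duration = 120,
                                exponent = 1.5, seed = 3)
  x <- src[1, ]
  ## alpha envelope via narrowband power in ERD vs baseline windows
  inErd <- rep(FALSE, length(x)); inBase <- rep(FALSE, length(x))
  for (a in ap) {
    inErd[round((a + 0.15) * 250):round((a + 0.55) * 250)] <- TRUE
    inBase[round((a + 1.3) * 250):round((a + 1.9) * 250)] <- TRUE
  }
  bp <- function(x) {
    X <- fft(x); f <- seq(0, 250, length.out = length(x) + 1)[seq_along(x)]
    X[!(f > 8 & f < 12) & !(f > 238 & f < 242)] <- 0
    Re(fft(X, inverse = TRUE)) / length(x)
  }
  xa <- bp(x)
  ratio <- sqrt(mean(xa[inErd]^2) / mean(xa[inBase]^2))
  ## 0.5 amplitude vs ~1.125 rebound-free baseline; allow generous slack
  expect_lt(ratio, 0.65)
  expect_gt(ratio, 0.35)
})

test_that("the noise layer shares artifacts but carries no brain signal", {
  cfg <- simConfig(nParticipants = 1, sessionLength = 60, nScalp = 8,
                   nNoise = 8, nMuscle = 2, fsEeg = 250, fsImu = 500,
                   rngSeed = 13, artifactGain = 1)
  st <- generateStudy(cfg)
  rec <- st$recordings[["P01_machine"]]
  brain <- trueCleanScalp(st$truth, "P01", "machine")
  noise <- recData(rec)[channelsWithRole(rec, "noise"), ]
  scalp <- recData(rec)[channelsWithRole(rec, "scalp"), ]
  ## noise channels nearly uncorrelated with the brain projection,
  ## strongly correlated with their scalp partner (shared artifact)
  brainCor <- mean(abs(sapply(1:8, function(i) cor(noise[i, ], brain[i, ]))))
  pairCor <- mean(sapply(1:8, function(i) cor(noise[i, ], scalp[i, ])))
  expect_lt(brainCor, 0.1)
  expect_gt(pairCor, 0.5)
})

test_that("windowed scalp/noise canonical correlation reflects artifact gain", {
  mkR2 <- function(gain, seed) {
    cfg <- simConfig(nParticipants = 1, sessionLength = 30, nScalp = 8,
                     nNoise = 8, nMuscle = 2, fsEeg = 250, fsImu = 500,
                     rngSeed = seed, artifactGain = gain)
    st <- generateStudy(cfg)
    rec <- st$recordings[["P01_machine"]]
    X <- t(recData(rec)[channelsWithRole(rec, "scalp"), ])
    Y <- t(recData(rec)[channelsWithRole(rec, "noise"), ])
    r2 <- sapply(seq(1, nrow(X) - 500, by = 500), function(s) {
      idx <- s:(s + 499)
      ## independent oracle: stats::cancor on the centred window
      cc <- stats::cancor(scale(X[idx, ], scale = FALSE),
                          scale(Y[idx, ], scale = FALSE))
      max(cc$cor^2)
    })
    r2
  }
  expect_gt(min(mkR2(1, 31)), 0.99)      # shared artifacts dominate
  expect_lt(max(mkR2(0, 32)), 0.85)      # nothing shared above threshold
})

test_that("an all-zero configuration yields an all-zero recording", {
  cfg <- simConfig(nParticipants = 1, sessionLength = 30, nScalp = 8,
                   nNoise = 8, nMuscle = 2, fsEeg = 250, fsImu = 500,
                   rngSeed = 1, artifactGain = 0, sensorNoiseSd = 0)
  fwd <- swingcycle:::makeForwardModel(cfg, syntheticSourceLayout(), 5)
  src <- matrix(0, nrow(syntheticSourceLayout()), 30 * 250)
  rec <- mixToChannels(src, fwd, cfg, seed = 6, muscleAmplitude = 0)
  expect_true(all(recData(rec) == 0))
  ## rank-deficient forward model is refused
  fwd2 <- fwd
  fwd2$mixing[, 2] <- fwd2$mixing[, 1]
  expect_error(mixToChannels(src, fwd2, cfg, seed = 6), "rank deficient")
})
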