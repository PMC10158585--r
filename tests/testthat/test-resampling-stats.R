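test_that("the signed-rank test matches exact enumeration for n <= 10", {
  expect_equal(wilcoxonSignedRank(1:5)$statistic, 15)
  expect_equal(wilcoxonSignedRank(1:5)$p, 0.0625)
  withr::with_seed(21, {
    for (rep in 1:12) {
      n <- sample(5:10, 1)
      d <- round(rnorm(n), 2)
      d <- d[d != 0]
      if (length(d) < 2) next
      got <- wilcoxonSignedRank(d)
      oracle <- bruteSignedRank(d)
      expect_equal(got$statistic, oracle$W)
      expect_equal(got$p, oracle$p, tolerance = 1e-12)
    }
  })
  ## cross-check against the base implementation on tie-free data
  withr::with_seed(22, {
    d <- rnorm(12)
    got <- wilcoxonSignedRank(d)
    ref <- wilcox.test(d, exact = TRUE)
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  })
  ## symmetric differences: no evidence
  expect_equal(wilcoxonSignedRank(c(-1, 1, -2, 2, -3, 3))$p, 1)
  expect_warning(z <- wilcoxonSignedRank(c(0, 0, 0)), "zero")
  expect_equal(z$p, 1)
  ## large-n normal approximation stays close to the exact route
  withr::with_seed(23, {
    d <- rnorm(24) + 0.5
    pExact <- wilcoxonSignedRank(d, exactMax = 25)$p
    pNorm <- wilcoxonSignedRank(d, exactMax = 10)$p
    expect_lt(abs(pExact - pNorm), 0.02)
  })
})

test_that("BH step-up matches the hand oracle", {
  expect_true(all(bhFdr(c(0.01, 0.02, 0.03, 0.04, 0.05), 0.05)))
  expect_false(any(bhFdr(rep(1, 6), 0.05)))
  expect_equal(sum(bhFdr(c(0.001, 0.9, 0.9, 0.9), 0.05)), 1)
  withr::with_seed(31, {
    for (rep in 1:20) {
      p <- runif(sample(3:40, 1))^sample(1:3, 1)
      q <- sample(c(0.01, 0.05, 0.1), 1)
      expect_identical(bhFdr(p, q), bruteBh(p, q))
    }
  })
  expect_length(bhFdr(numeric(0)), 0)
  ## shape is preserved
  pm <- matrix(runif(12), 3)
  expect_equal(dim(bhFdr(pm)), dim(pm))
})

test_that("bootstrap masks are calibrated on stationary nulls and detect
           planted effects", {
  withr::with_seed(41, {
    nU <- 12; nF <- 8; nT <- 40
    maps <- lapply(seq_len(nU), function(u) matrix(rnorm(nF * nT), nF))
    ## constant maps: the null equals the observation, nothing significant
    cm <- lapply(seq_len(nU), function(u) matrix(u, nF, nT))
    mk0 <- bootstrapMask(cm, nIter = 300, seed = 2)
    expect_false(any(mk0$mask))
    ## stationary null: pre-correction hit rate ~ alpha, BH kills the rest
    mkN <- bootstrapMask(maps, nIter = 400, seed = 3, correction = "none")
    alphaHat <- mean(mkN$mask)
    se <- sqrt(0.05 * 0.95 / (nF * nT))
    expect_lt(abs(alphaHat - 0.05), 4 * se + 0.01)
    mkB <- bootstrapMask(maps, nIter = 400, seed = 3)
    expect_lt(mean(mkB$mask), 0.01)
    ## planted +3 dB patch present in every unit: sensitivity >= 90%
    patchF <- 2:4; patchT <- 10:20
    mapsP <- lapply(maps, function(m) { m[patchF, patchT] <- m[patchF, patchT] + 3; m })
    mkP <- bootstrapMask(mapsP, nIter = 400, seed = 4)
    expect_gt(mean(mkP$mask[patchF, patchT]), 0.90)
    ## the mask is reported alongside the untouched observed statistic
    expect_equal(mkP$observed,
                 Reduce(`+`, mapsP) / length(mapsP), tolerance = 1e-12)
    expect_equal(mkP$masked[!mkP$mask], rep(0, sum(!mkP$mask)))
  })
  expect_error(bootstrapMask(list(matrix(0, 2, 2)), nIter = 50), "nIter")
})

test_that("cluster permutation controls family-wise error and finds planted
           patches", {
  withr::with_seed(51, {
    nP <- 16; nF <- 10; nT <- 25
    mk <- function(shift = 0, patch = NULL) lapply(seq_len(nP), function(u) {
      m <- matrix(rnorm(nF * nT), nF)
      if (!is.null(patch)) m[patch$f, patch$t] <- m[patch$f, patch$t] + shift
      m
    })
    ## identical conditions: no significant cluster
    A <- mk(); B <- lapply(A, function(m) m + matrix(rnorm(nF * nT), nF))
    pr <- clusterPermutation(A, B, nPerm = 300, seed = 5)
    expect_false(any(pr$clusters$p <= 0.05))
    ## symmetry: flipping every pair negates the observed t map
    D <- lapply(seq_len(nP), function(u) A[[u]] - B[[u]])
    prSwap <- clusterPermutation(B, A, nPerm = 50, seed = 5)
    expect_equal(prSwap$tMap, -pr$tMap, tolerance = 1e-10)
    ## planted difference with Cohen's d = 1 on the paired differences:
    ## cluster covering >= 80% of the patch
    patch <- list(f = 3:6, t = 8:18)
    B2 <- mk()
    A2 <- lapply(B2, function(m) {
      d <- matrix(rnorm(nF * nT), nF)
      d[patch$f, patch$t] <- d[patch$f, patch$t] + 1
      m + d
    })
    pr2 <- clusterPermutation(A2, B2, nPerm = 300, seed = 6)
    sig <- pr2$clusters$p <= 0.05
    expect_true(any(sig))
    inPatch <- pr2$mask[patch$f, patch$t]
    expect_gt(mean(inPatch), 0.80)
    ## p-values respect the (b+1)/(n+1) floor
    expect_gte(min(pr2$clusters$p), 1 / (300 + 1))
  })
  expect_error(clusterPermutation(list(matrix(0, 2, 2)),
                                  list(matrix(0, 2, 2))), "8 participant")
})

test_that("suprathreshold cluster labelling uses 4-connectivity", {
  m <- matrix(0, 5, 5)
  m[1, 1:2] <- 3; m[3, 3] <- 4; m[5, 5] <- -5   # two singletons + a pair
  lab <- swingcycle:::.labelClusters(m, 2)
  expect_equal(max(lab$labels), 3)
  expect_equal(sort(lab$mass), c(4, 5, 6))
  ## diagonal neighbours are NOT connected
  d <- matrix(0, 3, 3); d[1, 1] <- 3; d[2, 2] <- 3
  expect_equal(max(swingcycle:::.labelClusters(d, 2)$labels), 2)
  expect_equal(swingcycle:::.maxClusterMass(m, 2), 6)
})
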