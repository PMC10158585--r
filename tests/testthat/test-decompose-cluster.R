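test_that("PCA reduction removes exactly the rank lost to interpolation", {
  withr::with_seed(3, {
    ## rank-5 data in 12 channels reconstruct exactly from 5 components
    B <- matrix(rnorm(12 * 5), 12)
    S <- matrix(rnorm(5 * 3000), 5)
    X <- B %*% S
    red <- pcaReduce(X, 12 - 5)
    expect_equal(red$k, 5)
    recon <- red$basis %*% red$reduced + red$center
    expect_lt(max(abs(recon - X)), 1e-8)
    ## 0 interpolated channels: full-rank pass-through
    red0 <- pcaReduce(X + rnorm(length(X)), 0)
    expect_equal(red0$k, 12)
    expect_equal(crossprod(red0$basis), diag(12), tolerance = 1e-10)
    ## the rule is pure arithmetic on the channel count
    expect_equal(pcaReduce(matrix(rnorm(20 * 500), 20), 8)$k, 12)
    expect_error(pcaReduce(matrix(c(1, NA, 2, 3), 2), 0), "finite")
  })
})

test_that("ICA recovers independent non-Gaussian sources", {
  withr::with_seed(2, {
    S <- matrix(sign(rnorm(4 * 20000)) * rexp(4 * 20000), 4)
    A <- matrix(rnorm(8 * 4), 8)
    cs <- fitIca(A %*% S, nComp = 4, seed = 3)
    m <- abs(cor(t(componentActivations(cs)), t(S)))
    ## each true source matches one component after permutation
    expect_true(all(apply(m, 2, max) > 0.95))
    ## decomposition contract holds even for Gaussian sources
    G <- matrix(rnorm(6 * 8000), 6)
    csG <- fitIca(matrix(rnorm(36), 6) %*% G, seed = 5)
    expect_equal(csG@unmixing %*% csG@mixing, diag(6), tolerance = 1e-6)
    ## determinism
    cs2 <- fitIca(A %*% S, nComp = 4, seed = 3)
    expect_identical(cs@unmixing, cs2@unmixing)
    ## FastICA route on the same fixture
    csF <- fitIca(A %*% S, nComp = 4, method = "fastica", seed = 3)
    mF <- abs(cor(t(componentActivations(csF)), t(S)))
    expect_true(all(apply(mF, 2, max) > 0.95))
  })
})

test_that("unmixing weights apply to the full timeline and are linear", {
  withr::with_seed(6, {
    X <- matrix(rnorm(4 * 1000), 4)
    expect_equal(applyUnmixing(diag(4), X), X)
    W <- matrix(rnorm(16), 4)
    A <- matrix(rnorm(4 * 1000), 4); B <- matrix(rnorm(4 * 1000), 4)
    expect_equal(applyUnmixing(W, A + B),
                 applyUnmixing(W, A) + applyUnmixing(W, B))
    expect_error(applyUnmixing(W, matrix(0, 5, 10)), "mismatch")
    ## weights learned on a masked subset apply to the full length
    S <- matrix(sign(rnorm(4 * 20000)) * rexp(4 * 20000), 4)
    M <- matrix(rnorm(16), 4) %*% S
    cs <- fitIca(M[, 1:10000], seed = 1)
    act <- applyUnmixing(cs, M)
    expect_equal(ncol(act), 20000)
  })
})

makeLabelledSet <- function(participant, labels, ve = NULL) {
  k <- length(labels)
  ve <- ve %||% rev(seq_len(k)) / k
  new("ComponentSet", unmixing = diag(k), mixing = diag(k),
      activations = matrix(0, k, 10), fs = 250, participant = participant,
      positions = matrix(rnorm(3 * k), k, 3), labels = labels,
      varianceExplained = ve)
}

test_that("brain-component selection enforces the five-component rule", {
  csA <- makeLabelledSet("P01", rep("brain", 6))
  csB <- makeLabelledSet("P02", c(rep("brain", 4), rep("nonbrain", 4)))
  out <- selectBrainComponents(list(P01 = csA, P02 = csB))
  expect_named(out, "P01")                      # P02 has only 4: dropped
  expect_equal(sum(componentLabels(out$P01) == "brain"), 6)
  ## all-brain set passes unchanged
  expect_equal(length(out$P01@labels), 6)
  ## mixed labels: the retained set is exactly the brain subset
  csC <- makeLabelledSet("P03", c("brain", "nonbrain", "brain", "brain",
                                  "brain", "brain", "unknown"))
  outC <- selectBrainComponents(list(P03 = csC))
  expect_equal(nrow(componentPositions(outC$P03)), 5)
  expect_error(selectBrainComponents(list(P02 = csB)), "excluded")
})

test_that("k-means clustering recovers separated blobs and applies the
           retention and outlier rules", {
  withr::with_seed(10, {
    centers <- rbind(c(-50, 0, 0), c(50, 0, 0), c(0, 50, 0))
    pts <- do.call(rbind, lapply(1:3, function(i)
      sweep(matrix(rnorm(3 * 30, sd = 2), 30), 2, -centers[i, ])))
    tab <- data.frame(participant = rep(sprintf("P%02d", 1:30), 3),
                      component = rep(1:3, each = 30),
                      x = pts[, 1], y = pts[, 2], z = pts[, 3],
                      variance_explained = runif(90))
    ca <- clusterComponents(tab, kRange = 2:8, seed = 4)
    expect_equal(ca$k, 3)
    truthLab <- rep(1:3, each = 30)
    expect_equal(adjustedRand(ca$membership$cluster, truthLab), 1.0)
    expect_lt(max(abs(ca$centroids[order(ca$centroids[, 1]), ] -
                        centers[order(centers[, 1]), ])), 2)
    ## one retained component per participant per cluster, the one with
    ## the largest variance explained
    m <- ca$membership
    for (cl in 1:3) {
      rows <- m[m$cluster == cl & !m$outlier, ]
      for (p in unique(rows$participant)) {
        pr <- rows[rows$participant == p, ]
        expect_equal(sum(pr$retained), 1)
        expect_equal(pr$variance_explained[pr$retained],
                     max(pr$variance_explained))
      }
    }
    ## a point ~10 SD from its centroid is flagged as an outlier and
    ## excluded from the centroid
    tab2 <- tab
    tab2[1, c("x", "y", "z")] <- c(-50, 0, 30)
    ca2 <- clusterComponents(tab2, kRange = 2:8, seed = 4)
    expect_equal(ca2$k, 3)
    expect_true(ca2$membership$outlier[1])
    expect_false(ca2$membership$retained[1])
    expect_lt(max(abs(sort(ca2$centroids[, 1]) - sort(centers[, 1]))), 3)
    ## degenerate input
    tab3 <- tab; tab3[, c("x", "y", "z")] <- 0
    expect_error(clusterComponents(tab3, kRange = 2:8), "no cluster structure")
  })
})

test_that("retention never increases cluster size and silhouettes are
           reported for audit", {
  withr::with_seed(11, {
    pts <- matrix(rnorm(3 * 60, sd = 30), 60)
    tab <- data.frame(participant = sprintf("P%02d", rep(1:20, 3)),
                      component = rep(1:3, each = 20),
                      x = pts[, 1], y = pts[, 2], z = pts[, 3],
                      variance_explained = runif(60))
    ca <- clusterComponents(tab, kRange = 2:6, seed = 2)
    expect_true(all(as.integer(names(ca$silhouetteByK)) %in% 2:6))
    expect_lte(sum(ca$membership$retained), nrow(tab))
    byCl <- table(ca$membership$cluster[ca$membership$retained])
    expect_true(all(byCl <= table(ca$membership$cluster)[names(byCl)]))
    ## deterministic given the seed
    ca2 <- clusterComponents(tab, kRange = 2:6, seed = 2)
    expect_identical(ca$membership$cluster, ca2$membership$cluster)
  })
})
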