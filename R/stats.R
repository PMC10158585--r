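## Resampling statistics: bootstrap significance masks with time-shuffled
## nulls, Benjamini-Hochberg FDR, cluster-based permutation condition
## contrasts, and the paired Wilcoxon signed-rank test.

#' Wilcoxon signed-rank test on paired differences
#'
#' Exact two-sided p-value for n <= 25 non-zero differences, computed by
#' enumerating the signed-rank distribution through its generating
#' function (doubled ranks, so midranks from ties are handled exactly);
#' normal approximation with tie correction and continuity correction for
#' larger n.  Zero differences are dropped; if all differences are zero
#' the test is degenerate and p = 1 is returned with a warning.
#'
#' @param d numeric vector of paired differences.
#' @param exactMax largest n for which the exact distribution is used.
#' @return list: `statistic` (W+, sum of positive ranks), `p` (two-sided),
#'   `n` (non-zero differences), `method`.
#' @export
wilcoxonSignedRank <- function(d, exactMax = 25) {
  d <- d[is.finite(d)]
  nz <- d[d != 0]
  n <- length(nz)
  if (n == 0) {
    warning("all differences are zero: test is degenerate")
    return(list(statistic = 0, p = 1, n = 0, method = "degenerate"))
  }
  r <- rank(abs(nz))
  W <- sum(r[nz > 0])
  if (n <= exactMax) {
    ## generating function over doubled ranks: coefficients of
    ## prod_i (1 + z^{2 r_i}) give counts of each achievable 2*W
    r2 <- round(2 * r)
    maxS <- sum(r2)
    cnt <- numeric(maxS + 1)
    cnt[1] <- 1
    for (ri in r2) {
      shifted <- c(rep(0, ri), cnt[seq_len(maxS + 1 - ri)])
      cnt <- cnt + shifted
    }
    tot <- 2^n
    W2 <- round(2 * W)
    pGe <- sum(cnt[(W2 + 1):(maxS + 1)]) / tot
    pLe <- sum(cnt[1:(W2 + 1)]) / tot
    p <- min(1, 2 * min(pGe, pLe))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = W, p = p, n = n, method = method)
}

#' Benjamini-Hochberg step-up mask
#'
#' Rejects the hypotheses whose sorted p-values satisfy
#' `p_(i) <= i q / m` up to the largest such i.
#'
#' @param pvals numeric p-values in `[0, 1]` (any shape; shape preserved).
#' @param q FDR level (default 0.05).
#' @return logical mask of rejections, same shape as `pvals`.
#' @export
bhFdr <- function(pvals, q = 0.05) {
  if (!length(pvals)) return(logical(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    scStop("p-values must lie in [0, 1]")
  out <- p.adjust(as.vector(pvals), method = "BH") <= q
  if (!is.null(dim(pvals))) dim(out) <- dim(pvals)
  out
}

## Stack a list of equally sized matrices into units x cells.
stackMaps <- function(maps) {
  if (is.array(maps) && length(dim(maps)) == 3) {
    d <- dim(maps)
    list(X = matrix(maps, d[1]), dims = d[2:3])
  } else {
    d <- dim(maps[[1]])
    list(X = t(vapply(maps, as.vector, numeric(prod(d)))), dims = d)
  }
}

#' Bootstrap significance mask with a time-shuffled null
#'
#' Tests, per time-frequency cell, whether the group-mean map differs
#' from a stationarity null built by circularly shifting every unit's
#' map along the time axis by an independent random offset and
#' recomputing the group mean (`nIter` times).  Two-sided pointwise
#' p-values use the (b+1)/(n+1) convention, are BH-corrected across all
#' cells, and non-significant cells are zeroed in the masked output.
#'
#' @param maps list of freqs x times matrices (one per participant or
#'   trial), or a units x freqs x times array.
#' @param nIter bootstrap iterations (default 2000; at least 100).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed.
#' @param correction `"BH"` (default) or `"none"`.
#' @param center null-centering value subtracted before the two-sided
#'   comparison: the per-cell null mean by default.
#' @return list of class `SignificanceMask`: `observed`, `p`, `mask`,
#'   `masked` (observed with non-significant cells set to 0), `alpha`,
#'   `nIter`, `correction`, `seed`.
#' @export
bootstrapMask <- function(maps, nIter = 2000, alpha = 0.05, seed = 1,
                          correction = c("BH", "none")) {
  correction <- match.arg(correction)
  if (nIter < 100) scStop("nIter must be at least 100")
  st <- stackMaps(maps)
  X <- st$X
  if (nrow(X) < 5) scStop("need at least 5 units (participants or trials)")
  nU <- nrow(X); nC <- ncol(X)
  nT <- st$dims[2]; nF <- st$dims[1]
  obs <- colMeans(X)
  geCnt <- numeric(nC); leCnt <- numeric(nC)
  withSeed(seed, {
    for (b in seq_len(nIter)) {
      Xs <- X
      sh <- sample.int(nT, nU, replace = TRUE) - 1L
      for (u in seq_len(nU)) {
        if (sh[u] == 0L) next
        m <- matrix(X[u, ], nF, nT)
        idx <- c((nT - sh[u] + 1):nT, seq_len(nT - sh[u]))
        Xs[u, ] <- as.vector(m[, idx])
      }
      nullStat <- colMeans(Xs)
      geCnt <- geCnt + (nullStat >= obs)
      leCnt <- leCnt + (nullStat <= obs)
    }
  })
  pGe <- (geCnt + 1) / (nIter + 1)
  pLe <- (leCnt + 1) / (nIter + 1)
  p <- pmin(1, 2 * pmin(pGe, pLe))
  mask <- if (correction == "BH") bhFdr(p, alpha) else p <= alpha
  obsM <- matrix(obs, nF, nT)
  pM <- matrix(p, nF, nT)
  maskM <- matrix(mask, nF, nT)
  structure(list(observed = obsM, p = pM, mask = maskM,
                 masked = obsM * maskM, alpha = alpha, nIter = nIter,
                 correction = correction, seed = seed),
            class = "SignificanceMask")
}

#' @export
print.SignificanceMask <- function(x, ...) {
  cat(sprintf("SignificanceMask: %d x %d cells, %.1f%% significant (alpha %.3g, %s, %d iter)\n",
              nrow(x$mask), ncol(x$mask), 100 * mean(x$mask), x$alpha,
              x$correction, x$nIter))
  invisible(x)
}

#' Cluster-based permutation test for a paired condition contrast
#'
#' Per-cell paired t statistics on participant map differences; cells
#' with |t| above the two-sided alpha threshold form 4-connected clusters
#' whose mass (sum of |t|) is compared against the maximum-cluster-mass
#' distribution under random within-pair condition flips.
#'
#' @param mapsA,mapsB lists of freqs x times matrices (or units x f x t
#'   arrays), paired by participant.
#' @param nPerm permutations (default 2000).
#' @param alpha cluster-forming and cluster-level significance level.
#' @param seed integer seed.
#' @return list of class `PermutationResult`: `tMap`, `clusters`
#'   (data.frame `id`, `mass`, `p`, `nCells`), `labels` (integer matrix),
#'   `mask` (cells in significant clusters), `nullMaxMass`, `nPerm`,
#'   `alpha`, `seed`.
#' @export
clusterPermutation <- function(mapsA, mapsB, nPerm = 2000, alpha = 0.05,
                               seed = 1) {
  sa <- stackMaps(mapsA); sb <- stackMaps(mapsB)
  if (!all(sa$dims == sb$dims) || nrow(sa$X) != nrow(sb$X))
    scStop("condition maps must have identical unit counts and shapes")
  n <- nrow(sa$X)
  if (n < 8) scStop("need at least 8 participant pairs")
  D <- sa$X - sb$X
  nC <- ncol(D)
  dims <- sa$dims
  tcrit <- stats::qt(1 - alpha / 2, df = n - 1)
  tOf <- function(meanD, meanSq) {
    v <- (meanSq - meanD^2) * n / (n - 1)
    meanD / sqrt(pmax(v, 1e-300) / n)
  }
  meanSq <- colMeans(D^2)   # invariant under sign flips
  tObs <- matrix(tOf(colMeans(D), meanSq), dims[1], dims[2])
  lab <- .labelClusters(tObs, tcrit)
  nullMax <- numeric(nPerm)
  withSeed(seed, {
    S <- matrix(sample(c(-1, 1), nPerm * n, replace = TRUE), nPerm, n)
    M <- (S %*% D) / n
    for (b in seq_len(nPerm)) {
      tb <- matrix(tOf(M[b, ], meanSq), dims[1], dims[2])
      nullMax[b] <- .maxClusterMass(tb, tcrit)
    }
  })
  mass <- lab$mass
  pCl <- vapply(mass, function(m) (sum(nullMax >= m) + 1) / (nPerm + 1),
                numeric(1))
  clusters <- data.frame(id = seq_along(mass), mass = mass, p = pCl,
                         nCells = as.vector(table(factor(lab$labels[lab$labels > 0],
                                                         levels = seq_along(mass)))))
  sig <- which(pCl <= alpha)
  mask <- matrix(lab$labels %in% sig, dims[1], dims[2])
  structure(list(tMap = tObs, clusters = clusters, labels = lab$labels,
                 mask = mask, nullMaxMass = nullMax, nPerm = nPerm,
                 alpha = alpha, seed = seed),
            class = "PermutationResult")
}

#' @export
print.PermutationResult <- function(x, ...) {
  cat(sprintf("PermutationResult: %d cluster(s), %d permutations (alpha %.3g)\n",
              nrow(x$clusters), x$nPerm, x$alpha))
  if (nrow(x$clusters)) print(round(x$clusters, 4))
  invisible(x)
}
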