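## Rank-reduced ICA decomposition, brain-component selection, and
## group-level k-means clustering of component source locations.

#' Reduce data rank by PCA
#'
#' Projects channels x samples data onto its top
#' `nrow(data) - nInterpolatedMax` principal components, so that the rank
#' lost to channel interpolation is removed before ICA.
#'
#' @param data channels x samples matrix.
#' @param nInterpolatedMax largest number of channels interpolated in any
#'   constituent recording.
#' @return list with `reduced` (k x samples), `basis` (channels x k
#'   orthonormal), `center` (per-channel means), `k`.
#' @export
pcaReduce <- function(data, nInterpolatedMax = 0) {
  if (any(!is.finite(data))) scStop("data must be finite")
  if (nInterpolatedMax >= nrow(data))
    scStop("cannot remove %d components from %d channels",
           nInterpolatedMax, nrow(data))
  k <- nrow(data) - nInterpolatedMax
  center <- rowMeans(data)
  Xc <- data - center
  sv <- svd(Xc, nu = k, nv = 0)
  list(reduced = crossprod(sv$u, Xc), basis = sv$u, center = center, k = k)
}

## JADE on whitened data Z (k x n): estimate the parallel set of
## fourth-order cumulant matrices and jointly diagonalise them by Jacobi
## (Givens) rotations.  Deterministic; the sweep loop terminates when no
## rotation in a full sweep exceeds the angle threshold.  Returns the
## orthogonal unmixing rotation W (k x k) or NULL if the sweeps fail to
## settle.
jadeCore <- function(Z, maxit = 100, tol = NULL, maxSamples = 20000) {
  ## cumulant estimates stabilise long before 2e4 samples; subsample a
  ## deterministic stride for speed on long recordings
  if (ncol(Z) > maxSamples)
    Z <- Z[, round(seq(1, ncol(Z), length.out = maxSamples)), drop = FALSE]
  k <- nrow(Z); n <- ncol(Z)
  tol <- tol %||% (1 / sqrt(n) / 100)
  nCM <- k * (k + 1) / 2
  ## cumulant matrices, stored side by side in a k x (k * nCM) block row
  CM <- matrix(0, k, k * nCM)
  col0 <- 0
  for (i in seq_len(k)) {
    zi <- Z[i, ]
    Qii <- (Z * rep(zi * zi, each = k)) %*% t(Z) / n - diag(k)
    Qii[i, i] <- Qii[i, i] - 2
    CM[, col0 + seq_len(k)] <- Qii
    col0 <- col0 + k
    if (i > 1) for (j in seq_len(i - 1)) {
      zj <- Z[j, ]
      Qij <- (Z * rep(zi * zj, each = k)) %*% t(Z) / n
      Qij[i, j] <- Qij[i, j] - 1
      Qij[j, i] <- Qij[j, i] - 1
      CM[, col0 + seq_len(k)] <- sqrt(2) * Qij
      col0 <- col0 + k
    }
  }
  V <- diag(k)
  for (sweep in seq_len(maxit)) {
    rotated <- FALSE
    for (p in seq_len(k - 1)) for (q in (p + 1):k) {
      ip <- seq(p, k * nCM, by = k)
      iq <- seq(q, k * nCM, by = k)
      g1 <- CM[p, ip] - CM[q, iq]
      g2 <- CM[p, iq] + CM[q, ip]
      ton <- sum(g1 * g1) - sum(g2 * g2)
      toff <- 2 * sum(g1 * g2)
      theta <- 0.5 * atan2(toff, ton + sqrt(ton * ton + toff * toff))
      if (abs(sin(theta)) > tol) {
        rotated <- TRUE
        cs <- cos(theta); sn <- sin(theta)
        rowP <- CM[p, ]; rowQ <- CM[q, ]
        CM[p, ] <- cs * rowP + sn * rowQ
        CM[q, ] <- -sn * rowP + cs * rowQ
        colP <- CM[, ip]; colQ <- CM[, iq]
        CM[, ip] <- cs * colP + sn * colQ
        CM[, iq] <- -sn * colP + cs * colQ
        vp <- V[, p]; vq <- V[, q]
        V[, p] <- cs * vp + sn * vq
        V[, q] <- -sn * vp + cs * vq
      }
    }
    if (!rotated) return(list(W = t(V), iter = sweep))
  }
  NULL
}

## One symmetric FastICA run on whitened data Z (k x n).  Returns the
## rotation W (k x k) or NULL if not converged.
fastIcaCore <- function(Z, maxit, tol) {
  k <- nrow(Z); n <- ncol(Z)
  W <- qr.Q(qr(matrix(rnorm(k * k), k)))
  symDecor <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% (t(e$vectors) / sqrt(pmax(e$values, 1e-12))) %*% W
  }
  W <- symDecor(W)
  for (it in seq_len(maxit)) {
    WX <- W %*% Z
    G <- tanh(WX)
    gP <- rowMeans(1 - G^2)
    Wnew <- (G %*% t(Z)) / n - gP * W
    Wnew <- symDecor(Wnew)
    delta <- max(abs(1 - abs(rowSums(Wnew * W))))
    W <- Wnew
    if (delta < tol) return(list(W = W, iter = it))
  }
  NULL
}

#' Fit an independent component decomposition
#'
#' JADE (default: joint diagonalisation of the parallel set of
#' fourth-order cumulant matrices, deterministic Jacobi rotations) or
#' symmetric FastICA (logcosh contrast) on PCA-whitened data.  The result
#' is deterministic given `seed` (JADE is deterministic outright; the seed
#' governs the FastICA init); for FastICA up to three seeded restarts are
#' attempted before declaring non-convergence.  Components are ordered by
#' decreasing explained scalp variance and sign-fixed so the largest
#' mixing coefficient of each component is positive.
#'
#' @param data channels x samples matrix (e.g. cleaned scalp data, with
#'   bad stretches already excluded).
#' @param nComp number of components (default: full rank).
#' @param method `"jade"` (robust at the channel counts this pipeline
#'   uses) or `"fastica"`.
#' @param seed integer seed for the FastICA random init.
#' @param maxit,tol convergence controls (Jacobi sweeps / angle threshold
#'   for JADE, iterations / rotation tolerance for FastICA).
#' @param participant identifier stored in the result.
#' @param fs sampling rate of `data`, Hz.
#' @return a [ComponentSet]; positions are NA and labels `unknown` until
#'   annotated.
#' @export
fitIca <- function(data, nComp = nrow(data),
                   method = c("jade", "fastica"), seed = 1,
                   maxit = NULL, tol = NULL, participant = "P01", fs = 250) {
  method <- match.arg(method)
  if (any(!is.finite(data))) scStop("data must be finite")
  if (ncol(data) < 20 * nrow(data))
    scStop("too little data for a stable decomposition (need >= 20 samples per channel)")
  maxit <- maxit %||% if (method == "jade") 100 else 1000
  tol <- tol %||% if (method == "fastica") 1e-4 else NULL
  center <- rowMeans(data)
  Xc <- data - center
  C <- tcrossprod(Xc) / ncol(Xc)
  e <- eigen(C, symmetric = TRUE)
  keep <- seq_len(nComp)
  ev <- pmax(e$values[keep], max(e$values) * 1e-12)
  E <- e$vectors[, keep, drop = FALSE]
  Wwhite <- (t(E) / sqrt(ev))          # k x channels
  dewhite <- E * rep(sqrt(ev), each = nrow(E))  # channels x k
  Z <- Wwhite %*% Xc
  fit <- NULL
  if (method == "jade") {
    fit <- jadeCore(Z, maxit, tol)
    if (is.null(fit))
      scStop("ICA (jade) failed: joint diagonalisation did not settle in %d sweeps",
             maxit)
  } else {
    for (attempt in 0:2) {
      fit <- withSeed(seed + attempt, fastIcaCore(Z, maxit, tol))
      if (!is.null(fit)) break
    }
    if (is.null(fit))
      scStop("ICA (fastica) failed to converge within %d iterations (3 restarts, tol %g)",
             maxit, tol)
  }
  W <- fit$W
  unmixing <- W %*% Wwhite             # comps x channels
  mixing <- dewhite %*% solve(W)       # channels x comps
  act <- unmixing %*% Xc
  totVar <- sum(Xc^2)
  ve <- vapply(seq_len(nComp), function(i)
    sum(mixing[, i]^2) * sum(act[i, ]^2) / totVar, numeric(1))
  ord <- order(ve, decreasing = TRUE)
  unmixing <- unmixing[ord, , drop = FALSE]
  mixing <- mixing[, ord, drop = FALSE]
  act <- act[ord, , drop = FALSE]
  ve <- ve[ord]
  for (i in seq_len(nComp)) {
    j <- which.max(abs(mixing[, i]))
    if (mixing[j, i] < 0) {
      mixing[, i] <- -mixing[, i]
      unmixing[i, ] <- -unmixing[i, ]
      act[i, ] <- -act[i, ]
    }
  }
  new("ComponentSet", unmixing = unmixing, mixing = mixing,
      activations = act, fs = fs, participant = participant,
      positions = matrix(NA_real_, nComp, 3),
      labels = rep("unknown", nComp), varianceExplained = ve)
}

#' Apply an unmixing matrix to (possibly longer) channel data
#'
#' The weights learned on the bad-window-masked data are applied to the
#' full continuous timeline, so epoching can use every sample.
#'
#' @param cs a [ComponentSet] (its `unmixing` is used).
#' @param data channels x samples matrix with matching channel count.
#' @return components x samples activation matrix.
#' @export
applyUnmixing <- function(cs, data) {
  W <- if (is(cs, "ComponentSet")) cs@unmixing else as.matrix(cs)
  if (ncol(W) != nrow(data))
    scStop("channel count mismatch: weights expect %d channels, data has %d",
           ncol(W), nrow(data))
  W %*% data
}

#' Annotate components against the synthetic ground truth
#'
#' Stands in for equivalent-dipole fitting plus automated component
#' classification, which require real head models: each component's scalp
#' map (mixing column) is correlated with the planted sources' forward
#' gains; a component matching a source with |r| above `minAbsCor` is
#' labelled `brain` and assigned that source's participant-specific
#' position plus a small localisation error, the rest are labelled
#' `nonbrain`.
#'
#' @param cs a [ComponentSet].
#' @param truth `GroundTruth` from [generateStudy()].
#' @param minAbsCor topography-match threshold.
#' @param posErrorSd simulated dipole-localisation error SD, mm.
#' @param seed integer seed for the localisation error.
#' @return the annotated [ComponentSet].
#' @export
annotateComponentsFromTruth <- function(cs, truth, minAbsCor = 0.80,
                                        posErrorSd = 2, seed = 1) {
  stopifnot(is(cs, "ComponentSet"))
  p <- cs@participant
  trueMix <- truth$forward[[p]]$mixing
  truePos <- truth$sourcePositions[[p]]
  k <- ncol(cs@mixing)
  withSeed(deriveSeed(seed, paste0(p, ":annot")), {
    for (i in seq_len(k)) {
      cors <- suppressWarnings(abs(cor(cs@mixing[, i], trueMix)))
      cors[!is.finite(cors)] <- -1
      best <- which.max(cors)
      if (cors[best] >= minAbsCor) {
        cs@labels[i] <- "brain"
        cs@positions[i, ] <- truePos[best, ] + rnorm(3, sd = posErrorSd)
      } else {
        cs@labels[i] <- "nonbrain"
      }
    }
  })
  cs
}

## Subset a ComponentSet by component index.
subsetComponents <- function(cs, idx) {
  new("ComponentSet",
      unmixing = cs@unmixing[idx, , drop = FALSE],
      mixing = cs@mixing[, idx, drop = FALSE],
      activations = cs@activations[idx, , drop = FALSE],
      fs = cs@fs, participant = cs@participant,
      positions = cs@positions[idx, , drop = FALSE],
      labels = cs@labels[idx],
      varianceExplained = cs@varianceExplained[idx])
}

#' Retain brain components and exclude sparse participants
#'
#' Keeps only components labelled `brain` in each participant's
#' [ComponentSet]; participants contributing fewer than
#' `minPerParticipant` brain components are removed entirely.
#'
#' @param csList named list of annotated [ComponentSet]s (one per
#'   participant).
#' @param minPerParticipant minimum brain components per participant
#'   (default 5).
#' @return the filtered named list.
#' @export
selectBrainComponents <- function(csList, minPerParticipant = 5) {
  out <- list()
  for (nm in names(csList)) {
    cs <- csList[[nm]]
    idx <- which(cs@labels == "brain")
    if (length(idx) >= minPerParticipant)
      out[[nm]] <- subsetComponents(cs, idx)
  }
  if (!length(out))
    scStop("all participants excluded (fewer than %d brain components each)",
           minPerParticipant)
  out
}

#' Cluster component locations across participants
#'
#' K-means on 3-D component positions (MNI mm) with k chosen by maximum
#' mean silhouette over `kRange`, seeded restarts, a 3 SD outlier rule
#' (z-score of the Euclidean point-to-assigned-centroid distances),
#' centroid recomputation excluding outliers, and retention of at most
#' one component per participant per cluster (the one with the largest
#' explained scalp variance).
#'
#' @param positions data.frame with columns `participant`, `component`,
#'   `x`, `y`, `z`, `variance_explained`.
#' @param kRange candidate cluster counts (trimmed so that at least 3
#'   points per cluster are available).
#' @param outlierSd outlier threshold in SD units.
#' @param seed integer seed for the k-means restarts.
#' @param nstart k-means restarts.
#' @return list of class `ClusterAssignment`: `k`, `centroids`,
#'   `membership` (positions plus `cluster`, `outlier`, `retained`),
#'   `silhouetteByK`.
#' @export
clusterComponents <- function(positions, kRange = 2:15, outlierSd = 3,
                              seed = 1, nstart = 50) {
  need <- c("participant", "component", "x", "y", "z", "variance_explained")
  if (!all(need %in% names(positions)))
    scStop("positions must have columns: %s", paste(need, collapse = ", "))
  X <- as.matrix(positions[, c("x", "y", "z")])
  n <- nrow(X)
  if (all(dist(X) < 1e-9)) scStop("no cluster structure: all points identical")
  kRange <- kRange[kRange >= 2 & kRange * 3 <= n]
  if (!length(kRange)) scStop("too few points for the requested k range")
  D <- dist(X)
  sil <- setNames(numeric(length(kRange)), kRange)
  fits <- list()
  for (j in seq_along(kRange)) {
    k <- kRange[j]
    km <- withSeed(deriveSeed(seed, paste0("kmeans", k)),
                   kmeans(X, k, nstart = nstart, iter.max = 100))
    fits[[j]] <- km
    sil[j] <- mean(cluster::silhouette(km$cluster, D)[, 3])
  }
  best <- which.max(sil)
  km <- fits[[best]]
  k <- kRange[best]
  ## a point is an outlier when its centroid distance is more than
  ## outlierSd standard deviations above the mean distance (3-D distances
  ## have a non-zero mean, so the z-score is taken on the distances)
  dOwn <- sqrt(rowSums((X - km$centers[km$cluster, , drop = FALSE])^2))
  sdd <- sd(dOwn)
  outlier <- if (sdd > 0) (dOwn - mean(dOwn)) / sdd > outlierSd
  else rep(FALSE, length(dOwn))
  centroids <- t(vapply(seq_len(k), function(cl) {
    pts <- X[km$cluster == cl & !outlier, , drop = FALSE]
    if (!nrow(pts)) km$centers[cl, ] else colMeans(pts)
  }, numeric(3)))
  colnames(centroids) <- c("x", "y", "z")
  membership <- positions
  membership$cluster <- km$cluster
  membership$outlier <- outlier
  membership$retained <- FALSE
  for (cl in seq_len(k)) {
    rows <- which(membership$cluster == cl & !membership$outlier)
    for (p in unique(membership$participant[rows])) {
      pr <- rows[membership$participant[rows] == p]
      membership$retained[pr[which.max(membership$variance_explained[pr])]] <- TRUE
    }
  }
  structure(list(k = k, centroids = centroids, membership = membership,
                 silhouetteByK = sil),
            class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat(sprintf("ClusterAssignment: k = %d (%d points, %d outliers, %d retained)\n",
              x$k, nrow(x$membership), sum(x$membership$outlier),
              sum(x$membership$retained)))
  invisible(x)
}

#' Collect component positions from annotated component sets
#'
#' @param csList named list of [ComponentSet]s.
#' @return data.frame suitable for [clusterComponents()].
#' @export
componentPositionTable <- function(csList) {
  do.call(rbind, lapply(names(csList), function(nm) {
    cs <- csList[[nm]]
    idx <- which(cs@labels == "brain" & is.finite(cs@positions[, 1]))
    if (!length(idx)) return(NULL)
    data.frame(participant = cs@participant, component = idx,
               x = cs@positions[idx, 1], y = cs@positions[idx, 2],
               z = cs@positions[idx, 3],
               variance_explained = cs@varianceExplained[idx],
               stringsAsFactors = FALSE)
  }))
}
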